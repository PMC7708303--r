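#' Define the age-bin grid
#'
#' The analysis grid divides ages 0 to \code{max_age} years into
#' half-open bins \eqn{[k w, (k+1) w)} of width \code{bin_width}. The
#' default 3-month bins over 0-25 years give exactly 100 bins. Bin indices
#' are 0-based: bin 0 covers birth to 3 months.
#'
#' @param bin_width Bin width in years (default 0.25, i.e. 3 months).
#' @param max_age Upper age limit in years (default 25).
#' @return Object of class \code{bin_grid}: list(bin_width, max_age, n_bins).
#' @export
bin_grid <- function(bin_width = 0.25, max_age = 25) {
  stopifnot(bin_width > 0, max_age > 0)
  n <- max_age / bin_width
  if (abs(n - round(n)) > 1e-9)
    stop("max_age must be an integer multiple of bin_width")
  structure(list(bin_width = bin_width, max_age = max_age,
                 n_bins = as.integer(round(n))), class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("<bin_grid> ", x$n_bins, " bins of ", x$bin_width, " y over [0, ",
      x$max_age, ") y\n", sep = "")
  invisible(x)
}

#' Map an age to its bin index
#'
#' Returns \code{floor(age / bin_width)} for ages in \eqn{[0, max\_age)};
#' ages at or beyond the grid maximum return \code{NA} (the out-of-range
#' marker). Negative ages are an error.
#'
#' @param age Numeric vector of ages in years.
#' @param grid A \code{bin_grid}.
#' @return Integer vector of 0-based bin indices, \code{NA} where out of
#'   range.
#' @export
bin_index <- function(age, grid = bin_grid()) {
  stopifnot(inherits(grid, "bin_grid"))
  if (any(age < 0)) stop("negative encounter age")
  idx <- as.integer(floor(age / grid$bin_width))
  idx[age >= grid$max_age] <- NA_integer_
  idx
}

#' EMR-usage window of one individual
#'
#' The interval between the minimum and maximum age at documented
#' encounters, within which usage is assumed uninterrupted and phenotype
#' absence is interpretable.
#'
#' @param ages Numeric vector of encounter ages (years) of one individual.
#' @return Numeric vector \code{c(min_age, max_age)}.
#' @export
usage_window <- function(ages) {
  if (!length(ages)) stop("cannot derive a usage window from zero encounters")
  if (any(ages < 0)) stop("negative encounter age")
  c(min_age = min(ages), max_age = max(ages))
}

#' EMR-usage windows for a whole encounter table
#'
#' @param raw data.frame with columns \code{individual_id} and
#'   \code{age_years} (any further columns ignored); typically the raw
#'   encounter table, before ICD filtering, so that every documented
#'   contact extends the window.
#' @return data.frame (individual_id, min_age, max_age), one row per
#'   individual, ordered by individual_id.
#' @export
usage_windows <- function(raw) {
  stopifnot(all(c("individual_id", "age_years") %in% names(raw)))
  if (any(raw$age_years < 0)) stop("negative encounter age")
  sp <- split(raw$age_years, raw$individual_id)
  data.frame(
    individual_id = names(sp),
    min_age = vapply(sp, min, numeric(1)),
    max_age = vapply(sp, max, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Logical individuals x bins matrix: does the (closed, grid-clipped) window
# intersect the half-open bin? A window touching a bin only at the bin's
# left edge counts, so single-encounter individuals are informative in
# exactly one bin.
informative_matrix <- function(windows, grid) {
  lo <- pmin(windows$min_age, grid$max_age)
  hi <- pmin(windows$max_age, grid$max_age)
  starts <- (seq_len(grid$n_bins) - 1L) * grid$bin_width
  ends <- starts + grid$bin_width
  inf <- outer(lo, ends, "<") & outer(hi, starts, ">=")
  dimnames(inf) <- list(windows$individual_id, as.character(seq_len(grid$n_bins) - 1L))
  inf
}

#' Build the present/absent/not-applicable tensor
#'
#' For every individual and bin, takes the union of the propagated term
#' sets over all mapped encounters falling in that bin (duplicates from
#' repeat encounters or convergent mappings removed). A term is
#' \emph{present} if it is in that union, \emph{absent} if the bin
#' intersects the individual's usage window but the term was not coded,
#' and \emph{not applicable} if the bin lies outside the window. Encounter
#' ages at or beyond the grid maximum are dropped from binning (they still
#' shaped the usage window, which is clipped to the grid for intersection).
#'
#' @param mapped data.frame from [map_encounters()].
#' @param graph An \code{ontology_graph} used for propagation.
#' @param grid A \code{bin_grid}.
#' @param windows data.frame from [usage_windows()]; every individual in
#'   \code{mapped} must have a window.
#' @return Object of class \code{presence_tensor}: list with
#'   \item{present}{3-d logical array individuals x bins x terms.}
#'   \item{informative}{logical matrix individuals x bins.}
#'   \item{individuals, terms}{dimension labels.}
#'   \item{grid, windows}{the inputs.}
#' @export
build_presence <- function(mapped, graph, grid, windows) {
  stopifnot(inherits(graph, "ontology_graph"), inherits(grid, "bin_grid"))
  missing_w <- setdiff(unique(mapped$individual_id), windows$individual_id)
  if (length(missing_w))
    stop("mapped rows for individual(s) without a usage window: ",
         paste(utils::head(missing_w, 5L), collapse = ", "))

  individuals <- sort(unique(windows$individual_id))
  windows <- windows[match(individuals, windows$individual_id), , drop = FALSE]
  inf <- informative_matrix(windows, grid)

  bins <- bin_index(mapped$age_years, grid)
  keep <- !is.na(bins)
  mapped <- mapped[keep, , drop = FALSE]
  bins <- bins[keep]

  closures <- lapply(unique(mapped$term), function(t) propagate(graph, t))
  names(closures) <- unique(mapped$term)
  terms <- sort(unique(unlist(closures, use.names = FALSE)))

  present <- array(FALSE,
                   dim = c(length(individuals), grid$n_bins, length(terms)),
                   dimnames = list(individuals,
                                   as.character(seq_len(grid$n_bins) - 1L),
                                   terms))
  if (nrow(mapped)) {
    reps <- lengths(closures[mapped$term])
    i <- match(rep(mapped$individual_id, reps), individuals)
    b <- rep(bins, reps) + 1L
    t <- match(unlist(closures[mapped$term], use.names = FALSE), terms)
    present[cbind(i, b, t)] <- TRUE
  }

  structure(list(present = present, informative = inf,
                 individuals = individuals, terms = terms,
                 grid = grid, windows = windows),
            class = "presence_tensor")
}

#' @export
print.presence_tensor <- function(x, ...) {
  cat("<presence_tensor> ", length(x$individuals), " individuals x ",
      x$grid$n_bins, " bins x ", length(x$terms), " terms; ",
      sum(x$informative), " informative (individual, bin) cells, ",
      sum(x$present), " present states\n", sep = "")
  invisible(x)
}

#' Per-bin frequency trajectory of one term
#'
#' Counts, at every bin, the individuals with the term present and the
#' individuals informative (usage window intersecting the bin). A term
#' never observed in the cohort yields an all-zero present count with
#' unchanged informative counts.
#'
#' @param tensor A \code{presence_tensor}.
#' @param term A term id.
#' @return data.frame (bin, age_start, n_present, n_informative,
#'   frequency); frequency is \code{NA} where no individual is informative.
#' @export
term_trajectory <- function(tensor, term) {
  stopifnot(inherits(tensor, "presence_tensor"), length(term) == 1L)
  n_inf <- colSums(tensor$informative)
  n_pres <- if (term %in% tensor$terms)
              colSums(matrix(tensor$present[, , term],
                             nrow = length(tensor$individuals)))
            else numeric(tensor$grid$n_bins)
  data.frame(
    bin = seq_len(tensor$grid$n_bins) - 1L,
    age_start = (seq_len(tensor$grid$n_bins) - 1L) * tensor$grid$bin_width,
    n_present = as.integer(n_pres),
    n_informative = as.integer(n_inf),
    frequency = ifelse(n_inf > 0, n_pres / n_inf, NA_real_)
  )
}

#' Per-bin present-count matrix over all terms
#'
#' Compact terms x bins matrix of present counts, suitable for
#' heatmap-style export of term-frequency trajectories.
#'
#' @param tensor A \code{presence_tensor}.
#' @return Integer matrix, rows = terms, columns = 0-based bin labels.
#' @export
presence_counts <- function(tensor) {
  stopifnot(inherits(tensor, "presence_tensor"))
  m <- apply(tensor$present, c(3L, 2L), sum)
  storage.mode(m) <- "integer"
  m
}

#' Export the tensor in long format
#'
#' Writes one row per (individual, bin, term) with state coded
#' \code{present}, \code{absent} or \code{not_applicable}. Absent states
#' are enumerated only for terms observed in the cohort.
#'
#' @param tensor A \code{presence_tensor}.
#' @param path Output TSV path.
#' @return Invisibly, the number of rows written.
#' @export
write_presence_long <- function(tensor, path) {
  stopifnot(inherits(tensor, "presence_tensor"))
  grid <- expand.grid(individual_id = tensor$individuals,
                      bin = seq_len(tensor$grid$n_bins) - 1L,
                      term = tensor$terms,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  inf <- as.vector(tensor$informative[cbind(
    match(grid$individual_id, tensor$individuals), grid$bin + 1L)])
  pres <- as.vector(tensor$present)
  grid$state <- ifelse(!inf, "not_applicable", ifelse(pres, "present", "absent"))
  utils::write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nrow(grid))
}
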