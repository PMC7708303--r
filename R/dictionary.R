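#' Load a diagnosis-code to ontology-term dictionary
#'
#' Reads a tab-separated dictionary with columns \code{source_code},
#' \code{icd_code} and \code{hpo_id}. A row with an empty \code{hpo_id}
#' marks the source code as explicitly unmappable. A source code may map to
#' several terms (one row each); duplicate (code, term) rows collapse to a
#' single entry with a warning.
#'
#' @param path Path to the dictionary TSV.
#' @param graph An \code{ontology_graph}; every mapped term id must exist in
#'   it (alternate ids are resolved), otherwise loading fails listing the
#'   offenders.
#' @return An object of class \code{diagnosis_dictionary}: a list with
#'   \item{entries}{data.frame (source_code, icd_code, hpo_id).}
#'   \item{unmapped}{character vector of explicitly unmappable codes.}
#'   \item{icd}{named character vector mapping source code to its ICD code.}
#' @export
load_dictionary <- function(path, graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  if (!file.exists(path)) stop("dictionary file not found: ", path)
  d <- utils::read.delim(path, colClasses = "character", fill = TRUE,
                         na.strings = character())
  need <- c("source_code", "icd_code", "hpo_id")
  if (!all(need %in% names(d)))
    stop("dictionary must have columns: ", paste(need, collapse = ", "))
  d$hpo_id[is.na(d$hpo_id)] <- ""
  if (any(d$source_code == "" | d$icd_code == ""))
    stop("dictionary rows must carry a non-empty source_code and icd_code")

  mapped <- d[d$hpo_id != "", , drop = FALSE]
  bad <- setdiff(unique(mapped$hpo_id),
                 c(graph$terms, names(graph$alt_ids)))
  if (length(bad))
    stop("dictionary maps to term id(s) absent from the ontology: ",
         paste(bad, collapse = ", "))
  mapped$hpo_id <- resolve_term(graph, mapped$hpo_id)

  dup <- duplicated(mapped[c("source_code", "hpo_id")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (source_code, term) dictionary row(s) collapsed")
    mapped <- mapped[!dup, , drop = FALSE]
  }
  rownames(mapped) <- NULL

  unmapped <- setdiff(unique(d$source_code[d$hpo_id == ""]),
                      unique(mapped$source_code))
  icd <- d$icd_code[!duplicated(d$source_code)]
  names(icd) <- d$source_code[!duplicated(d$source_code)]

  structure(list(entries = mapped, unmapped = unmapped, icd = icd),
            class = "diagnosis_dictionary")
}

#' @export
print.diagnosis_dictionary <- function(x, ...) {
  cat("<diagnosis_dictionary> ", length(unique(x$entries$source_code)),
      " mapped codes -> ", length(unique(x$entries$hpo_id)), " terms; ",
      length(x$unmapped), " explicitly unmappable code(s)\n", sep = "")
  invisible(x)
}

# ICD-10 letter + two-digit prefix ranges retained as neurology-related,
# plus single codes matched as themselves or dotted extensions, plus one
# exact code. ICD-9 or site-specific additions go through `extra_codes`.
.neuro_ranges <- data.frame(
  letter = c("F", "G", "Q", "R", "R"),
  lo = c(0L, 0L, 0L, 25L, 40L),
  hi = c(99L, 99L, 7L, 29L, 49L)
)
.neuro_prefix_codes <- c("P90", "R56", "R62", "R90")
.neuro_exact_codes <- "R94.01"

#' Neurology ICD-code filter
#'
#' Keeps diagnosis rows whose ICD-10 code falls in the neurology-related
#' selection F00-F99, G00-G99, P90, Q00-Q07, R25-R29, R40-R49, R56, R62,
#' R90 or R94.01. Ranges are evaluated on the letter plus first two digits;
#' the single codes P90, R56, R62 and R90 also match any dotted extension
#' (e.g. \code{R56.00}); R94.01 matches exactly. Unparseable codes return
#' \code{FALSE}.
#'
#' @param icd Character vector of ICD code strings.
#' @param extra_codes Optional character vector of additional codes (e.g.
#'   ICD-9) accepted verbatim or as a dotted prefix.
#' @return Logical vector, one element per code.
#' @export
neurology_filter <- function(icd, extra_codes = character()) {
  icd <- trimws(toupper(as.character(icd)))
  out <- logical(length(icd))

  m <- regmatches(icd, regexec("^([A-Z])([0-9]{2})", icd))
  for (i in seq_along(icd)) {
    code <- icd[i]
    if (code %in% .neuro_exact_codes ||
        code %in% .neuro_prefix_codes ||
        any(startsWith(code, paste0(.neuro_prefix_codes, ".")))) {
      out[i] <- TRUE
      next
    }
    if (length(extra_codes) &&
        (code %in% extra_codes || any(startsWith(code, paste0(extra_codes, "."))))) {
      out[i] <- TRUE
      next
    }
    mm <- m[[i]]
    if (length(mm) == 3L) {
      num <- as.integer(mm[3L])
      hit <- .neuro_ranges$letter == mm[2L] &
             .neuro_ranges$lo <= num & num <= .neuro_ranges$hi
      out[i] <- any(hit)
    }
  }
  out
}

#' Map raw encounter rows to ontology terms
#'
#' Applies the neurology ICD filter and the diagnosis dictionary to a raw
#' encounter table, producing one row per (individual, age, term). Rows
#' failing the ICD filter and rows whose source code has no dictionary
#' mapping are dropped (counted in the attached drop summary). Diagnosis-
#' and problem-list provenance is merged: a \code{list_type} column, if
#' present, is ignored downstream, and duplicate (individual, age, term)
#' combinations collapse to one row.
#'
#' @param raw data.frame with columns \code{individual_id},
#'   \code{age_years}, \code{source_code}, \code{icd_code} (and optionally
#'   \code{list_type}).
#' @param dict A \code{diagnosis_dictionary}.
#' @param extra_codes Passed to [neurology_filter()].
#' @return data.frame (individual_id, age_years, term) with attribute
#'   \code{"drops"}: a named integer vector counting rows removed by the
#'   ICD filter and by missing mappings.
#' @export
map_encounters <- function(raw, dict, extra_codes = character()) {
  stopifnot(inherits(dict, "diagnosis_dictionary"))
  need <- c("individual_id", "age_years", "source_code", "icd_code")
  if (!all(need %in% names(raw)))
    stop("encounter table must have columns: ", paste(need, collapse = ", "))
  if (any(raw$age_years < 0)) stop("negative encounter age")

  keep <- neurology_filter(raw$icd_code, extra_codes)
  n_icd_dropped <- sum(!keep)
  raw <- raw[keep, , drop = FALSE]

  idx <- split(seq_len(nrow(dict$entries)), dict$entries$source_code)
  has_map <- raw$source_code %in% names(idx)
  n_unmapped_dropped <- sum(!has_map)
  raw <- raw[has_map, , drop = FALSE]

  if (nrow(raw)) {
    reps <- lengths(idx[raw$source_code])
    out <- data.frame(
      individual_id = rep(raw$individual_id, reps),
      age_years = rep(raw$age_years, reps),
      term = dict$entries$hpo_id[unlist(idx[raw$source_code], use.names = FALSE)],
      stringsAsFactors = FALSE
    )
    out <- out[!duplicated(out), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(individual_id = character(), age_years = numeric(),
                      term = character(), stringsAsFactors = FALSE)
  }
  attr(out, "drops") <- c(icd_filter = n_icd_dropped,
                          unmapped_code = n_unmapped_dropped)
  out
}
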