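#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value under the hypergeometric null with fixed
#' margins, using the minimum-likelihood convention: the sum of point
#' probabilities of all tables whose probability does not exceed that of
#' the observed table (relative tolerance 1 + 1e-7 on the comparison). A
#' zero margin leaves a single possible table and returns 1.
#'
#' @param a,b,c_,d Non-negative counts: carriers with the term present,
#'   carriers without it, non-carriers with it, non-carriers without it.
#' @return A p-value in (0, 1].
#' @export
fisher_two_sided <- function(a, b, c_, d) {
  stopifnot(a >= 0, b >= 0, c_ >= 0, d >= 0)
  m <- a + b      # carriers
  n <- c_ + d     # non-carriers
  k <- a + c_     # individuals with the term present
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  x <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

#' Gene-phenotype contingency table at one bin
#'
#' Counts are restricted to individuals informative at the bin (usage
#' window intersects it). Carriers are individuals whose causative gene
#' equals \code{gene}; everyone else informative at the bin — including
#' individuals with no genetic diagnosis — forms the comparison group.
#'
#' @param tensor A \code{presence_tensor}.
#' @param genotypes data.frame (individual_id, gene); \code{"none"} marks
#'   no genetic diagnosis.
#' @param gene Gene symbol under test.
#' @param term Term id.
#' @param bin 0-based bin index.
#' @return Named integer vector \code{c(a, b, c, d)}.
#' @export
contingency_at_bin <- function(tensor, genotypes, gene, term, bin) {
  stopifnot(inherits(tensor, "presence_tensor"),
            bin >= 0, bin < tensor$grid$n_bins)
  carrier <- carrier_mask(tensor, genotypes, gene)
  inf <- tensor$informative[, bin + 1L]
  pres <- if (term %in% tensor$terms) tensor$present[, bin + 1L, term]
          else rep(FALSE, length(tensor$individuals))
  a <- sum(inf & carrier & pres)
  b <- sum(inf & carrier & !pres)
  c_ <- sum(inf & !carrier & pres)
  d <- sum(inf & !carrier & !pres)
  c(a = a, b = b, c = c_, d = d)
}

# Logical mask over tensor$individuals marking carriers of `gene`.
carrier_mask <- function(tensor, genotypes, gene) {
  g <- genotypes$gene[match(tensor$individuals, genotypes$individual_id)]
  g[is.na(g)] <- "none"
  g == gene
}

#' Scan one gene-phenotype pair across all bins
#'
#' Computes the two-sided Fisher p-value independently at every bin with
#' at least one informative carrier (no information flows between time
#' points); bins without an informative carrier contribute no p-value. The
#' most significant bin defines \code{p_gxp_max}, the pair's summary
#' p-value; ties are broken by the earliest bin.
#'
#' @inheritParams contingency_at_bin
#' @param term Term id; a term never present yields p = 1 at every
#'   testable bin.
#' @return List with \code{gene}, \code{term}, \code{p_by_bin} (numeric
#'   vector, \code{NA} where untestable), \code{p_gxp_max},
#'   \code{argmax_bin} (0-based), and \code{table} (counts a, b, c, d at
#'   the argmax bin).
#' @export
scan_pair <- function(tensor, genotypes, gene, term) {
  stopifnot(inherits(tensor, "presence_tensor"))
  carrier <- carrier_mask(tensor, genotypes, gene)
  if (!any(carrier)) stop("gene ", gene, " has no carriers in the cohort")

  n_bins <- tensor$grid$n_bins
  pres <- if (term %in% tensor$terms)
            matrix(tensor$present[, , term], nrow = length(tensor$individuals))
          else matrix(FALSE, length(tensor$individuals), n_bins)

  inf_c <- colSums(tensor$informative[carrier, , drop = FALSE])
  inf_n <- colSums(tensor$informative[!carrier, , drop = FALSE])
  a_vec <- colSums(pres[carrier, , drop = FALSE])
  c_vec <- colSums(pres[!carrier, , drop = FALSE])

  p <- rep(NA_real_, n_bins)
  testable <- inf_c >= 1L
  for (j in which(testable))
    p[j] <- fisher_two_sided(a_vec[j], inf_c[j] - a_vec[j],
                             c_vec[j], inf_n[j] - c_vec[j])

  if (!any(testable)) {
    p_max <- NA_real_; arg <- NA_integer_
  } else {
    p_max <- min(p[testable])
    arg <- which(p == p_max)[1L] - 1L    # earliest bin on ties
  }
  tab <- if (is.na(arg)) c(a = NA_integer_, b = NA_integer_,
                           c = NA_integer_, d = NA_integer_)
         else c(a = a_vec[arg + 1L], b = inf_c[arg + 1L] - a_vec[arg + 1L],
                c = c_vec[arg + 1L], d = inf_n[arg + 1L] - c_vec[arg + 1L])
  list(gene = gene, term = term, p_by_bin = p,
       p_gxp_max = p_max, argmax_bin = arg, table = tab)
}

#' Time-resolved gene-phenotype association study
#'
#' The core fitting function. For every causative gene carried by at least
#' \code{min_carriers} individuals and every observed non-modifier
#' phenotype term, the term's frequency among informative carriers is
#' compared with the remainder of the cohort at each age bin by a
#' two-sided Fisher exact test; the most significant bin per pair defines
#' \code{p_gxp_max}, and the Benjamini-Hochberg procedure at FDR
#' \code{fdr_q} is applied across the family of per-pair \code{p_gxp_max}
#' values.
#'
#' @param tensor A \code{presence_tensor} from [build_presence()].
#' @param genotypes data.frame (individual_id, gene); gene \code{"none"}
#'   marks no genetic diagnosis and is never tested.
#' @param graph The \code{ontology_graph} (for modifier-branch tests and
#'   term names).
#' @param min_carriers Minimum carriers for a gene to be tested
#'   (default 2).
#' @param fdr_q False-discovery rate for the BH correction (default 0.05).
#' @param modifier_roots Term ids rooting the modifier branches excluded
#'   from testing; default [default_modifier_roots()], silently reduced to
#'   the roots present in \code{graph}.
#' @return Object of class \code{gxp_scan}: list with \code{results} (a
#'   data.frame ranked by \code{p_gxp_max}: gene, term, term_name,
#'   argmax_bin, argmax_age_years, p_gxp_max, neg_log10_p, p_adjusted,
#'   counts a/b/c/d and n_carriers at the argmax bin, nominal and
#'   bh_significant flags), \code{p_trajectories} (named list of per-bin
#'   p-value vectors, one per tested pair), \code{grid} and \code{params}.
#' @seealso [scan_pair()], [summary.gxp_scan()], [plot.gxp_scan()]
#' @export
gxp_scan <- function(tensor, genotypes, graph,
                     min_carriers = 2, fdr_q = 0.05,
                     modifier_roots = default_modifier_roots()) {
  stopifnot(inherits(tensor, "presence_tensor"),
            inherits(graph, "ontology_graph"),
            min_carriers >= 1, fdr_q > 0, fdr_q < 1)

  g <- genotypes$gene[match(tensor$individuals, genotypes$individual_id)]
  g[is.na(g)] <- "none"
  counts <- table(g[g != "none"])
  genes <- sort(names(counts)[counts >= min_carriers])

  modifier_roots <- intersect(modifier_roots,
                              c(graph$terms, names(graph$alt_ids)))
  is_mod <- vapply(tensor$terms, function(t)
    length(modifier_roots) > 0 && in_branch(graph, t, modifier_roots),
    logical(1))
  terms <- tensor$terms[!is_mod]

  if (!length(genes) || !length(terms)) {
    warning("empty test family: no gene meets min_carriers or no testable term")
    res <- data.frame(gene = character(), term = character())
    return(structure(list(results = res, p_trajectories = list(),
                          grid = tensor$grid,
                          params = list(min_carriers = min_carriers,
                                        fdr_q = fdr_q,
                                        modifier_roots = modifier_roots)),
                     class = "gxp_scan"))
  }

  pairs <- expand.grid(gene = genes, term = terms,
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  scans <- mapply(function(gn, tm) scan_pair(tensor, genotypes, gn, tm),
                  pairs$gene, pairs$term, SIMPLIFY = FALSE)

  p_max <- vapply(scans, `[[`, numeric(1), "p_gxp_max")
  defined <- !is.na(p_max)
  scans <- scans[defined]; pairs <- pairs[defined, , drop = FALSE]
  p_max <- p_max[defined]

  p_adj <- stats::p.adjust(p_max, method = "BH")
  tabs <- t(vapply(scans, `[[`, numeric(4), "table"))
  arg <- vapply(scans, `[[`, numeric(1), "argmax_bin")

  res <- data.frame(
    gene = pairs$gene,
    term = pairs$term,
    term_name = unname(graph$names[pairs$term]),
    argmax_bin = as.integer(arg),
    argmax_age_years = arg * tensor$grid$bin_width,
    p_gxp_max = p_max,
    neg_log10_p = -log10(p_max),
    p_adjusted = p_adj,
    a = as.integer(tabs[, 1L]), b = as.integer(tabs[, 2L]),
    c = as.integer(tabs[, 3L]), d = as.integer(tabs[, 4L]),
    n_carriers = as.integer(counts[pairs$gene]),
    nominal = p_max < 0.05,
    bh_significant = p_adj <= fdr_q,
    stringsAsFactors = FALSE
  )
  ord <- order(res$p_gxp_max, res$gene, res$term)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL

  traj <- lapply(scans, `[[`, "p_by_bin")
  names(traj) <- paste(pairs$gene, pairs$term, sep = "|")
  traj <- traj[ord]

  structure(list(results = res, p_trajectories = traj, grid = tensor$grid,
                 params = list(min_carriers = min_carriers, fdr_q = fdr_q,
                               modifier_roots = modifier_roots)),
            class = "gxp_scan")
}

#' @export
print.gxp_scan <- function(x, n = 6L, ...) {
  r <- x$results
  cat("<gxp_scan> ", nrow(r), " gene-phenotype pairs tested over ",
      x$grid$n_bins, " bins of ", x$grid$bin_width, " y\n", sep = "")
  if (nrow(r)) {
    cat(sum(r$nominal), " nominally significant (p_gxp_max < 0.05), ",
        sum(r$bh_significant), " BH-significant at q = ",
        x$params$fdr_q, "\n\n", sep = "")
    cols <- c("gene", "term", "term_name", "argmax_age_years",
              "p_gxp_max", "bh_significant")
    print(utils::head(r[cols], n))
  }
  invisible(x)
}

#' Summarize an association scan
#'
#' @param object A \code{gxp_scan}.
#' @param ... Unused.
#' @return The object, invisibly, after printing the test-family size,
#'   nominal and BH-significant counts, and the BH-significant pairs.
#' @export
summary.gxp_scan <- function(object, ...) {
  r <- object$results
  cat("Time-resolved gene-phenotype association scan\n")
  cat("  pairs tested:      ", nrow(r), "\n")
  cat("  nominal (p<0.05):  ", sum(r$nominal), "\n")
  cat("  BH-significant (q=", object$params$fdr_q, "): ",
      sum(r$bh_significant), "\n", sep = "")
  sig <- r[r$bh_significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("\nSignificant associations:\n")
    print(sig[c("gene", "term", "term_name", "argmax_age_years",
                "p_gxp_max", "p_adjusted")], row.names = FALSE)
  }
  invisible(object)
}

#' @export
as.data.frame.gxp_scan <- function(x, ...) x$results

#' Plot p-value trajectories of top associations
#'
#' Draws \eqn{-\log_{10} p} against bin start age for the \code{n_top}
#' most significant pairs (or a chosen set of \code{"gene|term"} keys),
#' the time-course view of an association.
#'
#' @param x A \code{gxp_scan}.
#' @param n_top Number of top-ranked pairs to draw (default 4).
#' @param pairs Optional character vector of \code{"gene|term"} keys
#'   overriding \code{n_top}.
#' @param ... Passed to \code{matplot}.
#' @return Invisibly, the matrix of plotted \eqn{-\log_{10} p} values.
#' @export
plot.gxp_scan <- function(x, n_top = 4L, pairs = NULL, ...) {
  keys <- if (!is.null(pairs)) pairs else utils::head(names(x$p_trajectories), n_top)
  keys <- intersect(keys, names(x$p_trajectories))
  if (!length(keys)) stop("no pairs to plot")
  m <- sapply(x$p_trajectories[keys], function(p) -log10(p))
  ages <- (seq_len(x$grid$n_bins) - 1L) * x$grid$bin_width
  graphics::matplot(ages, m, type = "l", lty = 1, lwd = 2,
                    xlab = "age (years)",
                    ylab = expression(-log[10] ~ p), ...)
  graphics::legend("topright", legend = keys, lty = 1, lwd = 2,
                   col = seq_along(keys), cex = 0.8, bty = "n")
  invisible(m)
}
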