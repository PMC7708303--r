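# Shared fixtures: the packaged mini ontology and dictionary, loaded once.
fixture_graph <- function() {
  load_ontology(system.file("extdata", "mini_hp.obo", package = "emrpheno"))
}

fixture_dict <- function(graph = fixture_graph()) {
  load_dictionary(system.file("extdata", "fixture_dictionary.tsv",
                              package = "emrpheno"), graph)
}

# Independent brute-force ancestor closure: repeated direct-parent
# expansion until a fixed point, root excluded.
brute_ancestors <- function(graph, term, include_self = FALSE) {
  out <- character(0)
  frontier <- term
  repeat {
    parents <- unique(unlist(graph$parents[frontier], use.names = FALSE))
    parents <- setdiff(parents, out)
    if (!length(parents)) break
    out <- c(out, parents)
    frontier <- parents
  }
  out <- setdiff(out, graph$roots)
  if (include_self) out <- unique(c(term, out))
  sort(out)
}

# Independent Benjamini-Hochberg step-up: reject the k smallest p-values
# where k is the largest index with p(k) <= k * q / m.
brute_bh_reject <- function(p, q) {
  m <- length(p)
  if (!m) return(logical(0))
  ord <- order(p)
  ps <- p[ord]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * q / m)))
  rej <- logical(m)
  if (is.finite(k)) rej[ord[seq_len(k)]] <- TRUE
  rej
}

# Independent two-sided Fisher p by explicit enumeration with binomial
# coefficients (no dhyper).
brute_fisher <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  xs <- max(0, k - n):min(k, m)
  tot <- choose(m + n, k)
  probs <- choose(m, xs) * choose(n, k - xs) / tot
  p_obs <- choose(m, a) * choose(n, k - a) / tot
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Small deterministic cohort pieces for temporal/association unit tests.
tiny_windows <- function(ids, lo, hi) {
  data.frame(individual_id = ids, min_age = lo, max_age = hi,
             stringsAsFactors = FALSE)
}

tiny_mapped <- function(ids, ages, terms) {
  data.frame(individual_id = ids, age_years = ages, term = terms,
             stringsAsFactors = FALSE)
}
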