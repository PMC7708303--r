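test_that("two-sided Fisher p matches hand enumeration on known tables", {
  # margins 3/5, observed diagonal table: only the observed table has
  # probability <= its own, so p = C(3,3)C(5,0)/C(8,3) = 1/56
  expect_equal(fisher_two_sided(3, 0, 0, 5), 1 / 56, tolerance = 1e-12)
  expect_identical(fisher_two_sided(0, 10, 0, 10), 1)   # zero margin
  expect_identical(fisher_two_sided(0, 0, 5, 5), 1)
  expect_equal(fisher_two_sided(2, 3, 4, 1),
               stats::fisher.test(matrix(c(2, 3, 4, 1), 2, byrow = TRUE))$p.value,
               tolerance = 1e-9)
})

test_that("Fisher implementation equals enumeration and fisher.test on random tables", {
  set.seed(123)
  for (i in 1:150) {
    N <- sample(4:60, 1)
    a <- sample(0:N, 1); b <- sample(0:(N - a), 1)
    c_ <- sample(0:(N - a - b), 1); d <- N - a - b - c_
    p <- fisher_two_sided(a, b, c_, d)
    expect_equal(p, brute_fisher(a, b, c_, d), tolerance = 1e-12,
                 info = paste(a, b, c_, d))
    expect_equal(p, stats::fisher.test(matrix(c(a, c_, b, d), 2))$p.value,
                 tolerance = 1e-7, info = paste(a, b, c_, d))
    expect_gt(p, 0); expect_lte(p, 1)
  }
})

test_that("two-sided p shrinks as the planted enrichment grows", {
  bg <- c(5, 45)   # comparison group: 10% presence
  p_prev <- Inf
  for (k in 3:10) {
    p <- fisher_two_sided(k, 10 - k, bg[1], bg[2])
    expect_lte(p, p_prev)
    p_prev <- p
  }
})

test_that("contingency tables partition the informative individuals", {
  g <- fixture_graph()
  co <- generate_cohort(planted_demo_config(120, seed = 5))
  m <- map_encounters(co$encounters, fixture_dict(g))
  tn <- build_presence(m, g, bin_grid(), usage_windows(co$encounters))
  for (b in c(0, 3, 40)) {
    tab <- contingency_at_bin(tn, co$genotypes, "SCN1A", "HP:0002133", b)
    expect_identical(sum(tab), sum(tn$informative[, b + 1L]))
  }
  # planted effect bin: carrier frequency far exceeds the background
  tab3 <- contingency_at_bin(tn, co$genotypes, "SCN1A", "HP:0002133", 3)
  expect_gt(tab3["a"] / (tab3["a"] + tab3["b"]),
            3 * tab3["c"] / (tab3["c"] + tab3["d"]))
})

test_that("scan_pair takes the most significant bin, earliest on ties", {
  g <- fixture_graph()
  # deterministic tensor: 4 individuals, 2 carriers; identical perfect
  # separation in bins 1 and 2 -> tie broken by bin 1
  mapped <- tiny_mapped(c("A", "A", "B", "B"), c(0.3, 0.6, 0.3, 0.6),
                        rep("HP:0002133", 4))
  w <- tiny_windows(c("A", "B", "C", "D"), 0, c(1, 1, 1, 1))
  tn <- build_presence(mapped, g, bin_grid(), w)
  geno <- data.frame(individual_id = c("A", "B", "C", "D"),
                     gene = c("SCN1A", "SCN1A", "none", "none"))
  s <- scan_pair(tn, geno, "SCN1A", "HP:0002133")
  expect_identical(s$argmax_bin, 1L)
  expect_equal(s$p_gxp_max, fisher_two_sided(2, 0, 0, 2), tolerance = 1e-12)
  expect_equal(min(s$p_by_bin, na.rm = TRUE), s$p_gxp_max)

  # a term never present: p = 1 at every testable bin
  s0 <- scan_pair(tn, geno, "SCN1A", "HP:0007018")
  expect_true(all(s0$p_by_bin[!is.na(s0$p_by_bin)] == 1))
  expect_identical(s0$p_gxp_max, 1)

  expect_error(scan_pair(tn, geno, "NOGENE", "HP:0002133"), "no carriers")
})

test_that("untestable bins contribute no p-value", {
  g <- fixture_graph()
  mapped <- tiny_mapped(c("A", "B"), c(0.1, 5.0),
                        c("HP:0002133", "HP:0002133"))
  w <- tiny_windows(c("A", "B"), c(0, 4), c(1, 6))
  geno <- data.frame(individual_id = c("A", "B"),
                     gene = c("SCN1A", "none"))
  tn <- build_presence(mapped, g, bin_grid(), w)
  s <- scan_pair(tn, geno, "SCN1A", "HP:0002133")
  # bins where the only carrier has no usage are undefined, not p = 1
  expect_true(all(is.na(s$p_by_bin[10:15])))
  expect_false(is.na(s$p_by_bin[1]))
})

test_that("BH step-up matches the naive oracle and the textbook example", {
  expect_identical(brute_bh_reject(c(0.001, 0.01, 0.03, 0.04), 0.05),
                   rep(TRUE, 4))
  expect_identical(p.adjust(c(0.001, 0.01, 0.03, 0.04), "BH") <= 0.05,
                   rep(TRUE, 4))
  expect_identical(brute_bh_reject(numeric(0), 0.05), logical(0))
  set.seed(99)
  for (i in 1:200) {
    m <- sample(1:60, 1)
    p <- stats::runif(m)^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(p.adjust(p, "BH") <= q, brute_bh_reject(p, q))
  }
})

test_that("the study restricts the family and flags significance", {
  g <- fixture_graph()
  co <- generate_cohort(planted_demo_config(150, seed = 2))
  m <- map_encounters(co$encounters, fixture_dict(g))
  tn <- build_presence(m, g, bin_grid(), usage_windows(co$encounters))

  # force one singleton gene to verify the min-carriers filter
  geno <- co$genotypes
  geno$gene[match(geno$individual_id[geno$gene == "none"][1],
                  geno$individual_id)] <- "SINGLETON"
  s <- gxp_scan(tn, geno, g, min_carriers = 2)
  r <- s$results
  expect_false("SINGLETON" %in% r$gene)
  expect_false("none" %in% r$gene)
  carried <- table(geno$gene[geno$gene != "none"])
  expect_true(all(carried[unique(r$gene)] >= 2))
  # modifier-branch terms never enter the family
  expect_false(any(vapply(unique(r$term), in_branch, logical(1),
                          graph = g, branch_roots = default_modifier_roots())))
  # BH flags equal the oracle applied to the family of p_gxp_max values
  expect_identical(r$bh_significant, brute_bh_reject(r$p_gxp_max, 0.05))
  expect_identical(r$nominal, r$p_gxp_max < 0.05)
  expect_equal(r$neg_log10_p, -log10(r$p_gxp_max))
  expect_false(is.unsorted(r$p_gxp_max))
  # trajectories align with the ranked table
  expect_identical(names(s$p_trajectories),
                   paste(r$gene, r$term, sep = "|"))

  expect_warning(
    gxp_scan(tn, data.frame(individual_id = tn$individuals, gene = "none"),
             g),
    "empty test family")
})
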