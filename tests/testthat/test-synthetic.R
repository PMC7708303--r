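test_that("generation is reproducible and internally consistent", {
  cfg <- cohort_config(n_individuals = 50, seed = 42)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$encounters, c2$encounters)
  expect_identical(c1$genotypes, c2$genotypes)

  # every encounter age lies inside its individual's generated window
  tr <- c1$truth$assignments
  lo <- tr$first_age[match(c1$encounters$individual_id, tr$individual_id)]
  hi <- lo + tr$duration[match(c1$encounters$individual_id, tr$individual_id)]
  expect_true(all(c1$encounters$age_years >= lo - 1e-9))
  expect_true(all(c1$encounters$age_years <= hi + 1e-9))

  # the first/last encounters pin the window exactly
  w <- usage_windows(c1$encounters)
  tr <- tr[match(w$individual_id, tr$individual_id), ]
  expect_equal(w$min_age, tr$first_age, tolerance = 1e-9)
  expect_equal(w$max_age - w$min_age, tr$duration, tolerance = 1e-9)
})

test_that("degenerate and invalid configurations are handled", {
  co <- null_cohort(2, seed = 1)
  expect_identical(nrow(co$genotypes), 2L)
  expect_true(all(table(co$encounters$individual_id) >= 1))

  expect_error(cohort_config(n_individuals = 1), "n_individuals")
  expect_error(cohort_config(gene_freqs = c(SCN1A = 0.6, none = 0.6)),
               "summing to 1")
  expect_error(cohort_config(gene_freqs = c(SCN1A = 1)), "none")
  expect_error(
    cohort_config(effects = data.frame(gene = "SCN1A",
                                       source_code = "Status epilepticus",
                                       age_min = 0.5, age_max = 1.25,
                                       odds_ratio = -2)),
    "odds ratio")
  expect_error(
    cohort_config(effects = data.frame(gene = "SCN1A",
                                       source_code = "Status epilepticus",
                                       age_min = 10, age_max = 30,
                                       odds_ratio = 2)),
    "within")
  expect_error(
    cohort_config(effects = data.frame(gene = "SCN1A",
                                       source_code = "No such code",
                                       age_min = 0.5, age_max = 1,
                                       odds_ratio = 2)),
    "baseline")
})

test_that("carrier fractions follow the configured gene frequencies", {
  co <- generate_cohort(cohort_config(
    n_individuals = 1000,
    gene_freqs = c(GENEA = 0.5, none = 0.5), seed = 8))
  f <- mean(co$genotypes$gene == "GENEA")
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("window durations track the configured median", {
  co <- generate_cohort(cohort_config(n_individuals = 1000, seed = 31))
  dur <- with(usage_windows(co$encounters), max_age - min_age)
  expect_lt(abs(stats::median(dur) - 6.9) / 6.9, 0.10)
})

test_that("an OR=1 effect is a null: carrier and background frequencies agree", {
  # pooled 2x2 over 20 seeds must not reject the null construction
  ok <- 0L
  for (sd in 1:20) {
    cfg <- cohort_config(
      n_individuals = 200,
      gene_freqs = c(SCN1A = 0.15, none = 0.85),
      effects = data.frame(gene = "SCN1A",
                           source_code = "Status epilepticus",
                           age_min = 0.5, age_max = 1.25, odds_ratio = 1),
      seed = sd)
    co <- generate_cohort(cfg)
    carrier <- co$genotypes$gene[match(co$encounters$individual_id,
                                       co$genotypes$individual_id)] == "SCN1A"
    hit <- co$encounters$source_code == "Status epilepticus" &
           co$encounters$age_years >= 0.5 & co$encounters$age_years < 1.25
    in_win <- co$encounters$age_years >= 0.5 & co$encounters$age_years < 1.25
    tab <- c(sum(hit & carrier), sum(in_win & carrier & !hit),
             sum(hit & !carrier), sum(in_win & !carrier & !hit))
    p <- fisher_two_sided(tab[1], tab[2], tab[3], tab[4])
    if (p > 0.001) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})

test_that("written cohorts round-trip through the pipeline readers", {
  co <- generate_cohort(cohort_config(n_individuals = 20, seed = 6))
  dir <- tempfile()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  enc <- utils::read.delim(paths["encounters"], colClasses = "character")
  expect_identical(nrow(enc), nrow(co$encounters))
  truth <- jsonlite::read_json(paths["truth"])
  expect_identical(length(truth$assignments$individual_id), 20L)
})
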