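test_that("the default grid has 100 three-month bins and half-open indexing", {
  grid <- bin_grid()
  expect_identical(grid$n_bins, 100L)
  expect_error(bin_grid(0.3, 25), "integer multiple")

  expect_identical(bin_index(c(0, 0.5, 0.625, 24.99), grid),
                   c(0L, 2L, 2L, 99L))
  expect_true(is.na(bin_index(25, grid)))
  expect_error(bin_index(-0.1, grid), "negative")
})

test_that("usage windows are the min/max of encounter ages", {
  expect_identical(unname(usage_window(c(0.4, 2.0, 6.9))), c(0.4, 6.9))
  expect_identical(unname(usage_window(1.0)), c(1.0, 1.0))
  expect_error(usage_window(numeric(0)), "zero encounters")

  w <- usage_windows(data.frame(individual_id = c("b", "a", "a"),
                                age_years = c(3, 1, 2)))
  expect_identical(w$individual_id, c("a", "b"))
  expect_identical(w$min_age, c(1, 3))
  expect_identical(w$max_age, c(2, 3))
})

test_that("shared ancestors surface in the same bin for distinct encounters", {
  # two individuals, encounters at 6 and 7.5 months, distinct seizure
  # types that share Seizure as an ancestor: both present in bin 2
  g <- fixture_graph()
  mapped <- tiny_mapped(c("A", "B"), c(0.5, 0.625),
                        c("HP:0007359", "HP:0002197"))
  w <- tiny_windows(c("A", "B"), c(0.5, 0.625), c(0.5, 0.625))
  tn <- build_presence(mapped, g, bin_grid(), w)
  expect_true(tn$present["A", "2", "HP:0001250"])
  expect_true(tn$present["B", "2", "HP:0001250"])
  expect_false("HP:0000001" %in% tn$terms)   # root never propagated
  # distinct assigned terms remain distinct
  expect_true(tn$present["A", "2", "HP:0007359"])
  expect_false(tn$present["B", "2", "HP:0007359"])
})

test_that("presence states respect the usage window", {
  g <- fixture_graph()
  mapped <- tiny_mapped("A", 2.5, "HP:0001250")
  w <- tiny_windows("A", 2.0, 3.0)
  tn <- build_presence(mapped, g, bin_grid(), w)
  expect_false(tn$informative["A", "1"])     # bin 0.25-0.5: outside window
  expect_true(all(tn$informative["A", as.character(8:12)]))
  # a window touching a bin only at the bin's left edge is informative
  w1 <- tiny_windows("B", 1.0, 1.0)
  tn1 <- build_presence(tiny_mapped("B", 1.0, "HP:0001250"), g, bin_grid(), w1)
  expect_identical(sum(tn1$informative), 1L)
  expect_true(tn1$informative["B", "4"])

  expect_error(build_presence(tiny_mapped("Z", 1, "HP:0001250"), g,
                              bin_grid(), w),
               "without a usage window")
})

test_that("duplicate sources collapse and trajectories count correctly", {
  g <- fixture_graph()
  # same term reached twice in one bin (repeat encounter + convergent code)
  mapped <- tiny_mapped(c("A", "A", "B"), c(1.0, 1.1, 5.0),
                        c("HP:0002121", "HP:0002121", "HP:0002133"))
  w <- tiny_windows(c("A", "B"), c(1.0, 0.0), c(1.2, 10.0))
  tn <- build_presence(mapped, g, bin_grid(), w)
  tr <- term_trajectory(tn, "HP:0002121")
  expect_identical(tr$n_present[tr$bin == 4], 1L)

  # informative-count identity at every bin
  for (b in c(0, 4, 20, 99)) {
    row <- tr[tr$bin == b, ]
    expect_identical(row$n_informative, sum(tn$informative[, b + 1L]))
  }
  # a term never observed: all-zero presence, unchanged informative counts
  tr0 <- term_trajectory(tn, "HP:0007018")
  expect_true(all(tr0$n_present == 0L))
  expect_identical(tr0$n_informative, tr$n_informative)
})

test_that("ancestor trajectories dominate descendants at every bin", {
  co <- generate_cohort(cohort_config(n_individuals = 60, seed = 11))
  g <- fixture_graph()
  d <- fixture_dict(g)
  m <- map_encounters(co$encounters, d)
  tn <- build_presence(m, g, bin_grid(), usage_windows(co$encounters))
  for (child in tn$terms) {
    for (parent in intersect(g$parents[[child]], tn$terms)) {
      tc <- term_trajectory(tn, child)
      tp <- term_trajectory(tn, parent)
      expect_true(all(tp$n_present >= tc$n_present),
                  info = paste(child, "->", parent))
    }
  }
})

test_that("halving the bin width never loses informative coverage", {
  co <- generate_cohort(cohort_config(n_individuals = 40, seed = 3))
  g <- fixture_graph()
  d <- fixture_dict(g)
  m <- map_encounters(co$encounters, d)
  w <- usage_windows(co$encounters)
  t1 <- build_presence(m, g, bin_grid(0.25), w)
  t2 <- build_presence(m, g, bin_grid(0.125), w)
  expect_gte(sum(t2$informative), sum(t1$informative))
})

test_that("ages beyond the grid drop from binning but windows clip", {
  g <- fixture_graph()
  mapped <- tiny_mapped(c("A", "A"), c(24.9, 26.0),
                        c("HP:0001250", "HP:0001250"))
  w <- tiny_windows("A", 24.9, 26.0)
  tn <- build_presence(mapped, g, bin_grid(), w)
  expect_true(tn$present["A", "99", "HP:0001250"])
  expect_true(tn$informative["A", "99"])
  expect_identical(sum(tn$present["A", , "HP:0001250"]), 1L)
})
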