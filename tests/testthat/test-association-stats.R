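test_that("chi-square behaves at the textbook anchor points", {
  # independent rows give a zero statistic
  r <- chi_square_2x2(c(10, 90, 20, 180))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # zero marginal is undefined
  expect_error(chi_square_2x2(c(0, 0, 5, 5)), "Fisher")

  # invariance under row and column swaps
  tab <- matrix(c(12, 34, 56, 78), 2, byrow = TRUE)
  base <- chi_square_2x2(tab)$statistic
  expect_equal(chi_square_2x2(tab[2:1, ])$statistic, base)
  expect_equal(chi_square_2x2(tab[, 2:1])$statistic, base)
  expect_equal(chi_square_2x2(t(tab))$statistic, base)
})

test_that("Yates correction never increases the statistic", {
  withr::local_seed(601)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 30) + 1, 2)
    expect_lte(chi_square_2x2(tab, TRUE)$statistic,
               chi_square_2x2(tab)$statistic)
  }
})

test_that("chi-square agrees with the reference implementation on random tables", {
  withr::local_seed(602)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(c(10, 50, 300), 1)) + 1, 2)
    ours <- chi_square_2x2(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_lt(abs(ours$p_value - ref$p.value) / ref$p.value, 1e-10)
    expect_lt(abs(ours$statistic - unname(ref$statistic)) /
                unname(ref$statistic + 1e-300), 1e-10)
    ours_y <- chi_square_2x2(tab, continuity_correction = TRUE)
    ref_y <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(ours_y$p_value, ref_y$p.value, tolerance = 1e-12)
  }
})

test_that("the pooled t-test matches t.test and is antisymmetric", {
  withr::local_seed(603)
  for (i in 1:50) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(sample(5:30, 1), mean = 0.3)
    ours <- students_t_test(x, y)
    ref <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    flipped <- students_t_test(y, x)
    expect_equal(flipped$statistic, -ours$statistic)
    expect_equal(flipped$p_value, ours$p_value)
    ours_w <- students_t_test(x, y, welch = TRUE)
    ref_w <- stats::t.test(x, y)
    expect_equal(ours_w$p_value, ref_w$p.value, tolerance = 1e-12)
    expect_equal(ours_w$df, unname(ref_w$parameter), tolerance = 1e-12)
  }
})

test_that("t-test degenerate cases behave as documented", {
  x <- c(1, 2, 3)
  r <- students_t_test(x, x)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(students_t_test(c(1), c(1, 2)), "at least 2")
  expect_error(students_t_test(c(1, 1), c(2, 2)), "zero variance")
  expect_equal(students_t_test(c(1, 1), c(1, 1))$p_value, 1)
})

test_that("a planted mean shift is detected with high power", {
  withr::local_seed(604)
  # shift of 1.2 SD with n = 30 per group: power well above 95%
  hits <- 0
  reps <- 400
  for (i in seq_len(reps)) {
    x <- rnorm(30, 1.2); y <- rnorm(30)
    hits <- hits + (students_t_test(x, y)$p_value < 0.05)
  }
  expect_gte(hits / reps, 0.95)
})

test_that("over-representation ranks a planted set first and BH is monotone", {
  withr::local_seed(605)
  universe <- paste0("mir", 1:200)
  query <- paste0("mir", 1:30)
  planted <- c(paste0("mir", 1:20), paste0("mir", 150:154))
  decoys <- lapply(1:6, function(i) sample(universe, 25))
  ann <- c(list(planted = planted), setNames(decoys, paste0("decoy", 1:6)))
  ora <- set_over_representation(query, ann, universe)
  expect_equal(ora$set_name[1], "planted")
  expect_lt(ora$p_value[1], 1e-6)
  # BH: adjusted >= raw, ordering preserved
  expect_true(all(ora$p_adjusted >= ora$p_value - 1e-15))
  expect_false(is.unsorted(ora$p_value))
  expect_false(is.unsorted(ora$p_adjusted))
  # raw p matches phyper cross-check via fisher.test (one-sided)
  k <- ora$overlap[1]
  ft <- stats::fisher.test(matrix(c(k, length(intersect(planted, universe)) - k,
                                    30 - k, 200 - length(planted) - 30 + k), 2),
                           alternative = "greater")
  expect_equal(ora$p_value[1], ft$p.value, tolerance = 1e-10)
})

test_that("degenerate and disjoint ORA cases give p = 1", {
  universe <- paste0("m", 1:10)
  ann <- list(all = universe, other = paste0("x", 1:5))
  ora <- set_over_representation(universe, ann, universe)
  expect_equal(ora$p_value[ora$set_name == "all"], 1)
  ora2 <- set_over_representation(paste0("m", 1:3),
                                  list(none = paste0("m", 8:10)), universe)
  expect_equal(ora2$overlap, 0L)
  expect_equal(ora2$p_value, 1)
  expect_error(set_over_representation(character(0), ann, universe), "empty")
  expect_error(set_over_representation("zzz", ann, universe), "subset")
})

test_that("figure-style summary reports group percentages at one decimal", {
  counts <- c(30, 120, 20, 160)
  f <- figure1_summary(counts = counts)
  expect_equal(f$pct_clustered_with_snp, 25.0)
  expect_equal(f$pct_clustered_without_snp, 12.5)
  expect_equal(unname(f$table[1, ]), c(30, 90))
  expect_s3_class(f$test, "seed_test")

  # all clustered in both groups: no signal
  f2 <- figure1_summary(counts = c(10, 10, 20, 20))
  expect_equal(f2$pct_clustered_with_snp, 100)
  expect_error(figure1_summary(counts = c(0, 0, 5, 10)), "non-empty")
})
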