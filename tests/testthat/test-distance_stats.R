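tab <- fixture_tables()

test_that("accuracy follows the printed-table formula and is asymmetric", {
  expect_equal(accuracy(610.88, 616.93)$percent, 99.01)
  expect_equal(accuracy(610.88, 624.86)$percent, 97.71)
  expect_equal(accuracy(123.4, 123.4)$percent, 100)
  # not symmetric: swapping actual and estimated changes the value
  expect_false(accuracy(100, 150)$percent == accuracy(150, 100)$percent)
  expect_equal(accuracy(100, 150)$percent, 50)
  expect_equal(accuracy(150, 100)$percent, 66.67)
  expect_error(accuracy(0, 1), class = "insolestride_invalid_input")
  expect_error(accuracy(-2, 1), class = "insolestride_invalid_input")
})

test_that("median and interquartile reproduce the cohort summaries", {
  expect_equal(median_iqr(tab$distance$actual_m)$median, 609.44)
  expect_equal(median_iqr(tab$stride$actual_stride_length_m)$median, 1.591)
  expect_equal(median_iqr(7)$median, 7)
  expect_equal(median_iqr(7)$iqr, 0)
  x <- c(1, 2, 3, 4, 10)
  expect_equal(median_iqr(x, type = "spss")$iqr,
               diff(quantile(x, c(0.25, 0.75), type = 6, names = FALSE)))
  expect_equal(median_iqr(x, type = "tukey")$iqr,
               diff(fivenum(x)[c(2, 4)]))
  expect_error(median_iqr(numeric(0)), class = "insolestride_invalid_input")
})

test_that("Mann-Whitney U reproduces the verified comparisons", {
  s <- tab$stride; d <- tab$distance
  u1 <- mann_whitney_u(s$approach1_right_m, s$approach2_right_m)
  expect_equal(u1$U, 31)
  expect_equal(round(u1$p_exact, 3), 0.959)
  u2 <- mann_whitney_u(s$approach1_left_m, s$approach2_left_m)
  expect_equal(u2$U, 30)
  expect_equal(round(u2$p_exact, 3), 0.878)
  cases <- list(list(col = "gaitup_right_m", U = 25, p = 0.505),
                list(col = "gaitup_left_m", U = 27, p = 0.645),
                list(col = "approach1_left_m", U = 26, p = 0.574),
                list(col = "approach2_right_m", U = 28, p = 0.721))
  for (cs in cases) {
    u <- mann_whitney_u(d$actual_m, d[[cs$col]])
    expect_equal(u$U, cs$U)
    expect_equal(round(u$p_exact, 3), cs$p)
    expect_equal(u$U, u_pair_count(d$actual_m, d[[cs$col]]))  # oracle
  }
})

test_that("U statistics satisfy rank identities, ties and oracles", {
  x <- c(1, 2, 3)
  expect_equal(mann_whitney_u(x, x)$U, 9 / 2)     # all tied: n^2/2 midranks
  set.seed(21)
  for (i in 1:20) {
    n1 <- sample(2:9, 1); n2 <- sample(2:9, 1)
    x <- sample(1:6, n1, replace = TRUE)           # ties likely
    y <- sample(1:6, n2, replace = TRUE)
    u <- mann_whitney_u(x, y, p_mode = "normal")
    expect_equal(u$U1 + u$U2, n1 * n2)
    expect_lte(u$U, n1 * n2 / 2)
    expect_gte(u$U, 0)
  }
  # untied samples: U1 agrees with stats::wilcox.test's W
  set.seed(22)
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(mann_whitney_u(x, y)$U1,
               unname(wilcox.test(x, y)$statistic))
  # exact p agrees with full enumeration via the pair-counting oracle
  for (i in 1:3) {
    x <- rnorm(5); y <- rnorm(5)
    expect_equal(mann_whitney_u(x, y)$p_exact, exact_p_enumerate(x, y))
  }
  # exact and normal p agree within 0.05 at n1 = n2 = 8
  set.seed(23)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8, mean = runif(1, -1, 1))
    u <- mann_whitney_u(x, y)
    expect_lt(abs(u$p_exact - u$p_normal), 0.05)
  }
})

test_that("ICC forms match the ANOVA decomposition", {
  # fixed 4x2 matrix; mean squares checked against stats::aov
  m <- cbind(c(1, 3, 5, 9), c(2, 5, 6, 11))
  ms <- anova_ms(m)
  r3 <- icc(m, form = "twoway_mixed_consistency")
  expect_equal(r3$icc, (ms$MSR - ms$MSE) / (ms$MSR + ms$MSE))
  expect_equal(r3$ms$MSR, ms$MSR)
  expect_equal(r3$ms$MSE, ms$MSE)
  r2 <- icc(m, form = "twoway_random_abs")
  expect_equal(r2$icc,
               (ms$MSR - ms$MSE) /
                 (ms$MSR + ms$MSE + 2 * (ms$MSC - ms$MSE) / 4))
  expect_true(r2$ci_low < r2$icc && r2$icc < r2$ci_high)
  # duplicated column: consistency ICC is exactly 1
  dup <- cbind(c(1, 2, 4), c(1, 2, 4))
  expect_equal(icc(dup, form = "twoway_mixed_consistency")$icc, 1)
  # independent columns at large n: ICC near 0
  set.seed(31)
  big <- cbind(rnorm(200), rnorm(200))
  expect_lt(abs(icc(big)$icc), 0.3)
  # degenerate: no between-subject variance
  expect_error(icc(cbind(c(1, 1), c(1, 1))), class = "insolestride_degenerate")
  expect_error(icc(cbind(1, 2)), class = "insolestride_invalid_input")
})

test_that("ICC bands follow the interpretation thresholds", {
  expect_identical(icc_band(0.95), "excellent")
  expect_identical(icc_band(0.90), "good")
  expect_identical(icc_band(0.75), "good")
  expect_identical(icc_band(0.60), "moderate")
  expect_identical(icc_band(0.20), "poor")
})

test_that("ICC on the bundled tables stays within 1 of all invariants", {
  # frozen from an independent hand ANOVA on the printed right-side distances
  r <- icc(cbind(tab$distance$actual_m, tab$distance$approach1_right_m))
  expect_equal(r$icc, 0.9833805, tolerance = 1e-6)
  expect_identical(r$band, "excellent")
  expect_lte(r$icc, 1)
  expect_lte(r$ci_high, 1 + 1e-9)
})

test_that("the validation report assembles every layer", {
  rep <- build_validation_report(tab)
  expect_equal(rep$distance_accuracy$approach1_right[
    rep$distance_accuracy$participant == "P2"], 99.72)
  u <- rep$u_tests
  expect_equal(u$U[u$comparison == "actual_vs_approach1" & u$side == "left"],
               26)
  expect_equal(
    rep$medians$median[rep$medians$outcome == "distance" &
                       rep$medians$column == "actual"], 609.44)
  expect_true(all(u$U >= 0 & u$U <= 64))
  expect_true(all(rep$icc$icc <= 1))
  # degenerate world: all estimates equal the actual outcome
  s2 <- tab$stride; d2 <- tab$distance
  for (cl in grep("_m$", names(s2), value = TRUE)) {
    s2[[cl]] <- s2$actual_stride_length_m
  }
  for (cl in setdiff(grep("_m$", names(d2), value = TRUE), "actual_m")) {
    d2[[cl]] <- d2$actual_m
  }
  rep2 <- build_validation_report(participant_table(s2, d2))
  expect_true(all(as.matrix(rep2$distance_accuracy[-1]) == 100))
  expect_true(all(rep2$u_tests$U == 32))         # n^2/2 under full ties
  expect_true(all(rep2$icc$icc == 1))
})
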