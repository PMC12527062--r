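test_that("swing slope is the OLS line slope", {
  for (fs in c(40, 100)) {
    tt <- (0:30) / fs
    expect_equal(swing_slope(2 * tt + 1, fs), 2)
  }
  expect_equal(swing_slope(rep(3, 10), 40), 0)
  set.seed(5)
  tt <- (0:39) / 40
  y <- 2 * tt + 1 + rnorm(40, 0, 0.01)
  s <- swing_slope(y, 40)
  expect_equal(s, unname(coef(lm(y ~ tt))[2]))   # closed-form OLS oracle
  expect_lt(abs(s - 2) / 2, 0.05)
  expect_error(swing_slope(1, 40), class = "insolestride_invalid_input")
})

test_that("approach 1 ratios: identity, scaling and averaging", {
  model <- analytic_reference_model(1.5, 1.0, sample_rate = 40)
  swing <- model_swing_acceleration(model, sample_rate = 40)
  # identity: insole swing == model swing on the model grid
  est <- approach1_stride_length(make_cycles(list(swing), 1.0, 40), model)
  expect_equal(est$mean_R, 1, tolerance = 1e-12)
  expect_equal(est$stride_length_L, 1.5, tolerance = 1e-12)
  expect_equal(est$stride_length_L, model$model_stride_Px * est$mean_R)
  # amplitude scaling k = 1.3 transfers to the length by OLS linearity
  est2 <- approach1_stride_length(make_cycles(list(1.3 * swing), 1.0, 40), model)
  expect_equal(est2$stride_length_L, 1.3 * 1.5, tolerance = 1e-12)
  # mean of per-cycle ratios 0.9 and 1.1 -> L = Px
  est3 <- approach1_stride_length(
    make_cycles(list(0.9 * swing, 1.1 * swing), 1.0, 40), model)
  expect_equal(est3$per_cycle_values, c(0.9, 1.1), tolerance = 1e-12)
  expect_equal(est3$stride_length_L, 1.5, tolerance = 1e-12)
  expect_equal(est3$n_cycles, 2L)
})

test_that("approach 1 invariances: offset, scaling equivariance, conventions", {
  model <- analytic_reference_model(1.5, 1.0, sample_rate = 40)
  swing <- model_swing_acceleration(model, sample_rate = 40)
  base <- approach1_stride_length(make_cycles(list(swing), 1, 40), model)
  set.seed(7)
  for (i in 1:5) {
    off <- rnorm(1, 0, 5)
    k <- runif(1, 0.5, 2)
    sh <- approach1_stride_length(make_cycles(list(swing + off), 1, 40), model)
    sc <- approach1_stride_length(make_cycles(list(k * swing), 1, 40), model)
    expect_equal(sh$stride_length_L, base$stride_length_L, tolerance = 1e-10)
    expect_equal(sc$stride_length_L, k * base$stride_length_L,
                 tolerance = 1e-10)
  }
  inv <- approach1_stride_length(make_cycles(list(swing), 1, 40), model,
                                 ratio_convention = "model_over_insole")
  expect_equal(inv$mean_R, 1, tolerance = 1e-12)
  # degenerate inputs
  expect_error(
    approach1_stride_length(make_cycles(list(swing), 1, 40),
                            analytic_reference_model(0, 1)),
    class = "insolestride_degenerate")
  expect_warning(
    z <- approach1_stride_length(make_cycles(list(rep(1, 10)), 1, 40), model),
    class = "insolestride_zero_slope")
  expect_equal(z$per_cycle_values, 0)
})

test_that("time normalization makes the ratio cadence-invariant", {
  model <- analytic_reference_model(1.0, 1.0, sample_rate = 40)
  # a walker with the same stride length but a faster cadence (T = 0.8 s)
  walker <- analytic_reference_model(1.0, 0.8, sample_rate = 40)
  swing <- model_swing_acceleration(walker, sample_rate = 40)
  cyc <- make_cycles(list(swing), 0.8, 40)
  est <- approach1_stride_length(cyc, model)
  expect_equal(est$stride_length_L, 1.0, tolerance = 1e-12)
  # the literal un-normalized ratio conflates length and cadence
  lit <- approach1_stride_length(cyc, model, time_normalize = FALSE)
  expect_equal(lit$stride_length_L, 1.0 / 0.8^3, tolerance = 1e-12)
})

test_that("dtw distance matches hand-derived and enumeration oracles", {
  expect_identical(dtw_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(dtw_distance(c(1, 2, 3), c(2, 3, 4)), 2)
  expect_identical(dtw_distance(0, 5), 5)
  set.seed(13)
  for (i in 1:25) {
    a <- round(rnorm(sample(1:6, 1)), 2)
    b <- round(rnorm(sample(1:6, 1)), 2)
    d <- dtw_distance(a, b)
    expect_equal(d, dtw_enumerate(a, b))
    expect_equal(d, dtw_distance(b, a))                  # symmetry
    # never exceeds the diagonal-then-edge path cost
    n <- length(a); m <- length(b)
    diag_cost <- sum(abs(a[seq_len(min(n, m))] - b[seq_len(min(n, m))]))
    edge_cost <- if (n > m) sum(abs(a[(m + 1):n] - b[m]))
                 else if (m > n) sum(abs(b[(n + 1):m] - a[n])) else 0
    expect_lte(d, diag_cost + edge_cost + 1e-12)
  }
  expect_error(dtw_distance(numeric(0), 1),
               class = "insolestride_invalid_input")
  # variants stay coherent
  expect_equal(dtw_distance(c(0, 1), c(0, 1), local_cost = "squared"), 0)
  expect_lte(dtw_distance(c(1, 2, 3), c(2, 3, 4), path_normalize = TRUE),
             dtw_distance(c(1, 2, 3), c(2, 3, 4)))
})

test_that("scaling coefficient implements S = 1/||A|| with selectable norm", {
  expect_equal(scaling_coefficient(c(2, -2, 2, -2)), 0.5)
  expect_equal(scaling_coefficient(1), 1.0)
  expect_equal(scaling_coefficient(c(3, 4), norm = "euclidean"), 1 / 5)
  expect_equal(scaling_coefficient(c(3, -4), norm = "max_abs"), 1 / 4)
  expect_error(scaling_coefficient(c(0, 0, 0)),
               class = "insolestride_degenerate")
})

test_that("approach 2 composes DTW, scaling and the model stride", {
  model <- analytic_reference_model(1.0, 1.0, sample_rate = 10)
  mswing <- model_swing_acceleration(model, sample_rate = 10)  # 6 samples
  # identical swing: degenerate similarity, L = 0 by construction
  expect_warning(
    e0 <- approach2_stride_length(make_cycles(list(mswing), 1, 10), model),
    class = "insolestride_degenerate_similarity")
  expect_equal(e0$per_cycle_values, 0)
  expect_equal(e0$E, 0)
  expect_equal(e0$stride_length_L, 0)
  # constant offset: expected values from the enumeration oracle + Eq. chain
  ins <- mswing + 2
  est <- approach2_stride_length(make_cycles(list(ins), 1, 10), model)
  d_expected <- dtw_enumerate(mswing, ins)
  expect_equal(est$per_cycle_values, d_expected)
  expect_equal(est$scaling_S, 1 / mean(abs(ins)))
  expect_equal(est$E, d_expected / mean(abs(ins)))
  expect_equal(est$stride_length_L, model$model_stride_Px * est$E,
               tolerance = 1e-12)
  # linearity: scaling every d_i by 2 (same S) doubles E and L
  expect_equal(2 * est$E, mean(2 * est$per_cycle_values) * est$scaling_S)
  # monotonicity in the per-cycle distances at fixed S
  ins_far <- mswing + 4
  d_far <- dtw_enumerate(mswing, ins_far)
  expect_gt(d_far, d_expected)
  expect_gt(d_far * est$scaling_S, est$E)
  # degenerate: all-zero swing
  expect_error(
    suppressWarnings(
      approach2_stride_length(make_cycles(list(rep(0, 6)), 1, 10), model)),
    class = "insolestride_degenerate")
  # per-cycle S variant runs and stays non-negative
  est_pc <- approach2_stride_length(make_cycles(list(ins, ins + 1), 1, 10),
                                    model, pooled_S = FALSE)
  expect_gte(est_pc$stride_length_L, 0)
})

test_that("total distance is L x Ns at table precision", {
  expect_equal(as.numeric(total_distance(1.681, 367)), 616.93)
  expect_equal(as.numeric(total_distance(1.800, 413)), 743.40)
  expect_equal(as.numeric(total_distance(0, 12)), 0)
  expect_equal(attr(total_distance(1.5, 3), "raw"), 4.5)
  expect_error(total_distance(-1, 10), class = "insolestride_invalid_parameter")
  expect_error(total_distance(1, 2.5), class = "insolestride_invalid_parameter")
})

test_that("estimate export writes the documented schema", {
  model <- analytic_reference_model(1.5, 1.0, sample_rate = 40)
  swing <- model_swing_acceleration(model, sample_rate = 40)
  est <- approach1_stride_length(make_cycles(list(swing), 1, 40), model)
  path <- withr::local_tempfile(fileext = ".csv")
  write_estimates_csv(list(est), 100, path, sides = "right")
  df <- read.csv(path)
  expect_named(df, c("method", "side", "n_cycles", "mean_R_or_E",
                     "stride_length_m", "total_distance_m"))
  expect_equal(df$total_distance_m, 150)
})
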