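test_that("moving-average smoothing preserves constants, ramps, and mass", {
  expect_equal(smooth_trace(rep(2.5, 50)), rep(2.5, 50))
  imp <- c(rep(0, 30), 1, rep(0, 30))
  sm <- smooth_trace(imp, span = 15)
  expect_equal(sm[24:38], rep(1 / 15, 15))
  expect_equal(sum(sm[20:42]), 1)
  ramp <- seq(0, 5, length.out = 101)
  expect_equal(smooth_trace(ramp)[8:94], ramp[8:94])
  expect_error(smooth_trace(ramp, span = 0), "span")
})

make_saccade_trace <- function(amplitude = 10, duration = 36,
                               onset = 150, noise_sd = 0.05,
                               n = 800, seed = 1) {
  t <- seq(-200, n - 201, 1)
  fix <- c(0, amplitude)
  xy <- saccpop:::eye_trajectory(t, fix, c(0, 0), onset, onset + duration,
                                 "regular", 0, NA)
  set.seed(seed)
  cbind(t = t, xy + matrix(rnorm(2 * length(t), 0, noise_sd), ncol = 2))
}

test_that("double velocity criterion finds saccades and rejects slow traces", {
  # fixation-only noise: no event
  t <- seq(-200, 500, 1)
  set.seed(2)
  fixtr <- cbind(t = t, x = rnorm(length(t), 0, 0.05),
                 y = 7 + rnorm(length(t), 0, 0.05))
  expect_null(detect_saccade(fixtr))
  # clean 10 deg, 36 ms saccade: timing recovered within +/-3 ms
  errs <- sapply(1:10, function(s) {
    ev <- detect_saccade(make_saccade_trace(seed = s))
    c(ev$onset - 150, ev$offset - 186)
  })
  expect_lt(max(abs(errs)), 3)
  ev <- detect_saccade(make_saccade_trace(seed = 3))
  expect_equal(unname(ev$post_position), c(0, 0), tolerance = 0.1)
  expect_equal(unname(ev$pre_position), c(0, 10), tolerance = 0.1)
  # movement peaking at 80 deg/s stays below the 100 deg/s criterion
  slow <- make_saccade_trace(amplitude = 80 * 0.075 / 1.875,
                             duration = 75, noise_sd = 0)
  expect_null(detect_saccade(slow))
})

test_that("intercept is the projection onto the motion direction", {
  expect_equal(intercept(1, 0, 0), 1)
  expect_equal(intercept(0.3, 0.4, 90), 0.4)
  expect_equal(intercept(1, 1, 45), sqrt(2))
  # invariant to components orthogonal to alpha
  a <- 30
  u <- c(cos(a * pi / 180), sin(a * pi / 180))
  p <- 1.3 * u + 2.7 * c(-u[2], u[1])
  expect_equal(intercept(p[1], p[2], a), 1.3)
})

test_that("intercept-time regression recovers exact and null structure", {
  t_end <- seq(100, 300, length.out = 60)
  exact <- data.table::data.table(intercept = 10 * t_end / 1000,
                                  t_end = t_end)
  r <- intercept_time_regression(exact, n_boot = 200, seed = 1)
  expect_equal(r$slope, 10, tolerance = 1e-9)
  expect_equal(r$offset, 0, tolerance = 1e-9)
  expect_equal(r$pearson_r, 1)
  # shuffling destroys the correlation
  set.seed(4)
  shuf <- data.table::data.table(
    intercept = 10 * sample(rep(t_end, 84)) / 1000 + rnorm(5040, 0, 0.01),
    t_end = rep(t_end, 84))
  expect_lt(abs(intercept_time_regression(shuf, n_boot = 50,
                                          seed = 2)$pearson_r), 0.05)
  expect_error(intercept_time_regression(exact[1:5]), "at least 10")
  degen <- data.table::data.table(intercept = rnorm(20), t_end = rep(150, 20))
  expect_error(intercept_time_regression(degen), "degenerate")
})

test_that("2-D Gaussian endpoint fits recover mean, SD and degeneracy", {
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  circ <- cbind(1 + 0.6 * cos(th), 0.6 * sin(th))
  f <- fit_endpoint_gaussian(circ)
  expect_equal(unname(f$mean), c(1, 0), tolerance = 1e-9)
  expect_false(f$singular)
  set.seed(11)
  iso <- matrix(rnorm(2e4, 0, 0.8), ncol = 2)
  fi <- fit_endpoint_gaussian(iso)
  expect_equal(unname(fi$axes), c(0.8, 0.8), tolerance = 0.05 * 0.8)
  col3 <- cbind(1:3, 2 * (1:3))
  expect_true(fit_endpoint_gaussian(col3)$singular)
  expect_error(fit_endpoint_gaussian(col3[1:2, ]), "at least 3")
})

test_that("selectivity test includes strongly tuned, excludes flat neurons", {
  expect_identical(selectivity_test(rep(5, 6), rep(5, 6)),
                   list(p_value = 1, include = FALSE, zero_variance = TRUE))
  # simulation oracle: Poisson(20) vs Poisson(2) at n = 10 is essentially
  # always detected at p < 0.01
  set.seed(8)
  hits <- vapply(1:50, function(i)
    selectivity_test(rpois(10, 20), rpois(10, 2))$include, logical(1))
  expect_true(all(hits))
  expect_error(selectivity_test(3, c(1, 2)), "at least 2")
})
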