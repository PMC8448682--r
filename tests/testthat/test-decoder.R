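test_that("stratified splits are disjoint, exhaustive and reproducible", {
  ids <- 1:40
  strata <- rep(1:4, each = 10)
  sp <- split_trials(ids, strata, n_repeats = 5, seed = 3)
  expect_length(sp, 5)
  for (s in sp) {
    expect_length(s$train, 28)  # 7 of 10 per stratum
    expect_length(intersect(s$train, s$validate), 0)
    expect_setequal(c(s$train, s$validate), ids)
    for (g in 1:4) expect_equal(sum(strata[s$train] == g), 7)
  }
  expect_identical(sp, split_trials(ids, strata, n_repeats = 5, seed = 3))
  expect_error(split_trials(1:3, c(1, 1, 2), seed = 1), "at least 2")
})

test_that("expected counts integrate rate over the window", {
  lay <- ring_positions(3)
  nt <- length(tuning_grid()$t)
  f10 <- build_tuning_field(lay, matrix(10, 8, nt))
  expect_equal(expected_count(f10, c(0.3, -0.7), c(-100, 100)), 2,
               tolerance = 1e-6)
  f0 <- build_tuning_field(lay, matrix(0, 8, nt))
  expect_equal(expected_count(f0, c(0, 0)), 0)
  expect_error(expected_count(f10, c(9, 0)), "outside")
})

test_that("pseudo-trials are Poisson with the field-implied means", {
  lay <- ring_positions(3)
  nt <- length(tuning_grid()$t)
  fields <- lapply(c(10, 40), function(r)
    build_tuning_field(lay, matrix(r, 8, nt)))
  ps <- generate_pseudo_trials(fields, n = 10000, seed = 4)
  expect_equal(dim(ps$counts), c(10000, 2))
  expect_true(all(ps$counts >= 0))
  expect_true(all(abs(ps$positions) <= 4))
  for (j in 1:2) {
    lam <- c(10, 40)[j] * 0.2
    se <- sqrt(lam / 10000)
    expect_lt(abs(mean(ps$counts[, j]) - lam), 3 * se)
    expect_equal(var(ps$counts[, j]), lam, tolerance = 0.1)
  }
  expect_identical(ps$counts,
                   generate_pseudo_trials(fields, n = 10000, seed = 4)$counts)
  expect_equal(nrow(generate_pseudo_trials(fields, n = 0, seed = 1)$counts), 0)
})

test_that("decoder recovers positions from a well-tuned population", {
  # single-trial validation error for a 105-neuron, cleanly tuned cohort
  co <- make_cohort(105, tau = 0, seed = 55, untuned_range = c(0, 0.2))
  maps <- analytic_maps(co)
  grid <- tuning_grid()
  tr <- saccpop:::pseudo_trials_from_maps(maps, grid, 0.2, 15000, seed = 6)
  model <- train_decoder(tr$counts, tr$positions, maxit = 350, seed = 7)
  va <- saccpop:::pseudo_trials_from_maps(maps, grid, 0.2, 1500, seed = 8)
  pred <- predict_endpoints(model, va$counts)
  err <- sqrt(rowSums((pred - va$positions)^2))
  expect_lt(mean(err), 0.5)
  # deterministic and finite on degenerate inputs
  expect_identical(predict_endpoints(model, va$counts[1, ]),
                   predict_endpoints(model, va$counts[1, ]))
  expect_true(all(is.finite(predict_endpoints(model, rep(0, 105)))))
  expect_error(predict_endpoints(model, rep(1, 11)), "input layer")
  expect_error(train_decoder(matrix(c(1, NA), 2, 2), cbind(0:1, 0:1)),
               "non-finite")
})

test_that("position-independent populations carry no position information", {
  lay <- ring_positions(3)
  nt <- length(tuning_grid()$t)
  fields <- lapply(rep(25, 8), function(r)
    build_tuning_field(lay, matrix(r, 8, nt)))
  ps <- generate_pseudo_trials(fields, n = 4000, seed = 9)
  model <- train_decoder(ps$counts, ps$positions, maxit = 200, seed = 10)
  fresh <- generate_pseudo_trials(fields, n = 2000, seed = 11)
  pred <- predict_endpoints(model, fresh$counts)
  # predictions center on the workspace mean and do not track the
  # generating positions
  expect_lt(max(abs(colMeans(pred))), 0.25)
  expect_lt(abs(cor(pred[, 1], fresh$positions[, 1])), 0.1)
  expect_lt(abs(cor(pred[, 2], fresh$positions[, 2])), 0.1)
})

test_that("confusion matrix implements nearest-position assignment", {
  tp <- ring_positions(1.7)
  idx <- rep(1:8, each = 25)
  exact <- tp[idx, ]
  cm <- confusion_matrix(exact, idx, tp)
  expect_equal(cm$pct_correct, 100)
  expect_equal(cm$pct_correct_or_neighbor, 100)
  expect_equal(diag(cm$confusion), rep(1, 8))
  expect_equal(rowSums(cm$confusion), rep(1, 8))
  # rotated past the decision boundary: everything lands on a neighbor
  rot <- ring_positions(1.7, seq(30, 345, 45))
  cm2 <- confusion_matrix(rot[idx, ], idx, tp)
  expect_equal(cm2$pct_correct, 0)
  expect_equal(cm2$pct_correct_or_neighbor, 100)
  expect_equal(rowSums(cm2$confusion), rep(1, 8))
})

test_that("center bias is the intercept difference with the stated sign", {
  p <- c(1.5 * cos(pi / 3), 1.5 * sin(pi / 3))
  expect_equal(center_bias(p, p, 60), 0)
  half <- 0.75 * p / 1.5
  expect_equal(center_bias(p, half, 60), 0.75)
  over <- (1.7 / 1.5) * p
  expect_equal(center_bias(p, over, 60), -0.2)
})

test_that("bias-to-lag conversion is exact", {
  expect_equal(bias_to_time_lag(0.3, 10), 30)
  expect_equal(bias_to_time_lag(0.8, 10), 80)
  expect_equal(bias_to_time_lag(0, 5), 0)
  expect_error(bias_to_time_lag(0.3, 0), "speed")
})
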