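test_that("stationary target layout has the 17 design positions", {
  lay <- stationary_target_layout()
  expect_equal(nrow(lay), 17)
  expect_equal(nrow(unique(lay[, c("x", "y")])), 17)
  has <- function(x, y) any(abs(lay$x - x) < 1e-9 & abs(lay$y - y) < 1e-9)
  expect_true(has(0, 0))
  expect_true(has(2, 0))
  expect_true(has(0, -4))
  expect_true(has(2 * cos(pi / 4), 2 * sin(pi / 4)))
  expect_equal(max(sqrt(lay$x^2 + lay$y^2)), 4)
})

test_that("neuron_rate has unit-peak structure and baseline floor", {
  sp <- neuron_spec("n1", spatial_center = c(1, -1), spatial_sigma = 1.5,
                    peak_rate = 80, baseline_rate = 5,
                    temporal_peak = 10, temporal_sigma = 40)
  expect_equal(neuron_rate(sp, c(1, -1), 10), 80)
  # far endpoint: rate indistinguishable from baseline
  far <- c(1, -1) + c(10 * sp$spatial_sigma, 0)
  expect_equal(neuron_rate(sp, far, 10), 5, tolerance = 0.01)
  expect_true(all(neuron_rate(sp, c(0, 0), seq(-400, 400, 50)) >= 5))
  # untuned component keeps the stated peak rate exact
  spu <- neuron_spec("n2", c(1, -1), 1.5, 80, 5, 10, 40, tau = -50,
                     untuned_gain = 0.5)
  expect_equal(neuron_rate(spu, c(1, -1), 10), 80)
  # but responds at all positions around its temporal peak
  expect_gt(neuron_rate(spu, far, 10), 5 + 10)
})

test_that("tau = 0 makes interceptive and regular rates identical", {
  for (u in c(0, 0.7)) {
    sp <- neuron_spec("n1", c(0.5, 0.5), 1.5, 60, 3, 0, 40, tau = 0,
                      untuned_gain = u)
    tt <- seq(-300, 300, 7)
    ep <- c(1.2, 0.3)
    expect_equal(
      neuron_rate(sp, ep, tt, "interceptive", target_speed = 10,
                  direction = 45),
      neuron_rate(sp, ep, tt, "regular"))
  }
})

test_that("session simulation is reproducible and respects trial counts", {
  cfg <- session_config(n_regular_per_position = 2,
                        n_interceptive_per_direction = 3, seed = 5)
  co <- make_cohort(3, seed = 9)
  s1 <- simulate_session(co, cfg)
  expect_equal(sum(s1$trials$condition == "regular"), 2 * 17)
  expect_equal(sum(s1$trials$condition == "interceptive"), 3 * 8)
  s2 <- simulate_session(co, cfg)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$trials, s2$trials)
  # hierarchical seeding: adding neurons leaves existing draws untouched
  s3 <- simulate_session(make_cohort(5, seed = 9), cfg)
  expect_identical(s1$trials, s3$trials)
  expect_identical(s1$spikes[neuron_id == "n001"],
                   s3$spikes[neuron_id == "n001"])
  expect_error(session_config(duration_mean = -5), "non-physical")
})

test_that("sessions round-trip to plain-text tables", {
  ses <- small_session()
  dir <- file.path(tempdir(), "session_io")
  write_session(ses, dir)
  expect_setequal(list.files(dir),
                  c("trials.csv", "spikes.csv", "traces.csv", "cohort.json"))
  sp <- data.table::fread(file.path(dir, "spikes.csv"))
  expect_equal(nrow(sp), nrow(ses$spikes))
  expect_equal(sp$t_ms, ses$spikes$t_ms, tolerance = 1e-9)
  co <- jsonlite::read_json(file.path(dir, "cohort.json"))
  expect_length(co, length(ses$cohort))
  expect_equal(co[[1]]$neuron_id, ses$cohort[[1]]$neuron_id)
})

test_that("interceptive endpoints track the target at the target speed", {
  # analytic oracle: by construction intercept = speed * t_end / 1000 plus
  # isotropic noise, so the OLS slope converges to the target speed
  beh <- simulate_session(list(), session_config(
    n_regular_per_position = 1, n_interceptive_per_direction = 250,
    seed = 31))
  tr <- beh$trials[condition == "interceptive"]
  ic <- intercept(tr$end_x, tr$end_y, tr$direction)
  b <- stats::coef(stats::lm(ic ~ I(tr$t_end / 1000)))
  expect_equal(unname(b[2]), 10, tolerance = 0.5)
  expect_lt(abs(b[1]), 0.2)
})

test_that("spike counts are Poisson (Fano factor near 1)", {
  sp <- neuron_spec("n1", c(0, 0), 1.5, 70, 4, 0, 45, tau = -50,
                    untuned_gain = 0.4)
  counts <- vapply(seq_len(1200), function(i) {
    st <- sample_spike_train(sp, c(0.5, 0.2), c(-500, 800), onset = 140,
                             condition = "interceptive", target_speed = 10,
                             direction = 0, seed = 7000 + i)
    sum(st >= 40 & st <= 240)  # onset 140: window -100..+100
  }, numeric(1))
  fano <- stats::var(counts) / mean(counts)
  expect_gt(mean(counts), 3)
  expect_equal(fano, 1, tolerance = 0.15)
})
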