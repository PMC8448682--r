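# Shared fixtures, built once per test run (memoized).

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Small session: 12 neurons, reduced trial counts; enough for pipeline
# mechanics without long runtimes.
small_session <- function() {
  fixture("small_session", function() {
    cohort <- make_cohort(12, tau = -50, seed = 101)
    simulate_session(cohort, session_config(
      n_regular_per_position = 6, n_interceptive_per_direction = 8,
      seed = 202))
  })
}

small_saccades <- function() {
  fixture("small_saccades", function() detect_saccades(small_session()))
}

# Analytic window-averaged rate maps for a synthetic cohort: Gaussian
# spatial tuning (plus untuned floor) times the window-mean temporal
# factor. Used to test the decoder without simulating sessions.
analytic_maps <- function(cohort, window = c(-100, 100),
                          grid = tuning_grid()) {
  q <- expand.grid(x = grid$x, y = grid$y)
  tpts <- seq(window[1], window[2], by = 10)
  vapply(cohort, function(s) {
    u <- s$untuned_gain
    gs <- exp(-((q$x - s$spatial_center[1])^2 +
                  (q$y - s$spatial_center[2])^2) / (2 * s$spatial_sigma^2))
    gt <- mean(exp(-(tpts - s$temporal_peak)^2 / (2 * s$temporal_sigma^2)))
    s$baseline_rate + (s$peak_rate - s$baseline_rate) *
      (u * gt + gs * gt) / (1 + u)
  }, numeric(nrow(q)))
}

ring_positions <- function(radius = 1.5, directions = seq(0, 315, 45)) {
  cbind(radius * cos(directions * pi / 180),
        radius * sin(directions * pi / 180))
}
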