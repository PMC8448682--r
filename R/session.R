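#' Session configuration
#'
#' Holds the behavioral study conditions of one recording session: trial
#' counts per target, target speed, saccade latency/duration statistics and
#' endpoint scatter. Defaults reproduce the experimental design: 10 trials
#' for each of the 17 stationary positions, 15 trials for each of 8 motion
#' directions at 10 deg/s, latency 134 +/- 44 ms, duration 36 +/- 8.9 ms.
#'
#' @param n_regular_per_position Regular trials per stationary position.
#' @param n_interceptive_per_direction Interceptive trials per direction.
#' @param target_speed Target speed, deg/s (> 0).
#' @param latency_mean,latency_sd Saccade latency from target step, ms.
#' @param duration_mean,duration_sd Saccade duration, ms.
#' @param endpoint_noise_sd Isotropic endpoint scatter SD, deg.
#' @param eye_noise_sd White positional noise added to eye traces, deg.
#' @param fixation Initial fixation position, deg.
#' @param trial_t Length-2: trial time span, ms (target step/motion onset
#'   at 0).
#' @param seed Integer seed fixing all downstream randomness.
#' @return A list of class `session_config`.
#' @export
session_config <- function(n_regular_per_position = 10,
                           n_interceptive_per_direction = 15,
                           target_speed = 10,
                           latency_mean = 134, latency_sd = 44,
                           duration_mean = 36, duration_sd = 8.9,
                           endpoint_noise_sd = 0.8,
                           eye_noise_sd = 0.05,
                           fixation = c(0, 9),
                           trial_t = c(-500, 1000),
                           seed = 1) {
  cfg <- list(
    n_regular_per_position = n_regular_per_position,
    n_interceptive_per_direction = n_interceptive_per_direction,
    target_speed = target_speed,
    latency_mean = latency_mean, latency_sd = latency_sd,
    duration_mean = duration_mean, duration_sd = duration_sd,
    endpoint_noise_sd = endpoint_noise_sd,
    eye_noise_sd = eye_noise_sd,
    fixation = as.numeric(fixation),
    trial_t = as.numeric(trial_t),
    seed = as.integer(seed)
  )
  problems <- validate_session_config(cfg)
  if (length(problems)) stop("invalid session_config: ",
                             paste(problems, collapse = "; "))
  structure(cfg, class = "session_config")
}

validate_session_config <- function(cfg) {
  p <- character(0)
  if (cfg$n_regular_per_position < 1) p <- c(p, "n_regular_per_position < 1")
  if (cfg$n_interceptive_per_direction < 1)
    p <- c(p, "n_interceptive_per_direction < 1")
  if (cfg$target_speed <= 0) p <- c(p, "target_speed must be > 0")
  if (cfg$latency_mean <= 0 || cfg$latency_sd < 0)
    p <- c(p, "non-physical latency parameters")
  if (cfg$duration_mean <= 0 || cfg$duration_sd < 0)
    p <- c(p, "non-physical duration parameters")
  if (cfg$endpoint_noise_sd < 0) p <- c(p, "endpoint_noise_sd < 0")
  if (cfg$eye_noise_sd < 0) p <- c(p, "eye_noise_sd < 0")
  if (cfg$trial_t[2] <= cfg$trial_t[1]) p <- c(p, "empty trial time span")
  p
}

# Minimum-jerk displacement profile on u in [0, 1].
min_jerk <- function(u) u^3 * (10 - 15 * u + 6 * u^2)

# Truncated normal draw via clamping (slight truncation bias is irrelevant
# at +/- 2 SD; keeps latencies/durations physical and saccade peak
# velocities above the detection threshold for the smallest amplitudes).
rnorm_clamped <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

# Target position at time t (ms) for one trial.
target_position <- function(condition, target_xy, direction, speed, t_ms) {
  if (condition == "regular") {
    matrix(rep(target_xy, each = length(t_ms)), ncol = 2)
  } else {
    u <- unit_vec(direction)
    cbind(pmax(t_ms, 0) / 1000 * speed * u[1],
          pmax(t_ms, 0) / 1000 * speed * u[2])
  }
}

# Noise-free eye trajectory: fixation -> minimum-jerk saccade -> post-
# saccadic fixation (regular) or constant-velocity pursuit (interceptive).
eye_trajectory <- function(t_ms, fixation, endpoint, onset, offset,
                           condition, speed, direction) {
  n <- length(t_ms)
  x <- numeric(n); y <- numeric(n)
  pre <- t_ms < onset
  dur <- offset - onset
  insac <- t_ms >= onset & t_ms <= offset
  post <- t_ms > offset
  x[pre] <- fixation[1]; y[pre] <- fixation[2]
  s <- min_jerk((t_ms[insac] - onset) / dur)
  x[insac] <- fixation[1] + (endpoint[1] - fixation[1]) * s
  y[insac] <- fixation[2] + (endpoint[2] - fixation[2]) * s
  if (condition == "regular") {
    x[post] <- endpoint[1]; y[post] <- endpoint[2]
  } else {
    u <- unit_vec(direction)
    dt <- (t_ms[post] - offset) / 1000
    x[post] <- endpoint[1] + speed * u[1] * dt
    y[post] <- endpoint[2] + speed * u[2] * dt
  }
  cbind(x = x, y = y)
}

#' Simulate a recording session
#'
#' Generates the full behavioral and spiking record of one session:
#' regular trials to the 17 stationary positions and interceptive trials in
#' 8 motion directions, each with a 1 kHz eye trace (fixation +
#' minimum-jerk saccade + post-saccadic pursuit or fixation + white
#' positional noise), ground-truth saccade parameters, and per-neuron spike
#' trains drawn by Poisson thinning from [neuron_rate()]. Regular saccades
#' land at the target plus isotropic noise; interceptive saccades land at
#' the target position at saccade end plus the same noise, so the
#' motion-aligned endpoint component grows with saccade end time at a slope
#' equal to the target speed.
#'
#' Randomness is seeded hierarchically (session seed, then per-trial, then
#' per-trial-per-neuron substreams): the behavioral record is invariant to
#' the number of neurons, and re-running with the same seed reproduces
#' spike times exactly.
#'
#' @param cohort A `neuron_cohort` (possibly empty `list()` for
#'   behavior-only simulations).
#' @param cfg A [session_config()].
#' @return A list of class `saccade_session` with elements `trials`
#'   (data.table of per-trial metadata incl. ground truth), `traces` (list
#'   of n x 3 matrices `t`, `x`, `y`), `spikes` (data.table `trial_id`,
#'   `neuron_id`, `t_ms`), `cohort`, `config`.
#' @export
simulate_session <- function(cohort = list(), cfg = session_config()) {
  stopifnot(inherits(cfg, "session_config"))
  layout <- stationary_target_layout()
  dirs <- interceptive_directions()

  reg <- data.table::data.table(
    condition = "regular",
    target_x = rep(layout$x, each = cfg$n_regular_per_position),
    target_y = rep(layout$y, each = cfg$n_regular_per_position),
    position_id = rep(layout$position_id, each = cfg$n_regular_per_position),
    direction = NA_real_
  )
  int <- data.table::data.table(
    condition = "interceptive",
    target_x = 0, target_y = 0, position_id = NA_integer_,
    direction = rep(dirs, each = cfg$n_interceptive_per_direction)
  )
  trials <- rbind(reg, int)
  trials[, trial_id := seq_len(.N)]

  t_ms <- seq(cfg$trial_t[1], cfg$trial_t[2], by = 1)
  lat_lo <- max(cfg$latency_mean - 2 * cfg$latency_sd, 60)
  lat_hi <- cfg$latency_mean + 2 * cfg$latency_sd
  dur_lo <- max(cfg$duration_mean - 2 * cfg$duration_sd, 12)
  dur_hi <- cfg$duration_mean + 2 * cfg$duration_sd

  n_tr <- nrow(trials)
  lat <- numeric(n_tr); dur <- numeric(n_tr)
  end_x <- numeric(n_tr); end_y <- numeric(n_tr)
  traces <- vector("list", n_tr)
  spike_list <- vector("list", n_tr)
  n_neu <- length(cohort)

  for (i in seq_len(n_tr)) {
    tr <- trials[i]
    behav_seed <- derive_seed(cfg$seed, i)
    draws <- with_seed(behav_seed, {
      l <- rnorm_clamped(1, cfg$latency_mean, cfg$latency_sd, lat_lo, lat_hi)
      d <- rnorm_clamped(1, cfg$duration_mean, cfg$duration_sd, dur_lo, dur_hi)
      eps <- stats::rnorm(2, 0, cfg$endpoint_noise_sd)
      noise <- matrix(stats::rnorm(2 * length(t_ms), 0, cfg$eye_noise_sd),
                      ncol = 2)
      list(l = l, d = d, eps = eps, noise = noise)
    })
    lat[i] <- draws$l; dur[i] <- draws$d
    t_end <- draws$l + draws$d
    if (tr$condition == "regular") {
      ep <- c(tr$target_x, tr$target_y) + draws$eps
    } else {
      ep <- (t_end / 1000) * cfg$target_speed * unit_vec(tr$direction) +
        draws$eps
    }
    end_x[i] <- ep[1]; end_y[i] <- ep[2]
    xy <- eye_trajectory(t_ms, cfg$fixation, ep, draws$l, t_end,
                         tr$condition, cfg$target_speed, tr$direction)
    traces[[i]] <- cbind(t = t_ms, xy + draws$noise)

    if (n_neu > 0) {
      per_neuron <- vector("list", n_neu)
      for (j in seq_len(n_neu)) {
        st <- sample_spike_train(
          cohort[[j]], ep, cfg$trial_t, onset = draws$l,
          condition = tr$condition, target_speed = cfg$target_speed,
          direction = tr$direction,
          seed = derive_seed(cfg$seed, i, j)
        )
        if (length(st))
          per_neuron[[j]] <- data.table::data.table(
            trial_id = tr$trial_id,
            neuron_id = cohort[[j]]$neuron_id,
            t_ms = st)
      }
      spike_list[[i]] <- data.table::rbindlist(per_neuron)
    }
  }

  trials[, `:=`(latency = lat, duration = dur, t_end = lat + dur,
                end_x = end_x, end_y = end_y)]
  spikes <- data.table::rbindlist(spike_list)
  if (nrow(spikes) == 0 || n_neu == 0) {
    spikes <- data.table::data.table(trial_id = integer(0),
                                     neuron_id = character(0),
                                     t_ms = numeric(0))
  }
  structure(list(trials = trials, traces = traces, spikes = spikes,
                 cohort = cohort, config = cfg),
            class = "saccade_session")
}

#' Write a session to disk as plain-text tables
#'
#' Writes `trials.csv`, `spikes.csv`, `traces.csv` (long format) and
#' `cohort.json` under `dir`.
#'
#' @param session A `saccade_session`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(session$trials, file.path(dir, "trials.csv"))
  data.table::fwrite(session$spikes, file.path(dir, "spikes.csv"))
  tr_long <- data.table::rbindlist(lapply(seq_along(session$traces), function(i)
    data.table::data.table(trial_id = i,
                           t_ms = session$traces[[i]][, 1],
                           x = session$traces[[i]][, 2],
                           y = session$traces[[i]][, 3])))
  data.table::fwrite(tr_long, file.path(dir, "traces.csv"))
  jsonlite::write_json(
    lapply(session$cohort, function(s) unclass(s)),
    file.path(dir, "cohort.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
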