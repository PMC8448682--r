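#' Construct a single neuron specification
#'
#' A synthetic neuron is a separable spatio-temporal rate model: a 2-D
#' Gaussian spatial tuning over saccade end-position multiplied by a
#' Gaussian temporal profile peaking near saccade onset, riding on a
#' baseline rate. The snapshot offset `tau` (ms, usually <= 0) controls how
#' the neuron represents a moving target: during interceptive saccades the
#' spatial tuning references the position the target occupied at
#' (saccade end + tau), and the temporal profile is delayed by |tau|. With
#' `tau = 0` the neuron treats an interceptive saccade exactly like a
#' regular saccade landing at the same point.
#'
#' @param neuron_id Character id.
#' @param spatial_center Length-2 numeric, deg; center of spatial tuning.
#' @param spatial_sigma Spatial tuning width, deg (> 0).
#' @param peak_rate,baseline_rate Spikes/s; `peak_rate >= baseline_rate >= 0`.
#' @param temporal_peak Time of maximal activity relative to saccade onset, ms.
#' @param temporal_sigma Temporal tuning width, ms (> 0).
#' @param tau Snapshot offset, ms relative to saccade end (see Details).
#' @param untuned_gain Relative strength `u >= 0` of a spatially untuned
#'   saccade-locked response component. The peri-saccadic drive is
#'   `(u + G_space) / (1 + u)`, so `u = 0` (default) gives purely tuned
#'   responses while `u > 0` adds saccade-related activation at all
#'   end-positions, as commonly seen in parietal neurons. The rate still
#'   equals `peak_rate` at the tuning center/temporal peak. During
#'   interceptive saccades only the tuned component is delayed by `|tau|`;
#'   the untuned component stays locked to the saccade.
#' @param preferred_vector Optional length-2 numeric `(amplitude, direction)`
#'   of the preferred saccade vector (deg, deg CCW from +x); bookkeeping only.
#' @return A list of class `neuron_spec`.
#' @export
neuron_spec <- function(neuron_id, spatial_center, spatial_sigma,
                        peak_rate, baseline_rate = 0,
                        temporal_peak = 0, temporal_sigma = 50,
                        tau = 0, untuned_gain = 0,
                        preferred_vector = c(NA_real_, NA_real_)) {
  stopifnot(spatial_sigma > 0, temporal_sigma > 0,
            peak_rate >= baseline_rate, baseline_rate >= 0,
            untuned_gain >= 0, length(spatial_center) == 2)
  structure(list(
    neuron_id = as.character(neuron_id),
    spatial_center = as.numeric(spatial_center),
    spatial_sigma = spatial_sigma,
    peak_rate = peak_rate,
    baseline_rate = baseline_rate,
    temporal_peak = temporal_peak,
    temporal_sigma = temporal_sigma,
    tau = tau,
    untuned_gain = untuned_gain,
    preferred_vector = as.numeric(preferred_vector)
  ), class = "neuron_spec")
}

#' Generate a synthetic cohort of neurons
#'
#' Draws a cohort whose spatial tuning centers tile the decoded workspace
#' (so that end-positions across the +/-4 deg square are decodable from the
#' population), with broad tuning widths, peri-saccadic temporal peaks, and
#' a common (or per-neuron) snapshot offset `tau`.
#'
#' @param n_neurons Number of neurons (study condition: 105).
#' @param tau Snapshot offset(s), ms; scalar or length `n_neurons`.
#' @param seed Integer seed; the cohort is reproducible from it.
#' @param fixation Initial fixation position, deg (used for the bookkeeping
#'   preferred vector).
#' @param center_halfwidth Tuning centers drawn uniformly over this
#'   half-width square, deg.
#' @param sigma_range,peak_range,baseline_range Uniform draw ranges for
#'   spatial sigma (deg), peak rate and baseline rate (spikes/s).
#' @param temporal_peak_sd SD of the per-neuron temporal peak around saccade
#'   onset, ms (peri-saccadic response timing is heterogeneous).
#' @param temporal_peak_max Upper clamp on temporal peaks, ms: response
#'   timing is dominated by build-up and burst activity; purely
#'   post-saccadic peaks are not generated.
#' @param temporal_sigma_range Uniform range of temporal sigma, ms.
#' @param untuned_range Uniform range of the per-neuron untuned gain (see
#'   [neuron_spec()]).
#' @return A list of `neuron_spec` with class `neuron_cohort`.
#' @export
make_cohort <- function(n_neurons = 105, tau = -50, seed = 1,
                        fixation = c(0, 9),
                        center_halfwidth = 6,
                        sigma_range = c(1.2, 2.5),
                        peak_range = c(30, 90),
                        baseline_range = c(1, 8),
                        temporal_peak_sd = 25,
                        temporal_peak_max = 40,
                        temporal_sigma_range = c(35, 60),
                        untuned_range = c(0.3, 0.9)) {
  stopifnot(n_neurons >= 1)
  tau <- rep_len(tau, n_neurons)
  cohort <- with_seed(seed, {
    lapply(seq_len(n_neurons), function(i) {
      ctr <- stats::runif(2, -center_halfwidth, center_halfwidth)
      base <- stats::runif(1, baseline_range[1], baseline_range[2])
      pv <- ctr - fixation
      neuron_spec(
        neuron_id = sprintf("n%03d", i),
        spatial_center = ctr,
        spatial_sigma = stats::runif(1, sigma_range[1], sigma_range[2]),
        peak_rate = base + stats::runif(1, peak_range[1], peak_range[2]),
        baseline_rate = base,
        temporal_peak = min(stats::rnorm(1, 0, temporal_peak_sd),
                            temporal_peak_max),
        temporal_sigma = stats::runif(1, temporal_sigma_range[1],
                                      temporal_sigma_range[2]),
        tau = tau[i],
        untuned_gain = stats::runif(1, untuned_range[1], untuned_range[2]),
        preferred_vector = c(sqrt(sum(pv^2)),
                             (atan2(pv[2], pv[1]) * 180 / pi) %% 360)
      )
    })
  })
  structure(cohort, class = "neuron_cohort")
}

#' Instantaneous firing rate of a synthetic neuron
#'
#' Rate at peri-saccadic time `t` for a saccade landing at `endpoint`:
#' `baseline + (peak - baseline) * (u * G_time(t) + G_space(eff) *
#' G_time(t_eff)) / (1 + u)` with unit-peak Gaussians, where `u` is the
#' untuned gain (0 by default, reducing to the separable tuned model
#' `baseline + (peak - baseline) * G_space * G_time`). For regular saccades
#' the effective endpoint is the endpoint itself and `t_eff = t`. For
#' interceptive saccades the tuned component's spatial argument is shifted
#' against the target motion by `|tau| * speed / 1000` deg (the neuron
#' references the target position at saccade end + tau; endpoint scatter
#' components are untouched) and its temporal profile is evaluated at
#' `t + tau`, i.e. delayed by `|tau|` ms, while the untuned component stays
#' saccade-locked.
#'
#' @param spec A [neuron_spec()].
#' @param endpoint Length-2 numeric: actual saccade end-position, deg.
#' @param t Numeric vector of times relative to saccade onset, ms.
#' @param condition `"regular"` or `"interceptive"`.
#' @param target_speed Target speed, deg/s (interceptive only).
#' @param direction Target motion direction, deg CCW from +x
#'   (interceptive only).
#' @return Rates in spikes/s, same length as `t`; never below zero by
#'   construction (minimum is the baseline as the Gaussians vanish).
#' @export
neuron_rate <- function(spec, endpoint, t,
                        condition = c("regular", "interceptive"),
                        target_speed = 0, direction = NA_real_) {
  condition <- match.arg(condition)
  u <- spec$untuned_gain %||% 0
  eff <- endpoint
  t_eff <- t
  if (condition == "interceptive") {
    stopifnot(is.finite(direction), target_speed >= 0)
    eff <- endpoint + (spec$tau / 1000) * target_speed * unit_vec(direction)
    t_eff <- t + spec$tau
  }
  g_space <- exp(-sum((eff - spec$spatial_center)^2) /
                   (2 * spec$spatial_sigma^2))
  g_tuned <- exp(-(t_eff - spec$temporal_peak)^2 / (2 * spec$temporal_sigma^2))
  g_unt <- exp(-(t - spec$temporal_peak)^2 / (2 * spec$temporal_sigma^2))
  drive <- (u * g_unt + g_space * g_tuned) / (1 + u)
  spec$baseline_rate + (spec$peak_rate - spec$baseline_rate) * drive
}

#' Draw an inhomogeneous Poisson spike train by thinning
#'
#' Exact sampling from the neuron's rate function over a trial: candidates
#' are drawn from a homogeneous Poisson process at the per-trial maximal
#' rate and accepted with probability rate(t)/max rate.
#'
#' @inheritParams neuron_rate
#' @param t_range Length-2 numeric: trial time span, ms (trial clock).
#' @param onset Saccade onset on the trial clock, ms.
#' @param seed Integer seed for this draw (or NULL to use the current RNG).
#' @return Sorted numeric vector of spike times on the trial clock, ms.
#' @export
sample_spike_train <- function(spec, endpoint, t_range, onset,
                               condition = "regular",
                               target_speed = 0, direction = NA_real_,
                               seed = NULL) {
  condition <- match.arg(condition, c("regular", "interceptive"))
  u <- spec$untuned_gain %||% 0
  eff <- endpoint
  if (condition == "interceptive") {
    eff <- endpoint + (spec$tau / 1000) * target_speed * unit_vec(direction)
  }
  g_space <- exp(-sum((eff - spec$spatial_center)^2) /
                   (2 * spec$spatial_sigma^2))
  lambda_max <- spec$baseline_rate +  # upper bound over t
    (spec$peak_rate - spec$baseline_rate) * (u + g_space) / (1 + u)
  dur_s <- (t_range[2] - t_range[1]) / 1000
  with_seed(seed, {
    n_cand <- stats::rpois(1, lambda_max * dur_s)
    if (n_cand == 0) return(numeric(0))
    tc <- stats::runif(n_cand, t_range[1], t_range[2])
    r <- neuron_rate(spec, endpoint, tc - onset, condition,
                     target_speed, direction)
    keep <- stats::runif(n_cand) < r / lambda_max
    sort(tc[keep])
  })
}
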