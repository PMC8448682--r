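#' Smooth an eye trace with a centered moving average
#'
#' @param trace Numeric matrix with one column per coordinate (time in
#'   rows, uniform 1 ms sampling), or a numeric vector.
#' @param span Filter span in ms (samples); default 15.
#' @return Smoothed trace of the same shape; the window is truncated at the
#'   edges so output length equals input length.
#' @export
smooth_trace <- function(trace, span = 15) {
  if (span < 1) stop("span must be >= 1 ms")
  half <- floor(span / 2)
  smooth1 <- function(x) {
    n <- length(x)
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  if (is.matrix(trace)) apply(trace, 2, smooth1) else smooth1(trace)
}

# 2-D eye speed in deg/s from a smoothed (x, y) trace sampled at 1 kHz;
# central differences in the interior, one-sided at the ends.
trace_speed <- function(xy) {
  n <- nrow(xy)
  dx <- numeric(n); dy <- numeric(n)
  dx[2:(n - 1)] <- (xy[3:n, 1] - xy[1:(n - 2), 1]) / 2
  dy[2:(n - 1)] <- (xy[3:n, 2] - xy[1:(n - 2), 2]) / 2
  dx[1] <- xy[2, 1] - xy[1, 1]; dy[1] <- xy[2, 2] - xy[1, 2]
  dx[n] <- xy[n, 1] - xy[n - 1, 1]; dy[n] <- xy[n, 2] - xy[n - 1, 2]
  1000 * sqrt(dx^2 + dy^2)
}

#' Detect the first saccade in an eye trace
#'
#' Double velocity criterion: find the first sample where eye speed exceeds
#' `v_high` (100 deg/s), then walk backward to the last preceding sample
#' with speed below `v_low` (30 deg/s) for the onset, and forward to the
#' first subsequent sample below `v_low` for the offset. Pre-/post-saccadic
#' positions are averages over 16-6 ms before onset and 2-4 ms after
#' offset (the short post-window avoids contamination by pursuit).
#'
#' @param trace n x 3 matrix (`t`, `x`, `y`), 1 ms sampling; the position
#'   columns are smoothed internally with [smooth_trace()].
#' @param v_high,v_low Velocity thresholds, deg/s.
#' @param smooth_span Span of the smoothing filter, ms.
#' @return A list with `onset`, `offset` (ms, trial clock), `duration`,
#'   `pre_position`, `post_position`, `peak_speed`; or `NULL` if no sample
#'   exceeds `v_high` ("no event").
#' @export
detect_saccade <- function(trace, v_high = 100, v_low = 30,
                           smooth_span = 15) {
  t <- trace[, 1]
  xy <- smooth_trace(trace[, 2:3, drop = FALSE], smooth_span)
  v <- trace_speed(xy)
  above <- which(v > v_high)
  if (!length(above)) return(NULL)
  i1 <- above[1]
  pre_slow <- which(v[seq_len(i1 - 1)] < v_low)
  onset_i <- if (length(pre_slow)) pre_slow[length(pre_slow)] else 1L
  post_slow <- which(v[(i1 + 1):length(v)] < v_low)
  if (!length(post_slow)) return(NULL)
  offset_i <- i1 + post_slow[1]
  pre_idx <- (onset_i - 16):(onset_i - 6)
  pre_idx <- pre_idx[pre_idx >= 1]
  post_idx <- (offset_i + 2):(offset_i + 4)
  post_idx <- post_idx[post_idx <= nrow(xy)]
  list(
    onset = t[onset_i], offset = t[offset_i],
    duration = t[offset_i] - t[onset_i],
    pre_position = colMeans(xy[pre_idx, , drop = FALSE]),
    post_position = colMeans(xy[post_idx, , drop = FALSE]),
    peak_speed = max(v[i1:offset_i])
  )
}

#' Detect saccades for every trial of a session
#'
#' Applies [detect_saccade()] to each trial. Latency is the detected onset
#' relative to the target step at t = 0; `t_end` is the detected offset on
#' the same clock.
#'
#' @param session A `saccade_session`.
#' @return data.table with one row per trial: detection flag, timing,
#'   pre/post positions, plus the trial's condition/target metadata.
#' @export
detect_saccades <- function(session) {
  res <- lapply(seq_along(session$traces), function(i) {
    ev <- detect_saccade(session$traces[[i]])
    tr <- session$trials[i]
    if (is.null(ev)) {
      data.table::data.table(
        trial_id = tr$trial_id, condition = tr$condition,
        position_id = tr$position_id, direction = tr$direction,
        detected = FALSE, onset = NA_real_, offset = NA_real_,
        latency = NA_real_, duration = NA_real_, t_end = NA_real_,
        pre_x = NA_real_, pre_y = NA_real_,
        post_x = NA_real_, post_y = NA_real_)
    } else {
      data.table::data.table(
        trial_id = tr$trial_id, condition = tr$condition,
        position_id = tr$position_id, direction = tr$direction,
        detected = TRUE, onset = ev$onset, offset = ev$offset,
        latency = ev$onset, duration = ev$duration, t_end = ev$offset,
        pre_x = ev$pre_position[1], pre_y = ev$pre_position[2],
        post_x = ev$post_position[1], post_y = ev$post_position[2])
    }
  })
  data.table::rbindlist(res)
}

#' Intercept: motion-aligned component of a saccade end-position
#'
#' Orthogonal projection of the end-position `(x, y)` onto the target
#' motion direction `alpha`: `x cos(alpha) + y sin(alpha)`.
#'
#' @param x,y End-position coordinates, deg (vectorized).
#' @param alpha Target motion direction, deg CCW from +x.
#' @return Intercept in deg.
#' @export
intercept <- function(x, y, alpha) {
  a <- deg2rad(alpha)
  x * cos(a) + y * sin(a)
}

#' Intercept samples from detected interceptive saccades
#'
#' @param saccades Output of [detect_saccades()].
#' @return data.table with `x`, `y` (post-saccadic position), `alpha`
#'   (motion direction), `intercept`, `t_end` (ms) for detected
#'   interceptive trials.
#' @export
intercept_samples <- function(saccades) {
  s <- saccades[saccades$condition == "interceptive" & saccades$detected]
  data.table::data.table(
    trial_id = s$trial_id, x = s$post_x, y = s$post_y, alpha = s$direction,
    intercept = intercept(s$post_x, s$post_y, s$direction),
    t_end = s$t_end)
}

#' Regression of intercept on saccade end time
#'
#' Ordinary least squares of the intercept (deg) on the time of saccade end
#' (converted to s, so the slope is in deg/s), with Pearson correlation and
#' a percentile bootstrap confidence interval at p = 0.01 (resampling
#' trials, 0.5/99.5 percentiles).
#'
#' @param samples data.table from [intercept_samples()] (needs columns
#'   `intercept`, `t_end`).
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap.
#' @return List: `slope` (deg/s), `offset` (deg), `pearson_r`, `slope_ci`,
#'   `offset_ci` (99% percentile intervals), `n`.
#' @export
intercept_time_regression <- function(samples, n_boot = 2000, seed = 1) {
  n <- nrow(samples)
  if (n < 10) stop("need at least 10 intercept samples")
  ts <- samples$t_end / 1000
  ic <- samples$intercept
  if (stats::var(ts) == 0) stop("degenerate t_end variance")
  fit_slope <- function(x, y) {
    b <- stats::cov(x, y) / stats::var(x)
    c(slope = b, offset = mean(y) - b * mean(x))
  }
  est <- fit_slope(ts, ic)
  r <- stats::cor(ts, ic)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      fit_slope(ts[idx], ic[idx])
    }, numeric(2))
  })
  list(slope = unname(est["slope"]), offset = unname(est["offset"]),
       pearson_r = r,
       slope_ci = unname(stats::quantile(boot[1, ], c(0.005, 0.995))),
       offset_ci = unname(stats::quantile(boot[2, ], c(0.005, 0.995))),
       n = n)
}

#' Fit a 2-D Gaussian to saccade end-positions
#'
#' Sample mean and covariance of a cloud of end-positions; the 1-SD
#' covariance ellipse is returned as axis lengths (sqrt of eigenvalues) and
#' orientation.
#'
#' @param endpoints n x 2 matrix or data.frame of (x, y), n >= 3.
#' @return List: `mean`, `cov`, `singular` (logical), `axes` (1-SD
#'   semi-axis lengths, deg), `angle` (orientation of the major axis, deg).
#' @export
fit_endpoint_gaussian <- function(endpoints) {
  ep <- as.matrix(endpoints)
  if (nrow(ep) < 3) stop("need at least 3 endpoints")
  mu <- colMeans(ep)
  S <- stats::cov(ep)
  e <- eigen(S, symmetric = TRUE)
  singular <- min(e$values) <= max(e$values) * 1e-12
  list(mean = mu, cov = S, singular = singular,
       axes = sqrt(pmax(e$values, 0)),
       angle = atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi)
}

#' Direction-selectivity inclusion test
#'
#' Two-sample t test of spike counts (window of 100 ms before to 100 ms
#' after saccade onset) between preferred and anti-preferred saccade
#' directions; a neuron is included when p < `alpha`.
#'
#' @param counts_pref,counts_anti Integer spike counts per trial (>= 2
#'   trials each).
#' @param alpha Significance level (default 0.01).
#' @return List: `p_value`, `include`, `zero_variance` flag (TRUE when both
#'   sides are constant, in which case the neuron is excluded).
#' @export
selectivity_test <- function(counts_pref, counts_anti, alpha = 0.01) {
  if (length(counts_pref) < 2 || length(counts_anti) < 2)
    stop("need at least 2 trials per direction")
  if (stats::var(counts_pref) == 0 && stats::var(counts_anti) == 0) {
    p <- if (mean(counts_pref) == mean(counts_anti)) 1 else 0
    return(list(p_value = p, include = FALSE, zero_variance = TRUE))
  }
  p <- stats::t.test(counts_pref, counts_anti)$p.value
  list(p_value = p, include = p < alpha, zero_variance = FALSE)
}
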