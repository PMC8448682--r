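#' Default spatio-temporal tuning grid
#'
#' Spatial axes from -4 to +4 deg in 0.1 deg steps (81 points each) and
#' peri-saccadic times from 400 ms before to 350 ms after saccade onset in
#' 10 ms steps (76 points).
#'
#' @return List with `x`, `y`, `t`.
#' @export
tuning_grid <- function() {
  list(x = seq(-4, 4, by = 0.1), y = seq(-4, 4, by = 0.1),
       t = seq(-400, 350, by = 10))
}

#' Trial-averaged peri-saccadic response function
#'
#' Convolves spike times (aligned to saccade onset) with a unit-area
#' Gaussian kernel (sigma = 20 ms, truncated at +/-4 sigma), scales to
#' spikes/s, and averages over trials.
#'
#' @param spike_times List with one numeric vector of aligned spike times
#'   (ms) per trial; trials without spikes contribute zeros.
#' @param grid_t Evaluation times, ms.
#' @param sigma Kernel SD, ms.
#' @return Numeric vector of mean rates (spikes/s) on `grid_t`.
#' @export
response_function <- function(spike_times, grid_t = tuning_grid()$t,
                              sigma = 20) {
  if (!is.list(spike_times)) spike_times <- list(spike_times)
  n_trials <- length(spike_times)
  if (n_trials == 0) stop("response_function needs at least one trial")
  sp <- unlist(spike_times, use.names = FALSE)
  if (!length(sp)) return(numeric(length(grid_t)))
  d <- outer(grid_t, sp, "-")
  k <- ifelse(abs(d) > 4 * sigma, 0,
              exp(-d^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi)))
  1000 * rowSums(k) / n_trials
}

#' Build an interpolated spatio-temporal tuning field
#'
#' Interpolates per-anchor response functions over the spatial grid: at
#' each time slice, piecewise-linear interpolation on the triangulated
#' anchor set inside its convex hull, nearest-anchor extrapolation outside.
#'
#' @param anchor_xy n_anchor x 2 matrix of anchor end-positions, deg
#'   (>= 3, non-collinear).
#' @param anchor_values n_anchor x n_t matrix of rates (one response
#'   function per row), or a length-n_anchor vector for a single slice.
#' @param grid Grid definition as from [tuning_grid()].
#' @param neuron_id,condition Optional metadata carried on the result.
#' @return An object of class `tuning_field`: list with `activity` (array
#'   x by y by t, or x by y matrix for vector input), grid axes, metadata.
#' @export
build_tuning_field <- function(anchor_xy, anchor_values,
                               grid = tuning_grid(),
                               neuron_id = NA_character_,
                               condition = NA_character_) {
  if (is.vector(anchor_values)) anchor_values <- matrix(anchor_values)
  stopifnot(nrow(anchor_xy) == nrow(anchor_values))
  q <- expand.grid(x = grid$x, y = grid$y)
  W <- interp_weights(anchor_xy, q$x, q$y)$W
  maps <- W %*% anchor_values  # (nx*ny) x n_t
  nt <- ncol(maps)
  act <- array(maps, dim = c(length(grid$x), length(grid$y), nt))
  if (nt == 1) act <- act[, , 1]
  structure(list(activity = act, grid_x = grid$x, grid_y = grid$y,
                 grid_t = if (nt > 1) grid$t[seq_len(nt)] else NULL,
                 anchor_xy = as.matrix(anchor_xy),
                 neuron_id = neuron_id, condition = condition),
            class = "tuning_field")
}

#' Average a tuning field over a peri-saccadic time window
#'
#' @param field A `tuning_field` with a time axis.
#' @param t_lo,t_hi Window bounds, ms (inclusive); default the broad
#'   -100..+100 ms peri-saccadic window.
#' @return Spatial map (matrix x by y) of mean rates.
#' @export
window_average <- function(field, t_lo = -100, t_hi = 100) {
  stopifnot(inherits(field, "tuning_field"), !is.null(field$grid_t))
  sel <- which(field$grid_t >= t_lo & field$grid_t <= t_hi)
  if (!length(sel)) stop("empty time window")
  if (length(sel) == 1) return(field$activity[, , sel])
  apply(field$activity[, , sel, drop = FALSE], c(1, 2), mean)
}

#' Similarity between regular and interceptive activity maps
#'
#' Both maps are z-transformed entrywise (subtract the map mean, divide by
#' the map SD), then
#' `SI = 1 - ||z(R) - z(I)||_F / (||z(R)||_F + ||z(I)||_F)`,
#' which lies in `[0, 1]` and equals 1 iff the z-maps are identical.
#' The Pearson correlation of the flattened maps is returned alongside.
#' With full standardization the SI is invariant to positive affine
#' rescaling of either map; a `center_only` variant (subtract the mean
#' only) retains sensitivity to amplitude differences.
#'
#' @param map_r,map_i Numeric matrices/vectors of identical shape,
#'   non-constant.
#' @param method `"standardize"` (default) or `"center_only"`.
#' @return List: `pearson_r`, `si`, `degenerate` (TRUE when either map is
#'   constant, in which case `si` and `pearson_r` are NA).
#' @export
similarity_index <- function(map_r, map_i,
                             method = c("standardize", "center_only")) {
  method <- match.arg(method)
  r <- as.numeric(map_r); i <- as.numeric(map_i)
  stopifnot(length(r) == length(i))
  if (stats::sd(r) == 0 || stats::sd(i) == 0) {
    return(list(pearson_r = NA_real_, si = NA_real_, degenerate = TRUE))
  }
  z <- function(v) {
    if (method == "standardize") (v - mean(v)) / stats::sd(v)
    else v - mean(v)
  }
  zr <- z(r); zi <- z(i)
  fro <- function(v) sqrt(sum(v^2))
  si <- 1 - fro(zr - zi) / (fro(zr) + fro(zi))
  list(pearson_r = stats::cor(r, i), si = si, degenerate = FALSE)
}

#' Select the subpopulation with similar regular/interceptive tuning
#'
#' Strict thresholds ("larger than"): neurons with Pearson r > `r_min` and
#' SI > `si_min`.
#'
#' @param similarity data.frame/data.table with columns `neuron_id`,
#'   `pearson_r`, `si`.
#' @param r_min,si_min Thresholds (defaults 0.5 and 0.3).
#' @return Character vector of selected neuron ids.
#' @export
select_subpopulation <- function(similarity, r_min = 0.5, si_min = 0.3) {
  sel <- !is.na(similarity$pearson_r) & !is.na(similarity$si) &
    similarity$pearson_r > r_min & similarity$si > si_min
  as.character(similarity$neuron_id[sel])
}
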