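#' Stationary-target layout
#'
#' The 17 stationary saccade-target positions: the screen center plus the
#' eight cardinal/oblique directions at eccentricities of 2 and 4 degrees.
#' These coincide with the positions a 10 deg/s moving target reaches after
#' 200 ms and 400 ms of motion, i.e. with the typical landing zone of
#' interceptive saccades.
#'
#' @return A data.frame with columns `x`, `y` (degrees, screen-centered,
#'   x rightward, y upward) and `position_id`; 17 rows, first row is the
#'   center (0, 0).
#' @export
stationary_target_layout <- function() {
  dirs <- seq(0, 315, by = 45)
  xy <- rbind(
    c(0, 0),
    t(vapply(dirs, function(d) 2 * unit_vec(d), numeric(2))),
    t(vapply(dirs, function(d) 4 * unit_vec(d), numeric(2)))
  )
  xy <- round(xy, 12)  # clean up cos/sin of multiples of 90 deg
  data.frame(position_id = seq_len(nrow(xy)), x = xy[, 1], y = xy[, 2])
}

#' Interceptive target motion directions
#'
#' The eight directions of target motion used in the interceptive trials,
#' in degrees counter-clockwise from the positive x axis.
#'
#' @return Numeric vector of 8 directions (0, 45, ..., 315).
#' @export
interceptive_directions <- function() seq(0, 315, by = 45)
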