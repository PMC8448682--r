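#' Regular-vs-interceptive tuning similarity for every neuron
#'
#' Builds each neuron's window-averaged spatial activity map for regular
#' and interceptive saccades (from all detected trials) and computes the
#' Pearson correlation and similarity index between them. Because the
#' interceptive end-positions cover only the central ~1.5 deg, the
#' comparison is restricted to grid nodes within `mask_radius` of the
#' screen center.
#'
#' @param session A `saccade_session`.
#' @param saccades Output of [detect_saccades()].
#' @param window Peri-saccadic window, ms.
#' @param mask_radius Comparison region radius, deg.
#' @param method z-transform variant passed to [similarity_index()].
#' @return data.table: `neuron_id`, `pearson_r`, `si`, `degenerate`.
#' @export
similarity_analysis <- function(session, saccades, window = c(-100, 100),
                                mask_radius = 1.5,
                                method = "standardize") {
  grid <- tuning_grid()
  anchors <- compute_anchors(saccades)
  aligned <- align_spikes(session, saccades)
  neuron_ids <- vapply(session$cohort, `[[`, "", "neuron_id")
  q <- expand.grid(x = grid$x, y = grid$y)
  mask <- sqrt(q$x^2 + q$y^2) <= mask_radius
  W_reg <- interp_weights(as.matrix(anchors$regular[, c("x", "y")]),
                          q$x, q$y)$W
  W_int <- interp_weights(as.matrix(anchors$interceptive[, c("x", "y")]),
                          q$x, q$y)$W
  resp_reg <- anchor_responses(aligned, trials_by_anchor_regular(saccades),
                               neuron_ids, grid$t)
  resp_int <- anchor_responses(aligned, trials_by_anchor_interceptive(saccades),
                               neuron_ids, grid$t)
  maps_reg <- maps_from_responses(resp_reg, W_reg, grid$t,
                                  window[1], window[2])
  maps_int <- maps_from_responses(resp_int, W_int, grid$t,
                                  window[1], window[2])
  data.table::rbindlist(lapply(seq_along(neuron_ids), function(j) {
    s <- similarity_index(maps_reg[mask, j], maps_int[mask, j],
                          method = method)
    data.table::data.table(neuron_id = neuron_ids[j],
                           pearson_r = s$pearson_r, si = s$si,
                           degenerate = s$degenerate)
  }))
}
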