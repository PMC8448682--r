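# Pipeline layer: from a simulated session + detected saccades to the
# decoding statistics. All functions here are deterministic given their
# seed arguments.

#' Anchor end-positions per condition
#'
#' Regular anchors are the mean detected saccade end-positions per
#' stationary target position (17); interceptive anchors the mean
#' end-positions per motion direction (8). The interceptive anchors double
#' as the "tested positions" of the decoding analysis.
#'
#' @param saccades Output of [detect_saccades()].
#' @return List of two data.tables `regular` (`anchor_id`, `position_id`,
#'   `x`, `y`, `n`) and `interceptive` (`anchor_id`, `direction`, `x`,
#'   `y`, `n`).
#' @export
compute_anchors <- function(saccades) {
  s <- saccades[saccades$detected]
  reg <- s[s$condition == "regular",
           .(x = mean(post_x), y = mean(post_y), n = .N),
           by = "position_id"]
  data.table::setorder(reg, position_id)
  reg[, anchor_id := seq_len(.N)]
  int <- s[s$condition == "interceptive",
           .(x = mean(post_x), y = mean(post_y), n = .N),
           by = "direction"]
  data.table::setorder(int, direction)
  int[, anchor_id := seq_len(.N)]
  list(regular = reg, interceptive = int)
}

#' Align spike times to detected saccade onsets
#'
#' @param session A `saccade_session`.
#' @param saccades Output of [detect_saccades()].
#' @return data.table `trial_id`, `neuron_id`, `t_al` (ms relative to the
#'   detected saccade onset); undetected trials are dropped.
#' @export
align_spikes <- function(session, saccades) {
  det <- saccades[saccades$detected, c("trial_id", "onset")]
  sp <- merge(session$spikes, det, by = "trial_id")
  sp[, t_al := t_ms - onset]
  sp[, c("trial_id", "neuron_id", "t_al")]
}

# Response functions per (neuron, anchor) for a given trial grouping.
# trials_by_anchor: list of trial-id vectors, one per anchor.
# Returns a list over neurons of n_anchor x n_t matrices.
anchor_responses <- function(aligned, trials_by_anchor, neuron_ids,
                             grid_t = tuning_grid()$t, sigma = 20) {
  lapply(neuron_ids, function(nid) {
    spn <- aligned[aligned$neuron_id == nid]
    t(vapply(trials_by_anchor, function(ids) {
      byt <- split(spn$t_al[spn$trial_id %in% ids],
                   factor(spn$trial_id[spn$trial_id %in% ids],
                          levels = ids))
      response_function(byt, grid_t, sigma)
    }, numeric(length(grid_t))))
  })
}

# Window-average anchor responses and interpolate to the spatial grid.
# Returns a (nx*ny) x n_neurons matrix of rates.
maps_from_responses <- function(resp_list, W, grid_t, t_lo, t_hi) {
  sel <- which(grid_t >= t_lo & grid_t <= t_hi)
  V <- vapply(resp_list, function(m) rowMeans(m[, sel, drop = FALSE]),
              numeric(nrow(resp_list[[1]])))
  W %*% V
}

trials_by_anchor_regular <- function(saccades, trial_subset = NULL) {
  s <- saccades[saccades$detected & saccades$condition == "regular"]
  if (!is.null(trial_subset)) s <- s[s$trial_id %in% trial_subset]
  split(s$trial_id, s$position_id)
}

trials_by_anchor_interceptive <- function(saccades) {
  s <- saccades[saccades$detected & saccades$condition == "interceptive"]
  split(s$trial_id, s$direction)
}

#' Run the end-position decoding experiment
#'
#' Full decoding analysis for one session: stratified 70/30 splits of the
#' regular trials; per split, tuning maps from the training trials, a
#' Poisson pseudo-population, a shallow-network decoder, and evaluation at
#' the 8 tested positions (mean interceptive end-positions) with
#' (1) regular validation maps and (2) interceptive maps built from all
#' interceptive trials. Statistics are averaged across splits (mean of
#' per-split values, no pooling of trials before averaging).
#'
#' @param session A `saccade_session`.
#' @param saccades Output of [detect_saccades()].
#' @param window Peri-saccadic time window, ms.
#' @param n_splits Number of train/validation splits.
#' @param n_pseudo Pseudo-trials for training per split.
#' @param n_eval Evaluation pseudo-trials per tested position per split.
#' @param maxit Decoder optimizer iterations.
#' @param seed Master seed (per-split substreams are derived from it).
#' @param neurons Optional character vector restricting the population
#'   (e.g. from [select_subpopulation()]).
#' @return List of class `decode_evaluation`; see elements `tested`,
#'   `summary` (per condition), `per_position`, `models`, `maps`.
#' @export
run_decoding_experiment <- function(session, saccades,
                                    window = c(-100, 100),
                                    n_splits = 5, n_pseudo = 20000,
                                    n_eval = 100, maxit = 500, seed = 1,
                                    neurons = NULL) {
  grid <- tuning_grid()
  anchors <- compute_anchors(saccades)
  aligned <- align_spikes(session, saccades)
  neuron_ids <- vapply(session$cohort, `[[`, "", "neuron_id")
  if (!is.null(neurons)) neuron_ids <- intersect(neuron_ids, neurons)
  if (!length(neuron_ids)) stop("no neurons to decode from")

  q <- expand.grid(x = grid$x, y = grid$y)
  W_reg <- interp_weights(as.matrix(anchors$regular[, c("x", "y")]),
                          q$x, q$y)$W
  W_int <- interp_weights(as.matrix(anchors$interceptive[, c("x", "y")]),
                          q$x, q$y)$W
  tested <- anchors$interceptive
  tested_xy <- as.matrix(tested[, c("x", "y")])
  dur_s <- (window[2] - window[1]) / 1000

  resp_int <- anchor_responses(aligned, trials_by_anchor_interceptive(saccades),
                               neuron_ids, grid$t)
  maps_int <- maps_from_responses(resp_int, W_int, grid$t,
                                  window[1], window[2])

  reg_sacc <- saccades[saccades$detected & saccades$condition == "regular"]
  splits <- split_trials(reg_sacc$trial_id, reg_sacc$position_id,
                         n_repeats = n_splits,
                         seed = derive_seed(seed, 1))

  eval_pos <- tested_xy[rep(seq_len(nrow(tested_xy)), each = n_eval), ]
  eval_idx <- rep(seq_len(nrow(tested_xy)), each = n_eval)

  per_split <- vector("list", n_splits)
  models <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    resp_tr <- anchor_responses(
      aligned, trials_by_anchor_regular(saccades, splits[[s]]$train),
      neuron_ids, grid$t)
    resp_va <- anchor_responses(
      aligned, trials_by_anchor_regular(saccades, splits[[s]]$validate),
      neuron_ids, grid$t)
    maps_tr <- maps_from_responses(resp_tr, W_reg, grid$t,
                                   window[1], window[2])
    maps_va <- maps_from_responses(resp_va, W_reg, grid$t,
                                   window[1], window[2])
    ps <- pseudo_trials_from_maps(maps_tr, grid, dur_s, n_pseudo,
                                  seed = derive_seed(seed, 2, s))
    model <- train_decoder(ps$counts, ps$positions, maxit = maxit,
                           seed = derive_seed(seed, 3, s))
    models[[s]] <- model

    eval_one <- function(maps_cond, cond, sub_seed) {
      pe <- pseudo_trials_from_maps(maps_cond, grid, dur_s,
                                    positions = eval_pos,
                                    n = nrow(eval_pos),
                                    seed = derive_seed(seed, sub_seed, s))
      pred <- predict_endpoints(model, pe$counts)
      cmx <- confusion_matrix(pred, eval_idx, tested_xy)
      pp <- data.table::rbindlist(lapply(seq_len(nrow(tested_xy)), function(i) {
        pr <- pred[eval_idx == i, , drop = FALSE]
        mp <- colMeans(pr)
        data.table::data.table(
          split = s, condition = cond, anchor_id = i,
          tested_x = tested_xy[i, 1], tested_y = tested_xy[i, 2],
          mean_x = mp[1], mean_y = mp[2],
          sd_x = stats::sd(pr[, 1]), sd_y = stats::sd(pr[, 2]),
          center_bias = center_bias(tested_xy[i, ], mp,
                                    tested$direction[i]),
          error = sqrt(sum((mp - tested_xy[i, ])^2)))
      }))
      list(per_position = pp, confusion = cmx)
    }
    ev_reg <- eval_one(maps_va, "regular", 4)
    ev_int <- eval_one(maps_int, "interceptive", 5)
    per_split[[s]] <- list(regular = ev_reg, interceptive = ev_int)
  }

  per_position <- data.table::rbindlist(lapply(per_split, function(x)
    rbind(x$regular$per_position, x$interceptive$per_position)))
  agg <- per_position[, .(
    mean_x = mean(mean_x), mean_y = mean(mean_y),
    sd_x = mean(sd_x), sd_y = mean(sd_y),
    center_bias = mean(center_bias), split_error = mean(error)),
    by = c("condition", "anchor_id", "tested_x", "tested_y")]
  # accuracy of the prediction combined over all trained networks:
  # distance of the across-split mean prediction from the tested position
  agg[, error := sqrt((mean_x - tested_x)^2 + (mean_y - tested_y)^2)]
  summarize_cond <- function(cond, which_cm) {
    cms <- lapply(per_split, function(x) x[[which_cm]]$confusion)
    list(
      mean_error = mean(agg$error[agg$condition == cond]),
      mean_split_error = mean(agg$split_error[agg$condition == cond]),
      mean_center_bias = mean(agg$center_bias[agg$condition == cond]),
      pct_correct = mean(vapply(cms, `[[`, 1, "pct_correct")),
      pct_correct_or_neighbor =
        mean(vapply(cms, `[[`, 1, "pct_correct_or_neighbor")),
      confusion = Reduce(`+`, lapply(cms, `[[`, "confusion")) / length(cms))
  }
  structure(list(
    tested = tested, per_position = agg, per_split_position = per_position,
    summary = list(regular = summarize_cond("regular", "regular"),
                   interceptive = summarize_cond("interceptive",
                                                 "interceptive")),
    models = models, maps_interceptive = maps_int,
    window = window, n_splits = n_splits, n_pseudo = n_pseudo,
    neuron_ids = neuron_ids, seed = seed),
    class = "decode_evaluation")
}

#' Prediction error field over the central workspace
#'
#' For each query position, draws Poisson pseudo-trials from the given
#' condition maps, decodes them with each model, and reports the mean
#' error vector (tested - predicted), its direction, and magnitude,
#' averaged over models. A radial (centripetal) compression shows up as
#' error vectors aligned with the outward position direction, i.e.
#' predictions shifted toward the center.
#'
#' @param models A `decoder_model` or list of them (one per split).
#' @param maps_mat (nx*ny) x n_neurons rate map matrix for the evaluated
#'   condition.
#' @param positions m x 2 matrix of query positions (default: square grid
#'   of step 0.5 deg over +/-1.5 deg).
#' @param duration_s Window duration in seconds used for expected counts.
#' @param n_draws Pseudo-trials per position per model.
#' @param seed Seed.
#' @param grid Spatial grid of the maps.
#' @return data.table: `x`, `y`, `err_x`, `err_y` (tested - predicted),
#'   `magnitude`, `direction` (deg), `radial` (signed radial error
#'   component; positive = prediction compressed toward the center).
#' @export
error_field <- function(models, maps_mat, positions = NULL,
                        duration_s = 0.2, n_draws = 100, seed = 1,
                        grid = tuning_grid()) {
  if (inherits(models, "decoder_model")) models <- list(models)
  if (is.null(positions)) {
    positions <- as.matrix(expand.grid(x = seq(-1.5, 1.5, 0.5),
                                       y = seq(-1.5, 1.5, 0.5)))
  }
  m <- nrow(positions)
  err <- matrix(0, m, 2)
  for (k in seq_along(models)) {
    ps <- pseudo_trials_from_maps(
      maps_mat, grid, duration_s,
      positions = positions[rep(seq_len(m), each = n_draws), ],
      n = m * n_draws, seed = derive_seed(seed, k))
    pred <- predict_endpoints(models[[k]], ps$counts)
    for (i in seq_len(m)) {
      mp <- colMeans(pred[((i - 1) * n_draws + 1):(i * n_draws), ,
                          drop = FALSE])
      err[i, ] <- err[i, ] + (positions[i, ] - mp)
    }
  }
  err <- err / length(models)
  rr <- sqrt(rowSums(positions^2))
  ux <- ifelse(rr > 0, positions[, 1] / rr, 0)
  uy <- ifelse(rr > 0, positions[, 2] / rr, 0)
  data.table::data.table(
    x = positions[, 1], y = positions[, 2],
    err_x = err[, 1], err_y = err[, 2],
    magnitude = sqrt(rowSums(err^2)),
    direction = atan2(err[, 2], err[, 1]) * 180 / pi,
    radial = err[, 1] * ux + err[, 2] * uy)
}

#' Sliding-window decoding time course
#'
#' Trains a separate decoder for every 100 ms window (shifted in 50 ms
#' steps between 400 ms before and 350 ms after saccade onset: 14 windows)
#' and every split, evaluates both conditions at the 8 tested positions,
#' and reports the center-bias and prediction-SD time courses plus a
#' paired t test (across the 8 positions, regular vs interceptive) per
#' window.
#'
#' @inheritParams run_decoding_experiment
#' @param window_width,window_step Window geometry, ms.
#' @param t_range Full analysis range, ms.
#' @return List of class `sliding_evaluation`: `windows` (data.table with
#'   one row per window x condition) and `tests` (per-window paired
#'   t test p-values and significance at p < 0.01).
#' @export
sliding_window_analysis <- function(session, saccades,
                                    n_splits = 5, n_pseudo = 4000,
                                    n_eval = 100, maxit = 120, seed = 1,
                                    window_width = 100, window_step = 50,
                                    t_range = c(-400, 350),
                                    neurons = NULL) {
  grid <- tuning_grid()
  anchors <- compute_anchors(saccades)
  aligned <- align_spikes(session, saccades)
  neuron_ids <- vapply(session$cohort, `[[`, "", "neuron_id")
  if (!is.null(neurons)) neuron_ids <- intersect(neuron_ids, neurons)

  q <- expand.grid(x = grid$x, y = grid$y)
  W_reg <- interp_weights(as.matrix(anchors$regular[, c("x", "y")]),
                          q$x, q$y)$W
  W_int <- interp_weights(as.matrix(anchors$interceptive[, c("x", "y")]),
                          q$x, q$y)$W
  tested <- anchors$interceptive
  tested_xy <- as.matrix(tested[, c("x", "y")])
  k <- nrow(tested_xy)
  dur_s <- window_width / 1000

  centers <- seq(t_range[1] + window_width / 2,
                 t_range[2] - window_width / 2, by = window_step)

  resp_int <- anchor_responses(aligned, trials_by_anchor_interceptive(saccades),
                               neuron_ids, grid$t)
  reg_sacc <- saccades[saccades$detected & saccades$condition == "regular"]
  splits <- split_trials(reg_sacc$trial_id, reg_sacc$position_id,
                         n_repeats = n_splits,
                         seed = derive_seed(seed, 1))
  resp_tr <- lapply(splits, function(sp)
    anchor_responses(aligned, trials_by_anchor_regular(saccades, sp$train),
                     neuron_ids, grid$t))
  resp_va <- lapply(splits, function(sp)
    anchor_responses(aligned, trials_by_anchor_regular(saccades, sp$validate),
                     neuron_ids, grid$t))

  eval_pos <- tested_xy[rep(seq_len(k), each = n_eval), ]
  eval_idx <- rep(seq_len(k), each = n_eval)

  rows <- list(); tests <- list()
  for (w in seq_along(centers)) {
    t_lo <- centers[w] - window_width / 2
    t_hi <- centers[w] + window_width / 2
    maps_int <- maps_from_responses(resp_int, W_int, grid$t, t_lo, t_hi)
    bias_mat <- array(NA_real_, dim = c(n_splits, k, 2))  # cond x pos
    sd_mat <- array(NA_real_, dim = c(n_splits, 2))
    for (s in seq_len(n_splits)) {
      maps_tr <- maps_from_responses(resp_tr[[s]], W_reg, grid$t, t_lo, t_hi)
      maps_va <- maps_from_responses(resp_va[[s]], W_reg, grid$t, t_lo, t_hi)
      ps <- pseudo_trials_from_maps(maps_tr, grid, dur_s, n_pseudo,
                                    seed = derive_seed(seed, w, s))
      model <- train_decoder(ps$counts, ps$positions, maxit = maxit,
                             seed = derive_seed(seed, 100 + w, s))
      for (ci in 1:2) {
        mm <- if (ci == 1) maps_va else maps_int
        pe <- pseudo_trials_from_maps(mm, grid, dur_s,
                                      positions = eval_pos,
                                      n = nrow(eval_pos),
                                      seed = derive_seed(seed, 200 * ci + w, s))
        pred <- predict_endpoints(model, pe$counts)
        sds <- numeric(k)
        for (i in seq_len(k)) {
          pr <- pred[eval_idx == i, , drop = FALSE]
          bias_mat[s, i, ci] <- center_bias(tested_xy[i, ], colMeans(pr),
                                            tested$direction[i])
          sds[i] <- mean(c(stats::sd(pr[, 1]), stats::sd(pr[, 2])))
        }
        sd_mat[s, ci] <- mean(sds)
      }
    }
    # mean over splits first, then positions (no pooling across trials)
    bias_pos <- apply(bias_mat, c(2, 3), mean)  # k x 2
    tt <- stats::t.test(bias_pos[, 2], bias_pos[, 1], paired = TRUE)
    for (ci in 1:2) {
      rows[[length(rows) + 1]] <- data.table::data.table(
        window_center = centers[w], t_lo = t_lo, t_hi = t_hi,
        condition = c("regular", "interceptive")[ci],
        center_bias = mean(bias_pos[, ci]),
        bias_sd = stats::sd(bias_pos[, ci]),
        pred_sd = mean(sd_mat[, ci]))
    }
    tests[[w]] <- data.table::data.table(
      window_center = centers[w], p_value = tt$p.value,
      significant = tt$p.value < 0.01,
      bias_difference = mean(bias_pos[, 2] - bias_pos[, 1]))
  }
  structure(list(windows = data.table::rbindlist(rows),
                 tests = data.table::rbindlist(tests),
                 tested = tested, n_splits = n_splits,
                 n_pseudo = n_pseudo, seed = seed),
            class = "sliding_evaluation")
}
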