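# Stage 4: population decoding.
#
# Trains shallow networks (105 -> 20 -> 20 -> 2) on Poisson
# pseudo-populations drawn from the regular-saccade tuning maps and
# evaluates them at the 8 mean interceptive end-positions: once with
# regular validation maps, once with interceptive maps. Reports assignment
# percentages, center bias, the recovered snapshot displacement, and the
# prediction error field over the central workspace.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_config.R"))

session <- run_session()
saccades <- detect_saccades(session)
ev <- run_decoding_experiment(session, saccades, n_splits = RUN$n_splits,
                              n_pseudo = RUN$n_pseudo, n_eval = RUN$n_eval,
                              maxit = RUN$maxit, seed = RUN$decode_seed)
dir <- out_dir("decoding")
data.table::fwrite(ev$per_position, file.path(dir, "per_position.csv"))
for (cond in c("regular", "interceptive")) {
  data.table::fwrite(data.table::as.data.table(ev$summary[[cond]]$confusion),
                     file.path(dir, paste0("confusion_", cond, ".csv")))
}

r <- ev$summary$regular; i <- ev$summary$interceptive
snapshot <- i$mean_center_bias - r$mean_center_bias
cat(sprintf("regular:      anchor error %.2f deg, bias %.2f deg, %.0f%% correct, %.0f%% correct-or-neighbor\n",
            r$mean_error, r$mean_center_bias, r$pct_correct,
            r$pct_correct_or_neighbor))
cat(sprintf("interceptive: bias %.2f deg, %.0f%% correct, %.0f%% correct-or-neighbor\n",
            i$mean_center_bias, i$pct_correct, i$pct_correct_or_neighbor))
cat(sprintf("snapshot displacement %.2f deg = %.0f ms of target motion\n",
            snapshot, bias_to_time_lag(snapshot, 10)))

ring <- cbind(1.5 * cos(seq(0, 315, 45) * pi / 180),
              1.5 * sin(seq(0, 315, 45) * pi / 180))
ef <- error_field(ev$models, ev$maps_interceptive,
                  positions = rbind(ring, c(0, 0)), n_draws = 150,
                  seed = RUN$decode_seed + 1)
data.table::fwrite(ef, file.path(dir, "error_field.csv"))
cat(sprintf("error field: %d of 8 eccentric nodes centripetal; center magnitude %.2f deg\n",
            sum(ef$radial[1:8] > 0), ef$magnitude[9]))

summary <- list(
  regular = r[c("mean_error", "mean_center_bias", "pct_correct",
                "pct_correct_or_neighbor")],
  interceptive = i[c("mean_error", "mean_center_bias", "pct_correct",
                     "pct_correct_or_neighbor")],
  snapshot_bias_deg = snapshot,
  snapshot_lag_ms = bias_to_time_lag(snapshot, 10))
jsonlite::write_json(summary, file.path(dir, "summary.json"),
                     auto_unbox = TRUE, digits = NA)
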