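# Stage 5: time course of end-position information.
#
# Retrains the decoder in 100 ms windows stepped by 50 ms across the
# peri-saccadic epoch and tracks the center bias of both conditions. With
# a -50 ms snapshot offset the interceptive bias minimum should trail the
# regular minimum by one window step; a tau = 0 control cohort should show
# no significant condition differences.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_config.R"))

dir <- out_dir("sliding")
for (tau in c(RUN$tau, 0)) {
  session <- run_session(tau = tau)
  saccades <- detect_saccades(session)
  sl <- sliding_window_analysis(session, saccades, n_splits = RUN$n_splits,
                                n_pseudo = 4000, n_eval = RUN$n_eval,
                                maxit = 200, seed = RUN$sliding_seed)
  tag <- paste0("tau", tau)
  data.table::fwrite(sl$windows, file.path(dir, paste0("windows_", tag, ".csv")))
  data.table::fwrite(sl$tests, file.path(dir, paste0("tests_", tag, ".csv")))
  argmin <- function(cond) {
    x <- sl$windows[sl$windows$condition == cond, ]
    x$window_center[which.min(x$center_bias)]
  }
  cat(sprintf("tau = %d ms: bias minima regular %d ms, interceptive %d ms; %d significant windows\n",
              tau, argmin("regular"), argmin("interceptive"),
              sum(sl$tests$significant)))
}
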