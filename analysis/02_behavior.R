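# Stage 2: oculomotor analysis.
#
# Detects saccades with the double velocity criterion (100 deg/s trigger,
# 30 deg/s bounds on the smoothed trace), fits 2-D Gaussians to the
# interceptive end-positions per motion direction, and regresses the
# intercept (motion-aligned endpoint component) on the time of saccade
# end. If the oculomotor system compensates target motion, that slope
# matches the target speed (10 deg/s).

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_config.R"))

session <- run_session()
saccades <- detect_saccades(session)
dir <- out_dir("behavior")
data.table::fwrite(saccades, file.path(dir, "saccades.csv"))

cat(sprintf("detected %d / %d saccades\n", sum(saccades$detected),
            nrow(saccades)))

# endpoint ellipses per motion direction
samples <- intercept_samples(saccades)
ell <- data.table::rbindlist(lapply(split(samples, samples$alpha), function(d) {
  f <- fit_endpoint_gaussian(cbind(d$x, d$y))
  data.table::data.table(direction = d$alpha[1], mean_x = f$mean[1],
                         mean_y = f$mean[2], sd_major = f$axes[1],
                         sd_minor = f$axes[2], angle = f$angle, n = nrow(d))
}))
data.table::fwrite(ell, file.path(dir, "endpoint_ellipses.csv"))
cat(sprintf("mean interceptive deflection %.2f deg\n",
            mean(sqrt(ell$mean_x^2 + ell$mean_y^2))))

# a larger behavioral cohort for a stable regression estimate
beh <- simulate_session(list(), session_config(
  n_regular_per_position = 1, n_interceptive_per_direction = 625,
  seed = RUN$session_seed + 100))
reg <- intercept_time_regression(intercept_samples(detect_saccades(beh)),
                                 n_boot = 2000, seed = RUN$decode_seed)
jsonlite::write_json(reg, file.path(dir, "intercept_regression.json"),
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("intercept vs end time: slope %.2f deg/s (99%% CI %.2f..%.2f), offset %.3f deg, r = %.3f\n",
            reg$slope, reg$slope_ci[1], reg$slope_ci[2], reg$offset,
            reg$pearson_r))
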