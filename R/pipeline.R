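#' Default pipeline configuration
#'
#' Returns the full run configuration as a plain list (serializable to
#' YAML/JSON). The defaults reflect the study conditions (105 neurons,
#' 10/15 trials per stationary position/motion direction, 50 splits,
#' 100000 pseudo-trials); smaller profiles for quick runs are obtained by
#' overriding fields, e.g. `default_config(n_neurons = 20, n_splits = 5,
#' n_pseudo = 20000)`.
#'
#' @param ... Named overrides of any configuration field.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    n_neurons = 105,
    tau = -50,
    n_regular_per_position = 10,
    n_interceptive_per_direction = 15,
    target_speed = 10,
    latency_mean = 134, latency_sd = 44,
    duration_mean = 36, duration_sd = 8.9,
    endpoint_noise_sd = 0.8,
    window = c(-100, 100),
    train_frac = 0.7,
    n_splits = 50,
    n_pseudo = 100000,
    n_eval = 100,
    maxit = 500,
    subpop_r_min = 0.5,
    subpop_si_min = 0.3,
    run_sliding = FALSE,
    n_boot = 2000,
    seed = 1,
    out_dir = "results/run"
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with any subset of the [default_config()] fields.
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' Validate a run configuration
#'
#' @param cfg A `run_config`.
#' @return Character vector of issues; empty when the config is runnable.
#' @export
validate_config <- function(cfg) {
  p <- character(0)
  chk <- function(cond, msg) if (cond) p <<- c(p, msg)
  chk(cfg$n_neurons < 1, "n_neurons must be >= 1")
  chk(cfg$target_speed <= 0, "target_speed must be > 0")
  chk(cfg$n_regular_per_position < 2,
      "need >= 2 regular trials per position for 70/30 splits")
  chk(cfg$n_interceptive_per_direction < 1,
      "n_interceptive_per_direction must be >= 1")
  chk(cfg$train_frac <= 0 || cfg$train_frac >= 1,
      "train_frac must be in (0, 1): both split halves must be non-empty")
  chk(cfg$n_splits < 1, "n_splits must be >= 1")
  chk(cfg$n_pseudo < 1, "n_pseudo must be >= 1")
  chk(cfg$window[2] <= cfg$window[1], "empty analysis window")
  chk(cfg$latency_mean <= 0 || cfg$duration_mean <= 0 ||
        cfg$latency_sd < 0 || cfg$duration_sd < 0,
      "non-physical latency/duration parameters")
  chk(cfg$endpoint_noise_sd < 0, "endpoint_noise_sd must be >= 0")
  p
}

#' Run the full analysis pipeline
#'
#' Executes generate -> detect -> behavioral statistics -> similarity ->
#' decode (optionally -> sliding windows) and writes all result tables plus
#' a run manifest under `cfg$out_dir`. A run is fully reproducible from the
#' configuration alone.
#'
#' @param cfg A `run_config` from [default_config()] / [read_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(cfg = default_config(), quiet = FALSE) {
  issues <- validate_config(cfg)
  if (length(issues))
    stop("config stage: invalid configuration: ",
         paste(issues, collapse = "; "))
  say <- function(...) if (!quiet) message(...)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("%s stage: %s", name, conditionMessage(e)), call. = FALSE))
    say(sprintf("[%s] done in %.1f s", name,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  session <- stage("simulate", {
    cohort <- make_cohort(cfg$n_neurons, tau = cfg$tau,
                          seed = derive_seed(cfg$seed, 11))
    simulate_session(cohort, session_config(
      n_regular_per_position = cfg$n_regular_per_position,
      n_interceptive_per_direction = cfg$n_interceptive_per_direction,
      target_speed = cfg$target_speed,
      latency_mean = cfg$latency_mean, latency_sd = cfg$latency_sd,
      duration_mean = cfg$duration_mean, duration_sd = cfg$duration_sd,
      endpoint_noise_sd = cfg$endpoint_noise_sd,
      seed = derive_seed(cfg$seed, 12)))
  })

  saccades <- stage("detect", detect_saccades(session))
  behavior <- stage("behavior", {
    ints <- intercept_samples(saccades)
    reg <- intercept_time_regression(ints, n_boot = cfg$n_boot,
                                     seed = derive_seed(cfg$seed, 13))
    ellipses <- lapply(split(ints, ints$alpha), function(d)
      fit_endpoint_gaussian(cbind(d$x, d$y)))
    list(intercepts = ints, regression = reg, ellipses = ellipses)
  })
  similarity <- stage("similarity",
                      similarity_analysis(session, saccades,
                                          window = cfg$window))
  subpop <- select_subpopulation(similarity, cfg$subpop_r_min,
                                 cfg$subpop_si_min)
  decoding <- stage("decode",
    run_decoding_experiment(session, saccades, window = cfg$window,
                            n_splits = cfg$n_splits,
                            n_pseudo = cfg$n_pseudo,
                            n_eval = cfg$n_eval, maxit = cfg$maxit,
                            seed = derive_seed(cfg$seed, 14)))
  sliding <- NULL
  if (isTRUE(cfg$run_sliding)) {
    sliding <- stage("sliding",
      sliding_window_analysis(session, saccades,
                              n_splits = cfg$n_splits,
                              n_pseudo = min(cfg$n_pseudo, 4000),
                              n_eval = cfg$n_eval,
                              seed = derive_seed(cfg$seed, 15)))
  }

  stage("report", {
    data.table::fwrite(saccades, file.path(out, "saccades.csv"))
    data.table::fwrite(behavior$intercepts, file.path(out, "intercepts.csv"))
    data.table::fwrite(similarity, file.path(out, "similarity.csv"))
    data.table::fwrite(decoding$per_position,
                       file.path(out, "decoding_per_position.csv"))
    for (cond in c("regular", "interceptive")) {
      data.table::fwrite(
        data.table::as.data.table(decoding$summary[[cond]]$confusion),
        file.path(out, paste0("confusion_", cond, ".csv")))
    }
    if (!is.null(sliding)) {
      data.table::fwrite(sliding$windows, file.path(out, "sliding_windows.csv"))
      data.table::fwrite(sliding$tests, file.path(out, "sliding_tests.csv"))
    }
    summary <- list(
      regression = behavior$regression[c("slope", "offset", "pearson_r")],
      n_subpopulation = length(subpop),
      regular = decoding$summary$regular[
        c("mean_error", "mean_center_bias", "pct_correct",
          "pct_correct_or_neighbor")],
      interceptive = decoding$summary$interceptive[
        c("mean_error", "mean_center_bias", "pct_correct",
          "pct_correct_or_neighbor")],
      interceptive_lag_ms = bias_to_time_lag(
        decoding$summary$interceptive$mean_center_bias, cfg$target_speed))
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(
      package_version = as.character(utils::packageVersion("saccpop")),
      config = unclass(cfg),
      n_trials = nrow(session$trials),
      n_detected = sum(saccades$detected),
      outputs = list.files(out))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    NULL
  })

  invisible(list(session = session, saccades = saccades,
                 behavior = behavior, similarity = similarity,
                 subpopulation = subpop, decoding = decoding,
                 sliding = sliding, out_dir = out))
}
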