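# Shared configuration for the analysis workflow. Each numbered script
# regenerates what it needs deterministically from these seeds, so any
# script can be run on its own.

library(saccpop)

RUN <- list(
  n_neurons = 105,     # cohort size
  tau = -50,           # snapshot offset, ms relative to saccade end
  cohort_seed = 3,
  session_seed = 7,
  decode_seed = 5,
  sliding_seed = 11,
  n_splits = 5,        # train/validation splits (study condition: 50)
  n_pseudo = 20000,    # pseudo-trials per split (study condition: 100000)
  n_eval = 150,
  maxit = 500,
  results = "results"
)

run_session <- function(tau = RUN$tau) {
  cohort <- make_cohort(RUN$n_neurons, tau = tau, seed = RUN$cohort_seed)
  simulate_session(cohort, session_config(seed = RUN$session_seed))
}

out_dir <- function(...) {
  d <- file.path(RUN$results, ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
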