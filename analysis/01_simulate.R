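# Stage 1: generate the synthetic session.
#
# 105 neurons with 2-D Gaussian spatial tuning, peri-saccadic temporal
# profiles and a -50 ms snapshot offset; 10 regular trials for each of the
# 17 stationary positions and 15 interceptive trials for each of the 8
# motion directions (10 deg/s). Writes the behavioral and spiking record
# as plain-text tables for inspection; later stages regenerate the session
# deterministically from the shared seeds.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_config.R"))

session <- run_session()
dir <- out_dir("session")
write_session(session, dir)

cat(sprintf("simulated %d trials (%d regular, %d interceptive), %d neurons\n",
            nrow(session$trials),
            sum(session$trials$condition == "regular"),
            sum(session$trials$condition == "interceptive"),
            length(session$cohort)))
cat(sprintf("%d spikes written to %s\n", nrow(session$spikes), dir))
cat(sprintf("mean ground-truth latency %.0f ms, duration %.0f ms\n",
            mean(session$trials$latency), mean(session$trials$duration)))
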