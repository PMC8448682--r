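# Stage 3: tuning-field similarity.
#
# Builds each neuron's window-averaged (+/-100 ms) spatial activity map
# for regular and interceptive saccades and quantifies their similarity
# (Pearson r and similarity index) within the central 1.5 deg where both
# conditions are sampled. The subpopulation with r > 0.5 and SI > 0.3 is
# the "most similar tuning" sample used for restricted decoding.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_config.R"))

session <- run_session()
saccades <- detect_saccades(session)
sim <- similarity_analysis(session, saccades)
dir <- out_dir("tuning")
data.table::fwrite(sim, file.path(dir, "similarity.csv"))

sub <- select_subpopulation(sim)
writeLines(sub, file.path(dir, "subpopulation.txt"))

cat(sprintf("similarity over %d neurons: median r = %.2f, median SI = %.2f\n",
            nrow(sim), median(sim$pearson_r, na.rm = TRUE),
            median(sim$si, na.rm = TRUE)))
cat(sprintf("%d neurons pass r > 0.5 and SI > 0.3\n", length(sub)))
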