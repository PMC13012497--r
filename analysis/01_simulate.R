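#!/usr/bin/env Rscript
# Step 1 - Generate the synthetic serial-awakening cohort.
#
# Produces a study-scale dataset (44 participants x 4 nights of repeated
# N2 awakenings) with the design features the downstream analyses assume:
# participant random intercepts nested in two experiments, the five-level
# report taxonomy at the published mix, time-of-night trends in both
# ratings, phenomenology ratings for contentful dreams, and electrode
# band-power features tied to a latent cortical-activation variable.

library(dreamdepth)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cfg <- sim_config(n_electrodes = 64L, seed = 20260920L)
coh <- generate_cohort(cfg)

write_awakening_table(coh$records, file.path(out_dir, "awakenings.csv"))
write_sensor_array(coh$sensors, file.path(out_dir, "sensors.csv"))
for (b in names(coh$features)) {
  write_band_power_table(coh$features[[b]],
                         file.path(out_dir, sprintf("bandpower_%s.csv", b)))
}

cat("Cohort:", nrow(coh$records), "awakenings from",
    length(unique(coh$records$participant_id)), "participants\n")
cat("Report mix (three-level):\n")
print(round(100 * prop.table(table(coh$records$report3)), 1))
cat("Report mix (five-level):\n")
print(round(100 * prop.table(table(coh$records$report5)), 1))
cat("Wrote awakening table, sensor coordinates and band-power tables to",
    out_dir, "\n")
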