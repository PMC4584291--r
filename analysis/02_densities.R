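#!/usr/bin/env Rscript

# Stage 2: trajectory -> per-component density profiles.
#
# Reads the toy trajectory from stage 1, discards the equilibration
# fraction, recenters every frame on the hydrocarbon center of mass, and
# writes electron- and mass-weighted per-component profiles.

suppressPackageStartupMessages(library(bilayerff))

out <- "results"
cfg <- read_run_config(file.path(out, "run_config.yaml"))
log_run(cfg)
traj <- read_trajectory_jsonl(file.path(out, "traj_deep.jsonl.gz"))

for (w in c("electron", "mass")) {
  prof <- bin_density(traj, bin_width = cfg$bin_width, weighting = w,
                      equilibration_fraction = cfg$equilibration_fraction)
  prof_sym <- lapply(prof, symmetrize_profile)
  write_profile_table(prof_sym, file.path(out, paste0("profiles_", w, ".tsv")))
  pk <- peak_density(prof_sym$total)
  cat(sprintf("  %s profiles: %d components, peak %.3f at z = %.2f A\n",
              w, length(prof_sym) - 1L, pk$value, pk$z))
}

# form factor of the trajectory-derived profile, for stage 3 comparisons
prof <- bin_density(traj, bin_width = cfg$bin_width,
                    equilibration_fraction = cfg$equilibration_fraction)
ff <- profile_form_factor(symmetrize_profile(prof$total),
                          cfg$water_density,
                          seq(cfg$qz_min, cfg$qz_max, by = cfg$qz_step))
write_formfactor_table(ff, file.path(out, "ff_traj_deep.tsv"))
cat("  trajectory form factor -> ff_traj_deep.tsv\n")
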