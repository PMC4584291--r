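#!/usr/bin/env Rscript

# Stage 1: define the study systems and synthesize their inputs.
#
# Builds the DOPC:DOPE (1:1) model family (neat, and with arginine-rich
# peptide at prescribed depths), synthesizes noisy arbitrarily-scaled
# "experimental" form factors for the ground-truth conditions, and writes a
# toy bead trajectory for the deep-insertion system. Everything downstream
# (02-05) reads only these files.

suppressPackageStartupMessages(library(bilayerff))

out <- "results"
dir.create(out, showWarnings = FALSE)
cfg <- run_config(seed = 1L)
write_run_config(cfg, file.path(out, "run_config.yaml"))
log_run(cfg)

message("synthesizing experiments (seed ", cfg$seed, ") ...")

systems <- list(
  neat      = list(model = dopc_dope_model(66), label = "neat A_L = 66"),
  headgroup = list(model = dopc_dope_model(68, peptide_z = 18,
                                           n_peptides = 2),
                   label = "x = 0.015, z = 18, A_L = 68"),
  deep      = list(model = dopc_dope_model(72, peptide_z = 8,
                                           n_peptides = 2),
                   label = "x = 0.015, z = 8, A_L = 72"),
  x030      = list(model = dopc_dope_model(68, peptide_z = 18,
                                           n_peptides = 4),
                   label = "x = 0.030, z = 18, A_L = 68")
)

for (nm in names(systems)) {
  s <- systems[[nm]]
  exp_ff <- synthesize_experiment(s$model, noise_seed = cfg$seed,
                                  arbitrary_scale = 37)
  write_formfactor_table(exp_ff, file.path(out, paste0("exp_", nm, ".tsv")))
  cat(sprintf("  %-10s %s -> exp_%s.tsv (%d points)\n",
              nm, s$label, nm, length(exp_ff$qz)))
}

# Toy trajectory for the deep-insertion system (used by stages 2 and 4);
# sampling model shares the candidate geometry but carries no methyl trough
# (terminal-methyl beads sample the slab).
traj <- generate_trajectory(
  list(n_lipids = 128L, n_peptides = 2L, A_L = 72, peptide_depth_z = 8,
       n_ions = 8L, n_frames = 40L,
       model = dopc_dope_model(72, peptide_z = 8, n_peptides = 2,
                               ch3_excess = 0)),
  seed = cfg$seed)
write_trajectory_jsonl(traj, file.path(out, "traj_deep.jsonl.gz"))
cat(sprintf("  trajectory: %d frames, %d beads/frame -> traj_deep.jsonl.gz\n",
            length(traj$frames), nrow(traj$frames[[1]])))
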