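#!/usr/bin/env Rscript

# Stage 3: grid-scan model selection.
#
# Scores the full candidate grid (A_L = 62..76 A^2 by 2; peptide depth
# z = 0, 5, 8, 10, 12, 14, 16, 18 A; 2 replicates) against the synthetic
# experiments from stage 1, writes per-cell chi-square tables, repeat
# summaries at selected cells, and a heatmap of mean chi-square.

suppressPackageStartupMessages(library(bilayerff))

out <- "results"
cfg <- read_run_config(file.path(out, "run_config.yaml"))
log_run(cfg)
qz <- seq(cfg$qz_min, cfg$qz_max, by = cfg$qz_step)

scan_one <- function(exp_name, n_peptides) {
  exp_ff <- normalize_experimental(
    read_formfactor_table(file.path(out, paste0("exp_", exp_name, ".tsv"))),
    qz_break = cfg$delta_qz_break, delta_low = cfg$delta_low,
    delta_high = cfg$delta_high)
  cand <- candidate_grid(n_peptides = n_peptides, qz = qz,
                         replicates = 2L, jitter_sd = 0.002,
                         seed = cfg$seed)
  scan <- scan_grid(exp_ff, cand, cutoff = cfg$cutoff)
  write_scan_table(scan,
                   tsv_path = file.path(out, paste0("scan_", exp_name, ".tsv")),
                   json_path = file.path(out, paste0("scan_", exp_name, ".json")))
  ggplot2::ggsave(file.path(out, paste0("scan_", exp_name, ".png")),
                  plot_scan_heatmap(scan), width = 7, height = 5, dpi = 150)
  cat(sprintf("  %-10s best cell z = %2g A, A_L = %g A^2, mean chi^2 = %.2f; %d/%d cells accepted (chi^2 <= %.1f)\n",
              exp_name, scan$best_cell$z, scan$best_cell$A_L,
              scan$best_cell$mean_chi2, sum(scan$cells$accepted),
              nrow(scan$cells), cfg$cutoff))
  scan
}

cat("scanning x = 0.015 systems (2 peptides / 128 lipids):\n")
scan_head <- scan_one("headgroup", 2)
scan_deep <- scan_one("deep", 2)
cat("scanning x = 0.030 system (4 peptides / 128 lipids):\n")
scan_x030 <- scan_one("x030", 4)

# Repeat-simulation statistics at the three focal cells (50 jittered
# replicates each), summarized as mean +/- sd, min, max of chi-square.
cat("repeat statistics (50 replicates per cell):\n")
exp_head <- normalize_experimental(
  read_formfactor_table(file.path(out, "exp_headgroup.tsv")))
focal <- list(c(z = 18, A_L = 68), c(z = 8, A_L = 72), c(z = 0, A_L = 72))
rows <- lapply(focal, function(cell) {
  cand <- candidate_grid(n_peptides = 2, qz = qz,
                         A_L_values = cell[["A_L"]],
                         z_values = cell[["z"]],
                         replicates = 50L, jitter_sd = 0.002,
                         seed = cfg$seed + 7L)
  chi2 <- scan_grid(exp_head, cand, cutoff = cfg$cutoff)$cells$chi2
  s <- summarize_repeats(chi2)
  cat(sprintf("  z = %2g, A_L = %g: chi^2 = %.2f +/- %.2f  [%.2f, %.2f]\n",
              cell[["z"]], cell[["A_L"]], s$mean, s$sd, s$min, s$max))
  data.frame(z = cell[["z"]], A_L = cell[["A_L"]], mean = s$mean,
             sd = s$sd, min = s$min, max = s$max, n = s$n)
})
utils::write.table(do.call(rbind, rows),
                   file.path(out, "repeat_stats.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
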