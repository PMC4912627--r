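#!/usr/bin/env Rscript
# Desynchronization / resynchronization assay in silico.
#
# Simulates noisy oscillator populations through a coupling blockade and
# washout across a coupling-strength grid (matched seeds), recording the
# order parameter, recovery time and predicted first recovered segment
# (FRS): stronger coupling resynchronizes faster, i.e. lower FRS. Also
# generates boundary-defect records from the calibrated synchrony
# trajectory presets and scores ALD/FRS/resynchronization rate with the
# same scorer applied to stained embryos.

suppressPackageStartupMessages(library(segclock))
dir.create("results", showWarnings = FALSE)

eps_grid <- c(0.03, 0.05, 0.09)
seeds <- 1:20
runs <- do.call(rbind, lapply(eps_grid, function(eps) {
  p <- osc_params(n_cells = 2, profile = "uniform", advection_v = 0,
                  epsilon = eps, noise_sigma = 0.1)
  do.call(rbind, lapply(seeds, function(sd) {
    s <- desync_resync(p, t_block_start = 0, t_washout = 300, Zc = 0.8,
                       segment_period_T = 23.5, stage_offset = 9,
                       duration = 1200, seed = sd, n_osc = 100)
    data.frame(epsilon = eps, seed = sd, t_recovery_min = s$t_recovery,
               predicted_FRS = s$predicted_FRS, censored = s$censored,
               Zmin = s$Zmin)
  }))
}))
write.table(format(runs, digits = 4), "results/resync_runs.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

summ <- aggregate(cbind(predicted_FRS, t_recovery_min) ~ epsilon, runs, mean)
cat("Mean predicted FRS by coupling strength (20 matched seeds):\n")
print(summ, row.names = FALSE, digits = 3)
cat("\n")

score_group <- function(name, frs_target, seed) {
  d <- gen_boundary_records(n_embryos = 40, ald_target = 8,
                            frs_target = frs_target, seed = seed)
  sc <- lapply(split(d, interaction(d$embryo_id, d$side)),
               function(r) score_boundaries(r$status[order(r$segment)]))
  frs <- vapply(sc, function(s) ifelse(is.na(s$frs), NA_real_, s$frs), numeric(1))
  ald <- vapply(sc, function(s) ifelse(is.na(s$ald), NA_real_, s$ald), numeric(1))
  rr <- vapply(sc, function(s) ifelse(is.na(s$resync_rate), NA_real_,
                                      s$resync_rate), numeric(1))
  data.frame(group = name, frs_anchor = frs_target,
             mean_FRS = mean(frs, na.rm = TRUE), sd_FRS = sd(frs, na.rm = TRUE),
             mean_ALD = mean(ald, na.rm = TRUE),
             mean_resync_rate = mean(rr, na.rm = TRUE),
             n_sides = sum(!is.na(frs)))
}
groups <- rbind(
  score_group("aei_het", fixture_preset("aei-het")$frs, 61),
  score_group("WT", fixture_preset("WT")$frs, 62),
  score_group("Damascus", fixture_preset("Damascus")$frs, 63))
write.table(format(groups, digits = 4), "results/boundary_scores.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("Scored boundary records (synthetic, 40 embryos x 2 sides each):\n")
print(groups, row.names = FALSE, digits = 3)
cat(sprintf("\nFRS ordering (faster resync with stronger coupling): %s\n",
            paste(groups$group[order(groups$mean_FRS)], collapse = " < ")))
cat("written: results/resync_runs.tsv, results/boundary_scores.tsv\n")
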