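#!/usr/bin/env Rscript

# Generate one synthetic dataset per modality, with ground-truth sidecars.
# Everything downstream (02-05) can be reproduced from these files or
# regenerated from the seeds recorded in the truth records.

suppressPackageStartupMessages({
  library(glrquant)
  library(jsonlite)
})

out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20240601L

# --- line scan: 5 puncta on a 60 um VNC segment -----------------------------
tr_scan <- scan_truth(
  length_um = 60, background_mean = 100, background_sd = 5,
  puncta = data.frame(center_um = c(8, 19, 28, 41, 52),
                      amplitude = c(70, 95, 120, 80, 105),
                      sigma_um = c(0.4, 0.55, 0.5, 0.7, 0.45)),
  bead_mean = 250, seed = seed)
scan <- gen_linescan(tr_scan)
write_linescan_csv(scan$scan, file.path(out, "linescan_vnc.csv"))
write_json(unclass(tr_scan)[names(tr_scan) != "puncta"],
           file.path(out, "linescan_vnc_truth.json"), auto_unbox = TRUE)
write.csv(tr_scan$puncta, file.path(out, "linescan_vnc_truth_puncta.csv"),
          row.names = FALSE)

# --- dual SEP/mCherry pair: half the receptor at the surface ----------------
tr_dual <- reporter_truth(total_per_pixel = 300, f_surf = 0.5, q = 1,
                          background_mean = 100, noise_sd = 6, seed = seed)
dual <- gen_dual_channel(tr_dual)
write_channel_tiff(dual$sep, file.path(out, "dual_sep.tif"))
write_channel_tiff(dual$mcherry, file.path(out, "dual_mcherry.tif"))
write_json(unclass(tr_dual), file.path(out, "dual_truth.json"), auto_unbox = TRUE)

# --- FRAP series: recycling-competent worm ----------------------------------
tr_frap <- frap_truth(f_surf = 0.5, q = 1, beta = 0.9, k_exo = 0.2,
                      k_endo = 0.2, k_ext = 0.05, noise_sd = 0.02,
                      seed = seed)
fr <- gen_frap_series(tr_frap)
frap_tab <- do.call(rbind, lapply(list(fr$sep, fr$mcherry), function(s)
  data.frame(channel = s$channel,
             timepoint = c("pre", as.character(s$t_min)),
             roi_total = c(s$pre_total, s$total))))
write.csv(frap_tab, file.path(out, "frap_roi_totals.csv"), row.names = FALSE)
write_json(unclass(tr_frap), file.path(out, "frap_truth.json"), auto_unbox = TRUE)

# --- behavior: wild type vs a transduction-defective mutant -----------------
tr_beh <- behavior_truth(genotypes = data.frame(
  genotype = c("WT", "mutA", "mutB"),
  p_resp = c(0.9, 0.45, 0.85),
  lambda_thrash = c(40, 38, 25),
  lambda_rev = c(12, 6, 11),
  paralysis_rate = c(0.02, 0.02, 0.008),
  n_worms = c(30L, 30L, 30L)), seed = seed)
beh <- gen_behavior(tr_beh)
for (nm in c("nose_touch", "opto", "thrash", "reversal", "aldicarb"))
  write.csv(beh[[nm]], file.path(out, paste0("behavior_", nm, ".csv")),
            row.names = FALSE)
write_json(tr_beh$genotypes, file.path(out, "behavior_truth.json"))

cat("simulated data written to", out, "\n")
cat(sprintf("  line scan: %d px, %d true puncta\n", nrow(scan$scan),
            nrow(tr_scan$puncta)))
cat(sprintf("  dual pair: %dx%d px, f_surf = %.2f\n",
            nrow(dual$sep), ncol(dual$sep), tr_dual$f_surf))
cat(sprintf("  FRAP: SEP floor %.3f (closed form %.3f)\n",
            fr$sep$total[1] / fr$sep$pre_total, 1 - 0.9))
cat(sprintf("  behavior: %d worms x %d genotypes\n", 30, 3))
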