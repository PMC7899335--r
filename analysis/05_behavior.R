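#!/usr/bin/env Rscript

# Score the simulated behavioral assays: nose touch and optogenetic ASH
# responses (per-worm fractions), thrashing and spontaneous reversals
# (per-worm counts), aldicarb paralysis time courses, with the
# figure-style group statistics (ANOVA, Tukey, Dunnett).

suppressPackageStartupMessages(library(glrquant))

dir.create("results", showWarnings = FALSE)
src <- "results/simulated"

nose <- nose_touch_score(read.csv(file.path(src, "behavior_nose_touch.csv")))
opto <- opto_response(read.csv(file.path(src, "behavior_opto.csv")))
thrash <- rate_score(read.csv(file.path(src, "behavior_thrash.csv")))
rev <- rate_score(read.csv(file.path(src, "behavior_reversal.csv")))
par_tab <- read.csv(file.path(src, "behavior_aldicarb.csv"))

cat("nose touch (fraction of 10 trials):\n")
print(nose$by_group, digits = 3, row.names = FALSE)
cat("optoASH (fraction of 5 pulses):\n")
print(opto$by_group, digits = 3, row.names = FALSE)
cat("thrashes / 30 s:\n")
print(thrash$by_group, digits = 3, row.names = FALSE)
cat("reversals / 5 min:\n")
print(rev$by_group, digits = 3, row.names = FALSE)

groups <- split(nose$per_worm$fraction, nose$per_worm$genotype)
av <- anova_oneway(groups)
cat(sprintf("nose touch one-way ANOVA: F(%d,%d) = %.1f, p = %.2g\n",
            av$df_between, av$df_within, av$F, av$p))
tk <- tukey_hsd(groups)
cat("Tukey HSD:\n"); print(tk, digits = 3, row.names = FALSE)
dn <- dunnett(groups, control = "WT")
cat("Dunnett vs WT:\n"); print(dn$comparisons, digits = 3, row.names = FALSE)

curve <- paralysis_curve(par_tab)
write.csv(curve, "results/behavior_paralysis_curve.csv", row.names = FALSE)
cat("aldicarb paralysis at 60 min:\n")
print(curve[curve$time_min == 60, c("genotype", "fraction", "se")],
      digits = 2, row.names = FALSE)

summaries <- rbind(
  cbind(assay = "nose_touch", nose$by_group),
  cbind(assay = "optoASH", opto$by_group),
  cbind(assay = "thrash", thrash$by_group),
  cbind(assay = "reversal", rev$by_group))
write.csv(summaries, "results/behavior_summaries.csv", row.names = FALSE)
write.csv(tk, "results/behavior_tukey.csv", row.names = FALSE)
write.csv(dn$comparisons, "results/behavior_dunnett.csv", row.names = FALSE)
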