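#!/usr/bin/env Rscript
# Stage 1: calibrate the cohort simulator and generate the working cohort.
#
# The default specification encodes the study conditions: n = 97, the
# published marginal means/SDs of the anthropometric, haemodynamic, aortic
# and EAT variables, and a latent correlation structure whose strain-EAT
# entries are refined by fixed-point calibration so that the derived-index
# correlations (stiffness index vs BSA-indexed EAT) hit their targets.
# Writes the cohort CSV, the calibrated latent matrix, and the achieved
# summary under results/.

suppressPackageStartupMessages(library(eataorta))

seed <- 20260927
dir.create("results", showWarnings = FALSE)

spec <- calibrate_spec(default_spec(n = 97, seed = seed))
trace <- attr(spec, "calibration")
cat("calibration rounds:", length(trace), "\n")
cat("final induced correlations (stiffness index vs EAT indices):\n")
print(round(trace[[length(trace)]], 3))

cohort <- generate_cohort(spec)
write_cohort(cohort, "results/cohort.csv")
utils::write.csv(round(spec$correlation, 4), "results/latent_correlation.csv")

s <- summarize_cohort(cohort)
utils::write.csv(transform(merge(s$moments, spec$marginals[, c("variable", "mean", "sd")],
                                 by = "variable", suffixes = c("_achieved", "_target")),
                           mean_bias = mean_achieved - mean_target),
                 "results/achieved_summary.csv", row.names = FALSE)
cat("cohort of", nrow(cohort), "records written to results/cohort.csv\n")
cat("largest |achieved - target| mean bias:",
    round(max(abs(s$mean_bias)), 3), "\n")
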