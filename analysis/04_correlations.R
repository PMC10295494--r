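#!/usr/bin/env Rscript
# Stage 4: Pearson correlations between EAT measures and aortic indices.
#
# The 4 x 3 grid: EAT thickness, volume and their BSA-indexed forms
# against stiffness index, strain and distensibility. The expected
# pattern under the calibrated generator: positive against stiffness,
# negative against both elasticity measures, strongest for the volume
# index.

suppressPackageStartupMessages(library(eataorta))

derived <- utils::read.csv("results/derived_indices.csv")
tab <- correlation_table(derived, method = "pearson")
utils::write.csv(round(tab, 2), "results/table_correlations.csv")
cat("EAT vs aortic-index Pearson correlations:\n")
print(round(tab, 2))
strongest <- which(abs(tab) == max(abs(tab)), arr.ind = TRUE)
cat("\nstrongest association:", rownames(tab)[strongest[1]], "vs",
    colnames(tab)[strongest[2]], "=",
    round(tab[strongest], 2), "\n")
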