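#!/usr/bin/env Rscript
# Step 1 — simulate sequencing depth with known copy-number truth.
#
# Writes samtools-depth style files (chrY, 1-based position, depth) for a
# representative subset of the truth cohort: the largest duplication carrier
# (R006, double b2/b4), the duplication+deletion carrier (R008), a b2/b3
# deletion carrier (R063), a P4-arm duplication carrier (R053) and one
# reference sample. The full 87-sample cohort is simulated in memory by
# step 4; these files demonstrate (and exercise) the on-disk interface.

suppressPackageStartupMessages(library(azfcnv))

model <- azf_model()
cohort <- load_cohort_truth()
subset <- c("R001", "R006", "R008", "R053", "R063")

manifest <- simulate_cohort(cohort$truth[subset, ], model,
                            simulation_config(haploid_coverage = 30, seed = 1),
                            outdir = "results/sim")
cat("simulated", nrow(manifest), "samples at 30x into results/sim/\n")
print(manifest)
cat("truth table:", attr(manifest, "truth_file"), "\n")
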