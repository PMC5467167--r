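#!/usr/bin/env Rscript
# Step 1: generate the synthetic study materials.
#
# Builds (a) the mitochondrial microsatellite catalogue from the hg19 chrM
# sequence and (b) a synthetic tumour cohort with known ground truth:
# a planted-repeat reference, per-sample tumour/normal allele-length
# tallies under the PCR-stutter slippage model, and MSI-H/MSS labels.
# Everything downstream (02-04) consumes the files written here.

suppressMessages({
  library(msisweep)
  library(data.table)
})

dir.create("results", showWarnings = FALSE)
seed <- 20260901

## Mitochondrial catalogue -------------------------------------------------
cat_m <- build_reference(hg19_chrM())
write_catalogue(cat_m, "results/chrM_catalogue.tsv")
message(sprintf("chrM: %d loci (%s mono/di/tri/tetra)",
                nrow(cat_m),
                paste(table(factor(cat_m$unit_len, 1:4)), collapse = "/")))

## Synthetic cohort --------------------------------------------------------
spec <- cohort_spec(seed = seed)       # 800 samples, 25% MSI-H, 600 loci
coh <- simulate_cohort(spec, output = "calls")
dir.create("scratch", showWarnings = FALSE)
saveRDS(coh, "scratch/cohort.rds")     # binary intermediate reused by 02-04
write_fasta(coh$reference, "results/sim_reference.fa")
write_catalogue(coh$catalogue, "results/sim_catalogue.tsv")
fwrite(coh$metadata, "results/sim_metadata.tsv", sep = "\t")
fwrite(coh$truth, "results/sim_truth_events.tsv", sep = "\t")

n_h <- sum(coh$metadata$msi_label == "MSI-H")
message(sprintf("cohort: %d samples (%d MSI-H), %d catalogue loci, %d planted events",
                nrow(coh$metadata), n_h, nrow(coh$catalogue),
                nrow(coh$truth)))
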