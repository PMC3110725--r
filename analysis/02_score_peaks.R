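#!/usr/bin/env Rscript
# Step 2 - threshold scoring of peak heights against replicated extractions.
#
# Optimises the (locus threshold, call threshold, mode) combination over a
# grid by minimising the mismatch rate between double extractions of the
# same individuals, then scores all samples with the winning thresholds and
# reports marker repeatability.

suppressPackageStartupMessages(library(aflpscan))

peaks <- read_peak_table("results/data/peaks.tsv")
replicates <- read.delim("results/data/replicates.tsv")

grid <- rbind(
  expand.grid(locus_threshold = c(50, 100, 200),
              call_threshold = c(0.25, 0.5, 0.75),
              call_mode = "relative", stringsAsFactors = FALSE),
  expand.grid(locus_threshold = c(50, 100, 200),
              call_threshold = c(300, 500, 700),
              call_mode = "absolute", stringsAsFactors = FALSE))
opt <- optimize_thresholds(peaks, replicates, grid)

calls <- call_phenotypes(peaks, opt$thresholds)
rep_rate <- mismatch_error_rate(calls, replicates)

write.table(opt$grid, "results/scoring_grid.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
# scored matrix for the original (non-replicate) samples
originals <- setdiff(rownames(calls), replicates$sample_id_b)
write_genotype_matrix(
  genotype_matrix(unclass(calls)[originals, , drop = FALSE]),
  "results/scored_matrix.tsv")

message(sprintf("best thresholds: locus %.0f RFU, call %.2f (%s); error %.4f",
                opt$thresholds$locus_threshold, opt$thresholds$call_threshold,
                opt$thresholds$call_mode, opt$error))
message(sprintf("repeatability over %d compared calls: %.1f%%",
                rep_rate$n_compared, 100 * rep_rate$repeatability))

# sanity check against the generating truth
truth <- read_genotype_matrix("results/data/matrix.tsv")
shared <- intersect(colnames(calls), colnames(truth))
agree <- mean(unclass(calls)[originals, shared] ==
              unclass(truth)[originals, shared])
message(sprintf("agreement with generating calls: %.2f%% over %d loci",
                100 * agree, length(shared)))
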