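#!/usr/bin/env Rscript
# Step 3 - pairwise FST between morphotype populations.
#
# Polymorphism-filters the matrix, drops populations with six or fewer
# individuals, and computes the multilocus mean and 30%-trimmed mean FST
# with 999-permutation significance for every sympatric different-morphotype
# and allopatric same-morphotype pair.

suppressPackageStartupMessages(library(aflpscan))

gm <- filter_polymorphic(read_genotype_matrix("results/data/matrix.tsv"))
meta <- read_sample_metadata("results/data/meta.tsv")
message(sprintf("%d polymorphic loci", ncol(gm)))

pops <- filter_min_population_size(morphotype_populations(meta))
pairs <- population_pairs(pops, c("sympatric-different", "allopatric-same"))

set.seed(101)
seeds <- sample.int(2^31 - 2L, nrow(pairs))
rows <- lapply(seq_len(nrow(pairs)), function(i) {
  pr <- pairs[i, ]
  ga <- population_calls(gm, meta, pr$morphotype_a, pr$location_a)
  gb <- population_calls(gm, meta, pr$morphotype_b, pr$location_b)
  sub <- filter_polymorphic(genotype_matrix(rbind(unclass(ga), unclass(gb))))
  groups <- rep(c(pr$pop_a, pr$pop_b), c(nrow(ga), nrow(gb)))
  fr <- estimate_allele_freqs(sub, groups)
  ml <- multilocus_fst(fr)
  perm <- permutation_test_fst(sub, groups, n_perm = 999L, seed = seeds[i],
                               prior = fr$prior)
  data.frame(pop_a = pr$pop_a, pop_b = pr$pop_b,
             design_class = pr$design_class, n_loci = ncol(sub),
             mean_fst = round(ml$mean_fst, 4),
             trimmed_mean_fst = round(ml$trimmed_mean_fst, 4),
             perm_p = perm$p_value)
})
fst_tab <- do.call(rbind, rows)
write.table(fst_tab, "results/pairwise_fst.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sym <- fst_tab$design_class == "sympatric-different"
message(sprintf("mean FST between sympatric morphotypes: %.3f (%d pairs)",
                mean(fst_tab$mean_fst[sym]), sum(sym)))
message(sprintf("mean FST within morphotypes across locations: %.3f (%d pairs)",
                mean(fst_tab$mean_fst[!sym]), sum(!sym)))
message(sprintf("%d of %d pairs significant at p < 0.05",
                sum(fst_tab$perm_p < 0.05), nrow(fst_tab)))
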