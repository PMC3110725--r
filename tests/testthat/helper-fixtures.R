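# shared fixture builders

make_calls <- function(n_samples, n_loci, seed = 1, miss_rate = 0) {
  set.seed(seed)
  m <- matrix(rbinom(n_samples * n_loci, 1L, 0.5), n_samples, n_loci,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("L%03d", seq_len(n_loci))))
  if (miss_rate > 0) m[runif(length(m)) < miss_rate] <- NA_integer_
  genotype_matrix(m)
}

pop_row <- function(morphotype, location) {
  data.frame(morphotype = morphotype, location = location,
             population = paste0(morphotype, "@", location),
             stringsAsFactors = FALSE)
}

# a small two-location, two-morphotype synthetic configuration
small_config <- function(seed = 1, n = 40, n_loci = 200, n_sel = 0,
                         fst_loc = 0.05, fst_morph = 0.05, sel_fst = 0.4) {
  synthetic_config(
    design = data.frame(location = rep(c("siteA", "siteB"), each = 2),
                        morphotype = rep(c("m1", "m2"), 2),
                        n = n),
    n_loci = n_loci, background_fst_location = fst_loc,
    background_fst_morphotype = fst_morph,
    n_selected_loci = n_sel, selected_fst = sel_fst,
    selected_pair = c("m1", "m2"), seed = seed)
}

# single-location two-population configuration (pairwise divergence = fst)
two_pop_config <- function(seed = 1, n = 40, n_loci = 436, fst = 0.05,
                           n_sel = 0, sel_fst = 0.4) {
  synthetic_config(
    design = data.frame(location = "loc1", morphotype = c("m1", "m2"),
                        n = c(n, n)),
    n_loci = n_loci, background_fst_location = 0,
    background_fst_morphotype = fst,
    n_selected_loci = n_sel, selected_fst = sel_fst,
    selected_pair = c("m1", "m2"), seed = seed)
}

first_sympatric_pair <- function(meta) {
  pops <- morphotype_populations(meta)
  population_pairs(pops, "sympatric-different")[1L, ]
}
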