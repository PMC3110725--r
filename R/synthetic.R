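#' Configuration for the synthetic AFLP dataset generator
#'
#' The generator emulates a multi-location, multi-morphotype dominant-marker
#' survey with hierarchical population structure: for each locus an
#' ancestral band-presence frequency is drawn from a Beta prior (default
#' Beta(0.4, 0.4), the mutation-drift equilibrium shape at theta = 4 Ne mu
#' with Ne = 10^4 and mu = 1e-5); location-level frequencies diverge from it
#' by `background_fst_location` and morphotype-level frequencies within each
#' location by `background_fst_morphotype`, both via Balding-Nichols Beta
#' draws. A planted subset of loci is divergent between one configured
#' morphotype pair at `selected_fst`, consistently across all locations -
#' the signature a repeated-outlier analysis is designed to detect.
#'
#' The default `design` is the sampling layout of the motivating study
#' system: 8 Caribbean locations, 5 colour morphotypes, per-population
#' sample sizes from 4 to 90 (528 fish), 436 loci; background
#' differentiation 0.060 among locations and 0.058 between sympatric
#' morphotypes.
#'
#' @param design data.frame with columns `location`, `morphotype`, `n`
#'   (default: the study layout, see [default_design()]).
#' @param n_loci number of loci (default 436).
#' @param background_fst_location,background_fst_morphotype hierarchical
#'   differentiation levels, each in \[0, 0.95).
#' @param n_selected_loci number of planted selected loci (default 10).
#' @param selected_fst divergence of planted loci between the selected
#'   morphotype pair (must exceed `background_fst_morphotype`).
#' @param selected_pair the two morphotype labels under divergent selection.
#' @param ancestral_freq_prior Beta shapes for the ancestral presence-allele
#'   frequency.
#' @param peak_model list with `signal_mean`, `noise_mean`, `sd` (RFU) and
#'   `flip_error` for [generate_peak_data()].
#' @param n_replicate_pairs number of double-extracted individuals.
#' @param seed RNG seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(design = default_design(),
                             n_loci = 436L,
                             background_fst_location = 0.060,
                             background_fst_morphotype = 0.058,
                             n_selected_loci = 10L,
                             selected_fst = 0.4,
                             selected_pair = c("chlorurus", "puella"),
                             ancestral_freq_prior = c(0.4, 0.4),
                             peak_model = list(signal_mean = 1000,
                                               noise_mean = 50, sd = 100,
                                               flip_error = 0.029),
                             n_replicate_pairs = 20L,
                             seed = 1L) {
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  stopifnot(all(c("location", "morphotype", "n") %in% colnames(design)),
            all(design$n >= 1), n_loci >= 1,
            background_fst_location >= 0, background_fst_location < 0.95,
            background_fst_morphotype >= 0, background_fst_morphotype < 0.95,
            n_selected_loci >= 0, selected_fst >= 0, selected_fst < 0.95,
            length(ancestral_freq_prior) == 2L, all(ancestral_freq_prior > 0))
  if (n_selected_loci > 0) {
    if (selected_fst <= background_fst_morphotype)
      stop("selected_fst must exceed background_fst_morphotype")
    sel_locs <- unique(design$location[design$morphotype %in% selected_pair])
    both <- vapply(sel_locs, function(l)
      all(selected_pair %in% design$morphotype[design$location == l]),
      logical(1L))
    if (!any(both))
      stop("selected pair (", paste(selected_pair, collapse = ", "),
           ") co-occurs at no location in the design")
  }
  structure(list(design = design, n_loci = as.integer(n_loci),
                 background_fst_location = background_fst_location,
                 background_fst_morphotype = background_fst_morphotype,
                 n_selected_loci = as.integer(n_selected_loci),
                 selected_fst = selected_fst,
                 selected_pair = as.character(selected_pair),
                 ancestral_freq_prior = as.numeric(ancestral_freq_prior),
                 peak_model = peak_model,
                 n_replicate_pairs = as.integer(n_replicate_pairs),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' The default multi-location, multi-morphotype sampling design
#'
#' Eight Caribbean locations by five colour morphotypes with the observed
#' per-population sample sizes (n = 4 to 90, 528 individuals in total).
#'
#' @return data.frame with columns `location`, `morphotype`, `n`.
#' @export
default_design <- function() {
  rows <- list(
    c("Bermuda", "puella", 90),
    c("Curacao", "chlorurus", 42), c("Curacao", "puella", 11),
    c("Curacao", "unicolor", 32),
    c("DominicanRepublic", "chlorurus", 4), c("DominicanRepublic", "nigricans", 24),
    c("DominicanRepublic", "puella", 31), c("DominicanRepublic", "unicolor", 33),
    c("Honduras", "nigricans", 4), c("Honduras", "puella", 39),
    c("Mexico", "nigricans", 34), c("Mexico", "vwhite", 44),
    c("Panama", "nigricans", 25), c("Panama", "puella", 17),
    c("Panama", "unicolor", 4),
    c("PuertoRico", "chlorurus", 38), c("PuertoRico", "nigricans", 6),
    c("PuertoRico", "puella", 9), c("PuertoRico", "unicolor", 6),
    c("USVirginIslands", "chlorurus", 4), c("USVirginIslands", "puella", 31))
  out <- data.frame(location = vapply(rows, `[[`, "", 1L),
                    morphotype = vapply(rows, `[[`, "", 2L),
                    n = as.integer(vapply(rows, `[[`, "", 3L)),
                    stringsAsFactors = FALSE)
  out
}

# Balding-Nichols draw of daughter frequencies around p with differentiation F
.bn_draw <- function(p, F) {
  if (F <= 1e-12) return(p)
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Generate a synthetic dominant-marker dataset with known ground truth
#'
#' See [synthetic_config()] for the generative model. Loci that come out
#' monomorphic across the entire dataset are resampled, so every returned
#' locus is polymorphic somewhere (as empirical scorable loci effectively
#' are); per-population monomorphism is retained. Fully reproducible under
#' the config seed.
#'
#' @param config a [synthetic_config()].
#' @return list with `genotypes` (a [genotype_matrix()]), `metadata`
#'   (sample metadata data.frame), `truth` (per-locus data.frame with
#'   `locus_id`, `selected`, `true_pair_fst`, and true presence-allele
#'   frequency columns per population).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  des <- config$design
  pops <- paste0(des$morphotype, "@", des$location)
  n_pop <- nrow(des)
  L <- config$n_loci
  locus_ids <- sprintf("L%03d", seq_len(L))
  sel_flag <- rep(FALSE, L)
  if (config$n_selected_loci > 0)
    sel_flag[sample.int(L, config$n_selected_loci)] <- TRUE

  sample_ids <- unlist(lapply(seq_len(n_pop), function(i)
    sprintf("%s_%02d", pops[i], seq_len(des$n[i]))))
  meta <- data.frame(sample_id = sample_ids,
                     morphotype = rep(des$morphotype, des$n),
                     location = rep(des$location, des$n),
                     stringsAsFactors = FALSE)
  N <- nrow(meta)
  pop_of_sample <- rep(seq_len(n_pop), des$n)

  calls <- matrix(NA_integer_, N, L, dimnames = list(sample_ids, locus_ids))
  p_true <- matrix(NA_real_, L, n_pop, dimnames = list(locus_ids, pops))
  locs <- unique(des$location)
  a0 <- config$ancestral_freq_prior[1L]; b0 <- config$ancestral_freq_prior[2L]
  sel_pair <- config$selected_pair

  todo <- seq_len(L)
  guard <- 0L
  while (length(todo)) {
    guard <- guard + 1L
    if (guard > 100L) stop("failed to generate polymorphic loci; check config")
    m <- length(todo)
    p0 <- stats::rbeta(m, a0, b0)
    # locus-level divergent anchors for the selected pair, shared by all
    # locations so the planted signal repeats across locations
    selm <- sel_flag[todo]
    pselA <- p0; pselB <- p0
    if (any(selm)) {
      pselA[selm] <- .bn_draw(p0[selm], config$selected_fst)
      pselB[selm] <- .bn_draw(p0[selm], config$selected_fst)
    }
    for (loc in locs) {
      p_loc <- .bn_draw(p0, config$background_fst_location)
      for (i in which(des$location == loc)) {
        morph <- des$morphotype[i]
        anchor <- p_loc
        if (any(selm) && morph %in% sel_pair) {
          psel <- if (morph == sel_pair[1L]) pselA else pselB
          # selected loci anchor on the shared morphotype target, jittered
          # by the within-location background level
          anchor[selm] <- psel[selm]
        }
        p_pop <- .bn_draw(anchor, config$background_fst_morphotype)
        p_true[todo, i] <- p_pop
        rows_i <- which(pop_of_sample == i)
        pres <- matrix(stats::rbinom(length(rows_i) * m, 1L,
                                     rep(1 - (1 - p_pop)^2, each = length(rows_i))),
                       nrow = length(rows_i))
        calls[rows_i, todo] <- pres
      }
    }
    csum <- colSums(calls[, todo, drop = FALSE])
    todo <- todo[csum == 0L | csum == N]
  }

  truth <- data.frame(locus_id = locus_ids, selected = sel_flag,
                      true_pair_fst = NA_real_, stringsAsFactors = FALSE)
  pair_cols <- lapply(sel_pair, function(mname) which(des$morphotype == mname))
  shared <- intersect(des$location[pair_cols[[1L]]], des$location[pair_cols[[2L]]])
  if (length(shared)) {
    per_loc_fst <- sapply(shared, function(loc) {
      ia <- which(des$location == loc & des$morphotype == sel_pair[1L])
      ib <- which(des$location == loc & des$morphotype == sel_pair[2L])
      qa <- 1 - p_true[, ia]; qb <- 1 - p_true[, ib]
      qbar <- (qa + qb) / 2
      den <- qbar * (1 - qbar)
      ifelse(den > 0, ((qa - qb)^2 / 2) / den, 0)
    })
    truth$true_pair_fst <- rowMeans(as.matrix(per_loc_fst))
  }
  truth <- cbind(truth, as.data.frame(p_true))
  list(genotypes = genotype_matrix(calls), metadata = meta, truth = truth)
}

#' Generate peak-height profiles and replicate pairs from genotype calls
#'
#' Present bands get heights from a Normal(signal_mean, sd) truncated at
#' zero; absent bands from Normal(noise_mean, sd) truncated at zero.
#' Replicate profiles (second extractions) copy a sample's true calls, flip
#' each call independently with probability `flip_error`, and then draw
#' heights; the replicate rows are appended with suffix `"_rep"`.
#'
#' @param x a [genotype_matrix()] of true calls.
#' @param config a [synthetic_config()]; uses `peak_model`,
#'   `n_replicate_pairs` and `seed`.
#' @return list with `peaks` (a [peak_table()] over originals + replicates)
#'   and `replicates` (data.frame `sample_id_a`, `sample_id_b`).
#' @export
generate_peak_data <- function(x, config) {
  stopifnot(inherits(config, "synthetic_config"))
  pm <- config$peak_model
  if (pm$signal_mean <= pm$noise_mean)
    stop("peak model is not separable: signal_mean must exceed noise_mean")
  set.seed(config$seed + 1L)
  n_rep <- min(config$n_replicate_pairs, nrow(x))
  rep_idx <- sort(sample.int(nrow(x), n_rep))
  true_calls <- unclass(x)
  rep_calls <- true_calls[rep_idx, , drop = FALSE]
  flips <- matrix(stats::rbinom(length(rep_calls), 1L, pm$flip_error) == 1L,
                  nrow = n_rep)
  rep_calls[flips] <- 1L - rep_calls[flips]
  rownames(rep_calls) <- paste0(rownames(true_calls)[rep_idx], "_rep")
  all_calls <- rbind(true_calls, rep_calls)
  heights <- matrix(.rtruncnorm0(length(all_calls),
                                 ifelse(all_calls == 1L, pm$signal_mean, pm$noise_mean),
                                 pm$sd),
                    nrow = nrow(all_calls), dimnames = dimnames(all_calls))
  list(peaks = peak_table(heights),
       replicates = data.frame(sample_id_a = rownames(true_calls)[rep_idx],
                               sample_id_b = rownames(rep_calls),
                               stringsAsFactors = FALSE))
}

# Normal(mu, sd) truncated below at 0, via the inverse-CDF method
.rtruncnorm0 <- function(n, mu, sd) {
  lo <- stats::pnorm(0, mu, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mu, sd)
}
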