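#' Outlier scan for one population pair
#'
#' Runs the full per-pair procedure: subset the two morphotype populations,
#' drop loci not polymorphic within the pair, estimate null-allele
#' frequencies (fitted prior by default), compute per-locus and trimmed
#' mean FST, calibrate the island-model neutral simulation to the trimmed
#' mean, simulate the neutral cloud at matched sample sizes, and derive
#' heterozygosity-conditional p values and outlier flags.
#'
#' @param x a [genotype_matrix()] (all samples).
#' @param meta sample metadata.
#' @param pair one row of [population_pairs()].
#' @param n_sim_loci simulated loci in the final cloud (default 50000).
#' @param n_calibration_loci loci per calibration evaluation (default 8000).
#' @param prior prior specification for [estimate_allele_freqs()].
#' @param window_rule,n_bins passed to [envelope_p_values()].
#' @param seed RNG seed for the simulation.
#' @param effective_size,mutation_rate island-model parameters.
#' @return list with `envelope` (per-locus results), `outcome`
#'   (a [comparison_outcome()]), `fst` (the [multilocus_fst()] summary),
#'   `params` (calibrated [simulation_params()]), `prior`.
#' @export
neutral_scan <- function(x, meta, pair, n_sim_loci = 50000L,
                         n_calibration_loci = 8000L, prior = "fitted",
                         window_rule = "hbins", n_bins = NULL, seed = 1L,
                         effective_size = 10000, mutation_rate = 1e-5) {
  ga <- population_calls(x, meta, pair$morphotype_a, pair$location_a)
  gb <- population_calls(x, meta, pair$morphotype_b, pair$location_b)
  sub <- genotype_matrix(rbind(unclass(ga), unclass(gb)))
  sub <- filter_polymorphic(sub)
  if (ncol(sub) < 10L) stop("fewer than 10 polymorphic loci in pair ",
                            pair$pop_a, " vs ", pair$pop_b)
  groups <- rep(c(pair$pop_a, pair$pop_b), c(nrow(ga), nrow(gb)))
  freqs <- estimate_allele_freqs(sub, groups, prior)
  fst <- multilocus_fst(freqs)
  params <- simulation_params(effective_size = effective_size,
                              mutation_rate = mutation_rate,
                              n_sim_loci = n_sim_loci,
                              sample_sizes = c(nrow(ga), nrow(gb)),
                              prior = freqs$prior, seed = seed)
  # sampling noise can push a small dataset's trimmed mean to or below zero;
  # the neutral baseline is then effectively undifferentiated and is
  # calibrated to a floor just above panmixia
  target <- max(fst$trimmed_mean_fst, 1e-3)
  params <- calibrate_to_trimmed_mean(target, params,
                                      n_calibration_loci = n_calibration_loci)
  cloud <- simulate_neutral_loci(params)
  env <- envelope_p_values(fst$per_locus, cloud, window_rule = window_rule,
                           n_bins = n_bins)
  list(envelope = env, outcome = comparison_outcome(pair, env), fst = fst,
       params = params, prior = freqs$prior)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [run_full_analysis()].
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' Run the complete outlier-scan analysis
#'
#' Orchestrates the pipeline on a genotype matrix + metadata (or a synthetic
#' dataset generated on the fly): polymorphism filtering, exclusion of
#' populations with six or fewer individuals, pair enumeration, per-pair FST
#' with permutation significance, per-pair neutral-envelope scans, the
#' outlier-frequency table (sympatric-different, allopatric-same and
#' allopatric-different classes, the latter two down-sampled to at most
#' `n_random_comparisons` seeded random picks), the p-value balance
#' diagnostic, repeated-outlier (Sel/Geo) reports for every morphotype pair
#' compared sympatrically in more than one location, and (optionally) the
#' consensus table against externally supplied selection probabilities.
#'
#' All randomness is derived from `seed`; rerunning with an identical
#' configuration yields byte-identical artifacts in `out_dir`:
#' `fst_summary.tsv`, `scan_<pair>.tsv` (per pair), `frequency_table.tsv`,
#' `repeated_outliers.json`, `consensus.tsv` (if probabilities are given)
#' and `run_info.json`.
#'
#' @param x a [genotype_matrix()], or `NULL` to generate synthetic data.
#' @param meta sample metadata (ignored when `x` is `NULL`).
#' @param synthetic a [synthetic_config()] used when `x` is `NULL`.
#' @param out_dir output directory (created; pre-existing artifact files are
#'   overwritten). `NULL` skips writing.
#' @param min_population_size populations below this size are excluded
#'   (default 7).
#' @param n_perm permutations for the FST significance test (default 1000).
#' @param n_sim_loci,n_calibration_loci,window_rule,n_bins,prior see
#'   [neutral_scan()].
#' @param n_random_comparisons allopatric comparisons sampled per class for
#'   the frequency table (default 9).
#' @param selection_probs optional data.frame `locus_id`, `prob` columns (one
#'   probability column per geographic comparison) for [consensus()].
#' @param consensus_threshold probability cutoff for consensus support.
#' @param seed master seed.
#' @return list with `scans`, `fst_table`, `frequency_table`, `balance`,
#'   `repeated`, `consensus`, `populations`, `pairs`, `paths` (written
#'   files).
#' @export
run_full_analysis <- function(x = NULL, meta = NULL, synthetic = NULL,
                              out_dir = NULL, min_population_size = 7L,
                              n_perm = 1000L, n_sim_loci = 50000L,
                              n_calibration_loci = 8000L,
                              window_rule = "hbins", n_bins = NULL,
                              prior = "fitted", n_random_comparisons = 9L,
                              selection_probs = NULL,
                              consensus_threshold = 0.7, seed = 1L) {
  if (is.null(x)) {
    if (is.null(synthetic)) stop("provide either a genotype matrix or a synthetic_config")
    ds <- generate_dataset(synthetic)
    x <- ds$genotypes; meta <- ds$metadata
  }
  meta <- sample_metadata(meta)
  x <- filter_polymorphic(x)
  pops <- filter_min_population_size(morphotype_populations(meta),
                                     min_population_size)
  if (nrow(pops) < 2L) stop("fewer than two populations after size filtering")
  pairs <- population_pairs(pops)

  set.seed(seed)
  stage_seeds <- sample.int(2^31 - 2L, nrow(pairs) + 1L)

  # per-class selection for the frequency analysis: all sympatric-different
  # pairs, plus seeded random subsets of the allopatric classes
  sel_rows <- which(pairs$design_class == "sympatric-different")
  for (cls in c("allopatric-same", "allopatric-different")) {
    rows <- which(pairs$design_class == cls)
    if (length(rows) > n_random_comparisons)
      rows <- sort(sample(rows, n_random_comparisons))
    sel_rows <- c(sel_rows, rows)
  }
  sel_rows <- sort(unique(sel_rows))

  scans <- list()
  fst_rows <- list()
  for (i in sel_rows) {
    pair <- pairs[i, ]
    key <- paste0(pair$pop_a, "_vs_", pair$pop_b)
    sc <- neutral_scan(x, meta, pair, n_sim_loci = n_sim_loci,
                       n_calibration_loci = n_calibration_loci,
                       prior = prior, window_rule = window_rule,
                       n_bins = n_bins, seed = stage_seeds[i])
    ga <- population_calls(x, meta, pair$morphotype_a, pair$location_a)
    gb <- population_calls(x, meta, pair$morphotype_b, pair$location_b)
    sub <- filter_polymorphic(genotype_matrix(rbind(unclass(ga), unclass(gb))))
    perm <- permutation_test_fst(sub,
                                 rep(c(pair$pop_a, pair$pop_b),
                                     c(nrow(ga), nrow(gb))),
                                 n_perm = n_perm, seed = stage_seeds[i],
                                 prior = sc$prior)
    scans[[key]] <- sc
    fst_rows[[key]] <- data.frame(
      pop_a = pair$pop_a, pop_b = pair$pop_b,
      design_class = pair$design_class,
      n_polymorphic_loci = nrow(sc$envelope),
      mean_fst = sc$fst$mean_fst,
      trimmed_mean_fst = sc$fst$trimmed_mean_fst,
      perm_p = perm$p_value, n_perm = n_perm,
      n_outlier95 = length(sc$outcome$outlier95_ids),
      n_outlier99 = length(sc$outcome$outlier99_ids),
      stringsAsFactors = FALSE)
  }
  fst_table <- do.call(rbind, c(fst_rows, list(make.row.names = FALSE)))
  outcomes <- lapply(scans, `[[`, "outcome")
  freq_table <- outlier_frequency_table(outcomes)
  balance <- pvalue_balance_diagnostic(lapply(scans, `[[`, "envelope"))

  # repeated outliers for morphotype pairs with >= 2 sympatric locations
  sym <- outcomes[vapply(outcomes, `[[`, "", "design_class") == "sympatric-different"]
  mp_keys <- unique(vapply(sym, function(o)
    paste(sort(c(o$morphotype_a, o$morphotype_b)), collapse = ":"), ""))
  repeated <- list()
  n_poly <- ncol(x)
  for (kk in mp_keys) {
    mp <- strsplit(kk, ":", fixed = TRUE)[[1L]]
    rep_k <- repeated_outliers(outcomes, mp, n_loci = n_poly)
    if (rep_k$n_comparisons >= 2L) repeated[[kk]] <- rep_k
  }

  cons <- NULL
  if (!is.null(selection_probs)) {
    recs <- list()
    for (kk in names(repeated)) {
      for (level in c("95", "99")) {
        ids <- repeated[[kk]][[paste0("sel", level, "_ids")]]
        for (id in ids) {
          pr <- selection_probs[selection_probs$locus_id == id,
                               setdiff(colnames(selection_probs), "locus_id"),
                               drop = FALSE]
          recs[[paste(id, level)]] <- list(locus_id = id,
                                           envelope_level = paste0(level, "Sel"),
                                           probs = as.numeric(pr[1L, ]))
        }
      }
    }
    cons <- if (length(recs)) consensus(recs, consensus_threshold) else NULL
  }

  result <- list(scans = scans, fst_table = fst_table,
                 frequency_table = freq_table, balance = balance,
                 repeated = repeated, consensus = cons,
                 populations = pops, pairs = pairs, seed = seed)
  result$paths <- if (!is.null(out_dir)) .write_bundle(result, out_dir) else NULL
  result
}

# deterministic text serialisation of the report bundle
.write_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w_tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    num <- vapply(df, is.numeric, logical(1L)) & !vapply(df, is.integer, logical(1L))
    df[num] <- lapply(df[num], function(v) sprintf("%.8g", v))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(paths, w_tsv(result$fst_table, "fst_summary.tsv"))
  for (key in names(result$scans)) {
    env <- result$scans[[key]]$envelope
    paths <- c(paths, w_tsv(env, paste0("scan_", gsub("[^A-Za-z0-9_.@-]", "_", key), ".tsv")))
  }
  paths <- c(paths, w_tsv(result$frequency_table, "frequency_table.tsv"))
  rep_json <- lapply(result$repeated, function(r) {
    list(morphotype_pair = r$morphotype_pair, locations = r$locations,
         n_comparisons = r$n_comparisons,
         sel95_ids = r$sel95_ids, sel99_ids = r$sel99_ids,
         geo95_ids = r$geo95_ids, geo99_ids = r$geo99_ids,
         expected = as.list(r$expected), binomial_p = as.list(r$binomial_p))
  })
  p <- file.path(out_dir, "repeated_outliers.json")
  jsonlite::write_json(rep_json, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  if (!is.null(result$consensus))
    paths <- c(paths, w_tsv(result$consensus, "consensus.tsv"))
  info <- list(seed = result$seed,
               populations = result$populations$population,
               balance = result$balance[c("differences", "mean_difference",
                                          "t_statistic", "df", "p_value")])
  p <- file.path(out_dir, "run_info.json")
  jsonlite::write_json(info, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(paths, p)
}
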