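#' Summarise one pair-wise comparison's outlier scan
#'
#' @param pair one row of [population_pairs()] (or an equivalent list with
#'   `pop_a`, `pop_b`, `morphotype_a`, `morphotype_b`, `location_a`,
#'   `location_b`, `design_class`).
#' @param envelope result of [envelope_p_values()] for this comparison.
#' @return An object of class `comparison_outcome`: list with the pair
#'   fields, `n_polymorphic_loci`, `outlier95_ids`, `outlier99_ids`,
#'   `pct95`, `pct99`.
#' @export
comparison_outcome <- function(pair, envelope) {
  n_loci <- nrow(envelope)
  ids95 <- envelope$locus_id[envelope$outlier95]
  ids99 <- envelope$locus_id[envelope$outlier99]
  structure(list(pop_a = pair$pop_a, pop_b = pair$pop_b,
                 morphotype_a = pair$morphotype_a,
                 morphotype_b = pair$morphotype_b,
                 location_a = pair$location_a, location_b = pair$location_b,
                 design_class = pair$design_class,
                 n_polymorphic_loci = n_loci,
                 outlier95_ids = ids95, outlier99_ids = ids99,
                 pct95 = 100 * length(ids95) / n_loci,
                 pct99 = 100 * length(ids99) / n_loci),
            class = "comparison_outcome")
}

#' Outlier-frequency table with tests against neutral expectations
#'
#' For each comparison design class (and all classes pooled) the observed
#' mean percentage of outlier loci at the 95% and 99% envelope levels is
#' compared against the neutral expectation (5% and 1% of polymorphic loci
#' per comparison) using a two-sample Mann-Whitney U test of the observed
#' per-comparison percentages against an equal-length constant vector at the
#' expectation (tie-corrected normal approximation, no continuity
#' correction). A Kolmogorov-Smirnov normality check (against a normal with
#' the sample moments) is recorded per group.
#'
#' @param outcomes list of [comparison_outcome()] objects.
#' @param expected95,expected99 neutral expectations, percent (defaults 5, 1).
#' @return data.frame with one row per (design class x level), columns
#'   `design_class`, `level`, `n_comparisons`, `observed_mean_pct`,
#'   `expected_pct`, `U`, `p_value`, `ks_p` (normality check).
#' @export
outlier_frequency_table <- function(outcomes, expected95 = 5, expected99 = 1) {
  cls <- vapply(outcomes, `[[`, "", "design_class")
  groups <- c(split(outcomes, cls), list(all = outcomes))
  rows <- list()
  for (g in names(groups)) {
    oc <- groups[[g]]
    if (!length(oc)) { warning("empty design class: ", g); next }
    for (level in c("95", "99")) {
      pct <- vapply(oc, `[[`, 0, paste0("pct", level))
      exp_pct <- if (level == "95") expected95 else expected99
      mw <- mann_whitney_u(pct, rep(exp_pct, length(pct)))
      ks <- if (length(pct) >= 2L && stats::sd(pct) > 0) {
        suppressWarnings(stats::ks.test(pct, "pnorm", mean(pct),
                                        stats::sd(pct))$p.value)
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        design_class = g, level = level, n_comparisons = length(pct),
        observed_mean_pct = mean(pct), expected_pct = exp_pct,
        U = mw$U, p_value = mw$p_value, ks_p = ks, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Mann-Whitney U with tie-corrected normal approximation
#'
#' U counts the pairs where an `x` value exceeds a `y` value, plus half the
#' tied pairs. The two-sided p value uses the normal approximation with the
#' tie-corrected variance. With complete ties (zero variance) the p value
#' is 1.
#'
#' @param x,y numeric samples.
#' @return list with `U`, `p_value`.
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  N <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p_value = 1))
  z <- (U - mu) / sqrt(sigma2)
  list(U = U, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Repeated outliers across locations: Sel and Geo designations
#'
#' Candidate selection-with-morphotype loci ("Sel") are loci flagged at a
#' given envelope level in every available sympatric comparison of the same
#' two morphotypes, in more than one location. Candidate
#' selection-with-geography loci ("Geo") are, per morphotype, loci flagged
#' in all of its allopatric same-morphotype comparisons (at least two) but
#' in no sympatric different-morphotype comparison involving it.
#'
#' @param outcomes list of [comparison_outcome()] objects covering the
#'   comparisons to consider.
#' @param morphotype_pair character vector of the two morphotypes for the
#'   Sel designation.
#' @param n_loci number of polymorphic loci in the study (for expected
#'   counts); default: the maximum over the outcomes.
#' @param p95,p99 per-test outlier probabilities under neutrality
#'   (defaults 0.05 and 0.01).
#' @return An object of class `repeated_outlier_report`: list with
#'   `morphotype_pair`, `locations`, `n_comparisons`, `sel95_ids`,
#'   `sel99_ids`, `geo95_ids`, `geo99_ids` (Geo sets are named lists per
#'   morphotype), `expected`, `binomial_p` (per level, from
#'   [expected_repeated_count()]).
#' @export
repeated_outliers <- function(outcomes, morphotype_pair, n_loci = NULL,
                              p95 = 0.05, p99 = 0.01) {
  mp <- sort(as.character(morphotype_pair))
  stopifnot(length(mp) == 2L)
  is_pair <- vapply(outcomes, function(o) {
    o$design_class == "sympatric-different" &&
      identical(sort(c(o$morphotype_a, o$morphotype_b)), mp)
  }, logical(1L))
  sym <- outcomes[is_pair]
  locations <- vapply(sym, `[[`, "", "location_a")
  if (is.null(n_loci)) {
    n_loci <- if (length(outcomes))
      max(vapply(outcomes, `[[`, 0, "n_polymorphic_loci")) else 0L
  }
  empty <- list(morphotype_pair = mp, locations = locations,
                n_comparisons = length(sym),
                sel95_ids = character(0), sel99_ids = character(0),
                geo95_ids = list(), geo99_ids = list(),
                expected = NULL, binomial_p = NULL)
  if (length(sym) < 2L)
    return(structure(empty, class = "repeated_outlier_report"))
  sel <- function(level) {
    sets <- lapply(sym, `[[`, paste0("outlier", level, "_ids"))
    Reduce(intersect, sets)
  }
  sel95 <- sel("95"); sel99 <- sel("99")
  geo <- function(level) {
    out <- list()
    allo <- outcomes[vapply(outcomes, `[[`, "", "design_class") == "allopatric-same"]
    sympd <- outcomes[vapply(outcomes, `[[`, "", "design_class") == "sympatric-different"]
    for (m in unique(vapply(allo, `[[`, "", "morphotype_a"))) {
      am <- allo[vapply(allo, function(o) o$morphotype_a == m, logical(1L))]
      if (length(am) < 2L) next
      in_all <- Reduce(intersect, lapply(am, `[[`, paste0("outlier", level, "_ids")))
      sm <- sympd[vapply(sympd, function(o) m %in% c(o$morphotype_a, o$morphotype_b),
                         logical(1L))]
      in_sym <- unique(unlist(lapply(sm, `[[`, paste0("outlier", level, "_ids"))))
      out[[m]] <- setdiff(in_all, in_sym)
    }
    out
  }
  exp95 <- expected_repeated_count(n_loci, p95, length(sym))
  exp99 <- expected_repeated_count(n_loci, p99, length(sym))
  structure(list(morphotype_pair = mp, locations = locations,
                 n_comparisons = length(sym),
                 sel95_ids = sel95, sel99_ids = sel99,
                 geo95_ids = geo("95"), geo99_ids = geo("99"),
                 expected = c(`95` = exp95$expected, `99` = exp99$expected),
                 binomial_p = c(`95` = exp95$test(length(sel95)),
                                `99` = exp99$test(length(sel99)))),
            class = "repeated_outlier_report")
}

#' Expected repeated-outlier count under neutrality and its exact test
#'
#' Under neutrality a locus exceeds a quantile level independently in each
#' comparison, so the chance of being flagged in all `n_comparisons`
#' comparisons is `per_test_prob^n_comparisons` and the expected number of
#' repeated outliers among `n_loci` polymorphic loci is
#' `E = n_loci * per_test_prob^n_comparisons`. The returned closure performs
#' the exact binomial upper-tail test
#' `Pr(X >= observed), X ~ Binomial(n_loci, per_test_prob^n_comparisons)`.
#'
#' @param n_loci number of polymorphic loci (>= 1).
#' @param per_test_prob per-comparison flag probability, in (0, 1).
#' @param n_comparisons number of comparisons a locus must repeat in (>= 2).
#' @return list with `expected` and `test` (function of the observed count).
#' @export
expected_repeated_count <- function(n_loci, per_test_prob, n_comparisons) {
  stopifnot(n_loci >= 1, per_test_prob > 0, per_test_prob < 1,
            n_comparisons >= 2)
  pi_rep <- per_test_prob^n_comparisons
  list(expected = n_loci * pi_rep,
       test = function(observed) {
         if (observed > n_loci) stop("observed count exceeds the number of loci")
         if (observed <= 0) return(1)
         stats::pbinom(observed - 1L, n_loci, pi_rep, lower.tail = FALSE)
       })
}

#' Cross-method consensus over per-locus selection probabilities
#'
#' Combines repeated envelope outliers with externally supplied per-locus
#' posterior probabilities of directional selection (one probability per
#' geographic comparison, e.g. from a Bayesian genome-scan run on the same
#' pairs). A locus is categorised by how many of its probabilities exceed
#' the threshold: `"Both"` if all do, `"One"` if exactly one does, `"None"`
#' otherwise. Records with missing probabilities are marked incomplete and
#' excluded with a warning.
#'
#' @param records data.frame with columns `locus_id`, `envelope_level`
#'   (e.g. `"95Sel"`/`"99Sel"`) and `probs` (list column of numeric
#'   vectors), or a list of such records.
#' @param threshold probability cutoff (default 0.7); support counts
#'   probabilities strictly greater than it.
#' @return data.frame `locus_id`, `envelope_level`, `n_support`, `category`,
#'   `probs` (formatted).
#' @export
consensus <- function(records, threshold = 0.7) {
  stopifnot(threshold > 0, threshold < 1)
  if (is.data.frame(records)) {
    records <- lapply(seq_len(nrow(records)), function(i)
      list(locus_id = records$locus_id[i],
           envelope_level = records$envelope_level[i],
           probs = records$probs[[i]]))
  }
  rows <- lapply(records, function(r) {
    pr <- as.numeric(r$probs)
    if (!length(pr) || anyNA(pr)) {
      warning("locus ", r$locus_id, " has missing probabilities; excluded")
      return(NULL)
    }
    ns <- sum(pr > threshold)
    cat_lab <- if (ns == length(pr)) "Both" else if (ns == 1L) "One" else "None"
    data.frame(locus_id = r$locus_id, envelope_level = r$envelope_level,
               n_support = ns, category = cat_lab,
               probs = paste(format(pr, trim = TRUE), collapse = " & "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(locus_id = character(0),
                               envelope_level = character(0),
                               n_support = integer(0), category = character(0),
                               probs = character(0)) else out
}
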