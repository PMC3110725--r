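#' Bayesian null-allele frequency estimate for a dominant locus
#'
#' Band absence is the homozygous-recessive phenotype: under Hardy-Weinberg
#' an individual lacks the band with probability q^2, where q is the
#' frequency of the band-absence (null) allele. Given `x` band-absent
#' individuals out of `n`, the likelihood is (q^2)^x (1-q^2)^(n-x); with a
#' Beta(prior_a, prior_b) prior on q the function returns the posterior mean
#' (and variance) of q by deterministic quadrature.
#'
#' Numerically the posterior moments use a fixed 4096-panel composite
#' Simpson rule on \[0, 1\] with the prior density folded into the
#' integrand, verified against one grid doubling (relative tolerance 1e-8).
#' Prior shapes below 1 put an integrable singularity at an endpoint that a
#' fixed grid cannot see; the doubling check detects those cases and they
#' are refined by deterministic adaptive quadrature.
#'
#' @param x number of band-absent individuals (0 <= x <= n).
#' @param n number of scored individuals.
#' @param prior_a,prior_b Beta prior shapes (> 0); default uniform.
#' @param moments if `TRUE` return `c(mean, var)` instead of the mean.
#' @return Posterior mean of q (numeric scalar), or mean and variance.
#' @export
bayes_allele_freq <- function(x, n, prior_a = 1, prior_b = 1, moments = FALSE) {
  if (length(x) != 1L || length(n) != 1L) stop("x and n must be scalars")
  if (is.na(x) || is.na(n) || x < 0 || n < 0) stop("x and n must be non-negative")
  if (x > n) stop("x (band-absent count) cannot exceed n")
  if (prior_a <= 0 || prior_b <= 0) stop("prior shapes must be positive")
  est <- .bayes_q_moments(x, n, prior_a, prior_b)
  if (moments) est else est[[1L]]
}

# Posterior moments of q by composite Simpson on [0, 1] (4096 panels, the
# prior density folded into the integrand), verified by one grid doubling;
# priors with a shape below 1 put an integrable singularity at an endpoint,
# where the fixed grid misses mass - those cases are refined adaptively.
.bayes_q_moments <- function(x, n, a, b) {
  est <- .bayes_q_simpson(x, n, a, b, panels = 4096L)
  chk <- .bayes_q_simpson(x, n, a, b, panels = 8192L)
  if (abs(est[1L] - chk[1L]) <= 1e-8 * max(abs(chk[1L]), 1e-12)) return(est)
  f <- function(q, pow) {
    lw <- pow * log(q) + (a - 1) * log(q) + (b - 1) * log1p(-q)
    if (x > 0) lw <- lw + 2 * x * log(q)
    if (n - x > 0) lw <- lw + (n - x) * log1p(-q^2)
    out <- exp(lw)
    out[!is.finite(out)] <- 0
    out
  }
  I0 <- stats::integrate(f, 0, 1, pow = 0, rel.tol = 1e-10)$value
  I1 <- stats::integrate(f, 0, 1, pow = 1, rel.tol = 1e-10)$value
  I2 <- stats::integrate(f, 0, 1, pow = 2, rel.tol = 1e-10)$value
  mu <- I1 / I0
  c(mean = mu, var = max(I2 / I0 - mu^2, 0))
}

.bayes_q_simpson <- function(x, n, a, b, panels = 4096L) {
  q <- seq(0, 1, length.out = panels + 1L)
  logL <- numeric(panels + 1L)
  if (x > 0) logL <- logL + 2 * x * log(q)
  if (n - x > 0) logL <- logL + (n - x) * log1p(-q^2)
  if (a != 1) logL <- logL + (a - 1) * log(q)
  if (b != 1) logL <- logL + (b - 1) * log1p(-q)
  logL[!is.finite(logL)] <- -Inf   # open interval: singular priors excluded
  mx <- max(logL)
  L <- if (is.finite(mx)) exp(logL - mx) else rep(1, panels + 1L)
  L[!is.finite(L)] <- 0
  w <- c(1, rep(c(4, 2), length.out = panels - 1L), 1) / 3
  I0 <- sum(w * L)
  I1 <- sum(w * q * L)
  I2 <- sum(w * q^2 * L)
  mu <- I1 / I0
  c(mean = mu, var = max(I2 / I0 - mu^2, 0))
}

#' Posterior mean/variance lookup table for all absence counts
#'
#' Convenience memo used by the vectorised estimators: posterior mean and
#' variance of q for every x in 0..n at a fixed sample size and prior. The
#' quadrature grid is shared across counts and results are cached per
#' (n, prior) within the session.
#'
#' @inheritParams bayes_allele_freq
#' @return matrix with columns `mean`, `var` and n + 1 rows (x = 0..n).
#' @export
bayes_qhat_table <- function(n, prior_a = 1, prior_b = 1) {
  key <- sprintf("%d_%.12g_%.12g", as.integer(n), prior_a, prior_b)
  hit <- .qtab_cache[[key]]
  if (!is.null(hit)) return(hit)
  one_grid <- function(panels) {
    q <- seq(0, 1, length.out = panels + 1L)
    lq2 <- 2 * log(q)
    l1q2 <- log1p(-q^2)
    lprior <- numeric(panels + 1L)
    if (prior_a != 1) lprior <- lprior + (prior_a - 1) * log(q)
    if (prior_b != 1) lprior <- lprior + (prior_b - 1) * log1p(-q)
    w <- c(1, rep(c(4, 2), length.out = panels - 1L), 1) / 3
    out <- matrix(NA_real_, n + 1L, 2L,
                  dimnames = list(NULL, c("mean", "var")))
    for (x in 0:n) {
      logL <- lprior
      if (x > 0) logL <- logL + x * lq2
      if (n - x > 0) logL <- logL + (n - x) * l1q2
      logL[!is.finite(logL)] <- -Inf   # open interval: singular priors excluded
      mx <- max(logL)
      L <- if (is.finite(mx)) exp(logL - mx) else rep(1, panels + 1L)
      L[!is.finite(L)] <- 0
      I0 <- sum(w * L); I1 <- sum(w * q * L); I2 <- sum(w * q^2 * L)
      mu <- I1 / I0
      out[x + 1L, ] <- c(mu, max(I2 / I0 - mu^2, 0))
    }
    out
  }
  est <- one_grid(4096L)
  chk <- one_grid(8192L)
  bad <- abs(est[, "mean"] - chk[, "mean"]) >
    1e-8 * pmax(abs(chk[, "mean"]), 1e-12)
  for (x in which(bad) - 1L) {
    est[x + 1L, ] <- .bayes_q_moments(x, n, prior_a, prior_b)
  }
  .qtab_cache[[key]] <- est
  est
}

.qtab_cache <- new.env(parent = emptyenv())

#' Fit a non-uniform Beta prior from across-locus band-absence fractions
#'
#' Method-of-moments fit of a Beta distribution to the naive per-locus
#' null-allele frequency estimates sqrt(band-absence fraction). The fitted
#' prior feeds [bayes_allele_freq()], mirroring the data-driven prior used
#' for dominant-marker surveys. Shapes are clamped to \[0.1, 100\]. With
#' fewer than 10 usable loci or a degenerate variance the fit falls back to
#' the uniform prior with a warning.
#'
#' @param band_absence_fractions per-locus fractions of band-absent
#'   individuals, in \[0, 1\].
#' @return `c(prior_a, prior_b)`.
#' @export
fit_nonuniform_prior <- function(band_absence_fractions) {
  f <- band_absence_fractions
  f <- f[!is.na(f)]
  if (length(f) < 10L) stop("need at least 10 loci with defined absence fractions")
  if (any(f < 0 | f > 1)) stop("absence fractions must be in [0, 1]")
  s <- sqrt(f)
  m <- mean(s); v <- stats::var(s)
  if (v < 1e-10 || m <= 0 || m >= 1 || v >= m * (1 - m)) {
    warning("degenerate absence-fraction distribution; falling back to uniform prior")
    return(c(prior_a = 1, prior_b = 1))
  }
  k <- m * (1 - m) / v - 1
  shapes <- c(prior_a = m * k, prior_b = (1 - m) * k)
  pmin(pmax(shapes, 0.1), 100)
}

#' Estimate per-locus, per-population null-allele frequencies
#'
#' Applies the Bayesian dominant-marker estimator to every locus in every
#' population. The prior defaults to a single non-uniform prior fitted from
#' the pooled across-locus absence fractions of the populations analysed
#' (`prior = "fitted"`); `prior = "uniform"` or a numeric `c(a, b)` are also
#' accepted.
#'
#' @param x a [genotype_matrix()].
#' @param groups factor/character vector assigning each row of `x` to a
#'   population.
#' @param prior `"fitted"`, `"uniform"`, or numeric shapes `c(a, b)`.
#' @return list with `q`, `pv` (posterior variance), `h` (expected
#'   heterozygosity 2q(1-q)), `n`, `x_absent`: loci x populations matrices;
#'   plus `prior`, the shapes used.
#' @export
estimate_allele_freqs <- function(x, groups, prior = "fitted") {
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(x))
  pops <- unique(groups)
  L <- ncol(x)
  n_mat <- x_mat <- matrix(0L, L, length(pops),
                           dimnames = list(colnames(x), pops))
  for (j in seq_along(pops)) {
    sub <- unclass(x)[groups == pops[j], , drop = FALSE]
    n_mat[, j] <- colSums(!is.na(sub))
    x_mat[, j] <- colSums(sub == 0L, na.rm = TRUE)
  }
  shapes <- .resolve_prior(prior, x_mat, n_mat)
  q_mat <- pv_mat <- matrix(NA_real_, L, length(pops),
                            dimnames = list(colnames(x), pops))
  for (nn in unique(as.vector(n_mat))) {
    if (nn == 0L) next
    tab <- bayes_qhat_table(nn, shapes[1L], shapes[2L])
    idx <- which(n_mat == nn)
    q_mat[idx] <- tab[x_mat[idx] + 1L, "mean"]
    pv_mat[idx] <- tab[x_mat[idx] + 1L, "var"]
  }
  list(q = q_mat, pv = pv_mat, h = 2 * q_mat * (1 - q_mat),
       n = n_mat, x_absent = x_mat, prior = shapes)
}

.resolve_prior <- function(prior, x_mat, n_mat) {
  if (is.numeric(prior)) {
    stopifnot(length(prior) == 2L, all(prior > 0))
    return(c(prior_a = prior[1L], prior_b = prior[2L]))
  }
  prior <- match.arg(prior, c("fitted", "uniform"))
  if (prior == "uniform") return(c(prior_a = 1, prior_b = 1))
  ok <- n_mat > 0L
  fr <- (x_mat[ok] / n_mat[ok])
  tryCatch(fit_nonuniform_prior(fr),
           error = function(e) c(prior_a = 1, prior_b = 1))
}

#' Per-locus FST from population null-allele frequencies
#'
#' Variance-component estimator for one locus: with sample-size-weighted
#' mean frequency `qbar` and among-population variance of q (divisor k - 1,
#' sample-size weights) corrected for the sampling variance of each
#' frequency estimate, `fst = corrected among-population variance /
#' (qbar (1 - qbar))`. Negative estimates are retained; when
#' `qbar (1 - qbar) = 0` the convention is `fst = 0`. Because the
#' among-population variance uses the k - 1 divisor (which keeps the
#' multilocus ratio-of-sums mean unbiased), single-locus values can exceed 1
#' for populations fixed for opposite alleles (maximum k/(k-1)).
#'
#' The sampling-variance correction defaults to the posterior variances of
#' the Bayesian estimates (`sampling_var`), the uncertainty the
#' dominant-marker model itself reports. Passing `sampling_var = NULL`
#' disables the correction (the infinite-sample limit).
#'
#' @param q per-population null-allele frequency estimates (length >= 2).
#' @param n per-population sample sizes (weights); equal weights if `NULL`.
#' @param sampling_var per-population sampling variances of `q`, or `NULL`.
#' @return list with `fst`, `num` (corrected among-population variance),
#'   `den` (qbar(1-qbar)), `qbar`.
#' @export
locus_fst <- function(q, n = NULL, sampling_var = NULL) {
  k <- length(q)
  if (k < 2L) stop("locus_fst needs at least two populations")
  if (is.null(n)) n <- rep(1, k)
  stopifnot(length(n) == k)
  w <- n / sum(n)
  qbar <- sum(w * q)
  nbar <- sum(n) / k
  s2 <- sum(n * (q - qbar)^2) / ((k - 1) * nbar)
  corr <- if (is.null(sampling_var)) 0 else sum(w * sampling_var)
  num <- s2 - corr
  den <- qbar * (1 - qbar)
  fst <- if (den > 0) num / den else 0
  list(fst = fst, num = num, den = den, qbar = qbar)
}

#' Multilocus FST summary for a set of populations
#'
#' Computes per-locus FST values from the output of
#' [estimate_allele_freqs()], the multilocus mean as the ratio of summed
#' variance components (numerator and denominator summed over loci), the
#' 30%-trimmed mean of the per-locus values, and mean per-locus
#' heterozygosity.
#'
#' @param freqs result of [estimate_allele_freqs()].
#' @param trim_fraction fraction trimmed from each tail for the trimmed mean.
#' @return list with `per_locus` (data.frame `locus_id`, `fst`, `mean_h`),
#'   `mean_fst`, `trimmed_mean_fst`.
#' @export
multilocus_fst <- function(freqs, trim_fraction = 0.30) {
  L <- nrow(freqs$q)
  fst <- num <- den <- rep(NA_real_, L)
  mean_h <- rowMeans(freqs$h, na.rm = TRUE)
  for (l in seq_len(L)) {
    use <- freqs$n[l, ] > 0L
    if (sum(use) < 2L) next
    r <- locus_fst(freqs$q[l, use], freqs$n[l, use], freqs$pv[l, use])
    fst[l] <- r$fst; num[l] <- r$num; den[l] <- r$den
  }
  ok <- !is.na(fst)
  list(per_locus = data.frame(locus_id = rownames(freqs$q), fst = fst,
                              mean_h = mean_h, num = num, den = den,
                              stringsAsFactors = FALSE),
       mean_fst = sum(num[ok]) / sum(den[ok]),
       trimmed_mean_fst = trimmed_mean(fst[ok], trim_fraction))
}

#' Trimmed mean
#'
#' Sorts the values, removes `floor(trim_fraction * length)` from each end
#' and averages the remainder. The 30% trim is the robust neutral-background
#' summary used to calibrate neutral simulations.
#'
#' @param values numeric vector (non-empty).
#' @param trim_fraction in \[0, 0.5).
#' @return Arithmetic mean of the retained values.
#' @export
trimmed_mean <- function(values, trim_fraction = 0.30) {
  if (!length(values)) stop("no values to average")
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stop("trim_fraction must be in [0, 0.5)")
  v <- sort(values)
  k <- floor(trim_fraction * length(v))
  if (2L * k >= length(v)) stop("trimming removed all values")
  mean(v[(k + 1L):(length(v) - k)])
}

#' Permutation test for multilocus differentiation
#'
#' Permutes individuals among groups, recomputing the multilocus mean FST
#' each time. The p value is the probability of a permuted mean FST as high
#' as or higher than the observed one, with the observed arrangement counted:
#' `p = (1 + #{perm >= obs}) / (n_perm + 1)`. The allele-frequency prior is
#' fitted once from the observed data and held fixed across permutations.
#'
#' @param x a [genotype_matrix()].
#' @param groups population label per row of `x` (two or more groups).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param prior passed to [estimate_allele_freqs()].
#' @return list with `observed` mean FST, `p_value`, `n_perm`, `perm` (the
#'   permuted means).
#' @export
permutation_test_fst <- function(x, groups, n_perm = 1000L, seed = 1L,
                                 prior = "fitted") {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L) stop("need two or more groups")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  fr <- estimate_allele_freqs(x, groups, prior)
  shapes <- fr$prior
  obs <- multilocus_fst(fr)$mean_fst
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    g <- sample(groups)
    multilocus_fst(estimate_allele_freqs(x, g, shapes))$mean_fst
  }, numeric(1L))
  list(observed = obs,
       p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
       n_perm = n_perm, perm = perm)
}
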