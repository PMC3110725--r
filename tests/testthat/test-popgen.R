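# independent fine-grid trapezoid oracle for the posterior mean of q
trapezoid_posterior_mean <- function(x, n, a = 1, b = 1, grid = 2e5) {
  q <- seq(0, 1, length.out = grid + 1)
  logw <- numeric(grid + 1)
  if (x > 0) logw <- logw + 2 * x * log(q)
  if (n - x > 0) logw <- logw + (n - x) * log1p(-q^2)
  if (a != 1) logw <- logw + (a - 1) * log(q)
  if (b != 1) logw <- logw + (b - 1) * log1p(-q)
  logw[is.nan(logw)] <- -Inf
  w <- exp(logw - max(logw[is.finite(logw)]))
  w[c(1, grid + 1)] <- w[c(1, grid + 1)] / 2   # trapezoid end weights
  sum(q * w) / sum(w)
}

test_that("posterior mean of q matches the quadrature oracle", {
  expect_equal(bayes_allele_freq(5, 10), trapezoid_posterior_mean(5, 10),
               tolerance = 1e-6)
  for (case in list(c(0, 10), c(3, 25), c(40, 40), c(17, 40))) {
    expect_equal(bayes_allele_freq(case[1], case[2]),
                 trapezoid_posterior_mean(case[1], case[2]),
                 tolerance = 1e-6)
  }
  # non-uniform prior
  expect_equal(bayes_allele_freq(4, 12, 2, 5),
               trapezoid_posterior_mean(4, 12, 2, 5), tolerance = 1e-6)
})

test_that("with no data the posterior mean is the prior mean", {
  expect_equal(bayes_allele_freq(0, 0), 0.5)
  expect_equal(bayes_allele_freq(0, 0, 2, 6), 0.25, tolerance = 1e-8)
})

test_that("posterior mean is strictly increasing in the absence count", {
  q <- vapply(0:10, bayes_allele_freq, 0, n = 10)
  expect_true(all(diff(q) > 0))
  expect_gt(bayes_allele_freq(9, 10), bayes_allele_freq(1, 10))
  expect_true(all(q > 0 & q < 1))
  tab <- bayes_qhat_table(10)
  expect_equal(tab[, "mean"], q, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the non-uniform prior fit recovers known Beta shapes", {
  set.seed(31)
  q <- rbeta(5000, 2, 5)
  shapes <- fit_nonuniform_prior(q^2)  # noiseless phenotype model
  expect_lt(abs(shapes[1] - 2) / 2, 0.15)
  expect_lt(abs(shapes[2] - 5) / 5, 0.15)

  expect_warning(sh <- fit_nonuniform_prior(rep(0.25, 50)), "degenerate")
  expect_equal(unname(sh), c(1, 1))

  sh2 <- suppressWarnings(
    fit_nonuniform_prior(c(rep(0.2500001, 49), 0.2500002) + 0))
  expect_true(all(sh2 <= 100))
})

test_that("locus FST handles the canonical limits", {
  expect_equal(locus_fst(c(0.3, 0.3, 0.3))$fst, 0)
  # opposite fixation: with the k-1-divisor among-population variance over
  # the pooled-frequency variance, two demes at (0, 1) reach the estimator's
  # maximum k/(k-1) = 2 (per-locus values may exceed 1; the multilocus
  # ratio-of-sums stays on the usual scale)
  expect_equal(locus_fst(c(0, 1))$fst, 2)
  expect_equal(locus_fst(c(1, 1))$fst, 0)  # qbar(1-qbar) = 0 convention
})

test_that("locus FST equals an independent evaluation of the formula", {
  set.seed(17)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    q <- runif(k, 0.05, 0.95)
    n <- sample(10:90, k, replace = TRUE)
    sv <- runif(k, 0, 0.002)
    r <- locus_fst(q, n, sv)
    # plain transcription of the variance-component definition
    w <- n / sum(n)
    qb <- sum(w * q)
    s2 <- sum(n * (q - qb)^2) / ((k - 1) * mean(n))
    expect_equal(r$fst, (s2 - sum(w * sv)) / (qb * (1 - qb)), tolerance = 1e-12)
  }
  q <- c(0.1, 0.9)
  r <- locus_fst(q, c(1e6, 1e6))
  expect_equal(r$fst, ((0.4^2) * 2 / 1) / 0.25, tolerance = 1e-9)
})

test_that("locus FST is invariant to population order and allele relabeling", {
  set.seed(23)
  q <- runif(4); n <- sample(10:50, 4); sv <- runif(4, 0, 1e-3)
  perm <- sample(4)
  expect_equal(locus_fst(q, n, sv)$fst,
               locus_fst(q[perm], n[perm], sv[perm])$fst, tolerance = 1e-12)
  expect_equal(locus_fst(q, n, sv)$fst, locus_fst(1 - q, n, sv)$fst,
               tolerance = 1e-12)
  expect_error(locus_fst(0.5), "two populations")
})

test_that("trimmed mean matches sort-and-slice and its edge cases", {
  expect_equal(trimmed_mean(1:10, 0.30), 5.5)
  expect_equal(trimmed_mean(rep(3.2, 7), 0.4), 3.2)
  expect_equal(trimmed_mean(1:10, 0), mean(1:10))
  set.seed(4)
  v <- rnorm(137)
  k <- floor(0.3 * 137)
  expect_equal(trimmed_mean(v, 0.3),
               mean(sort(v)[(k + 1):(137 - k)]), tolerance = 1e-12)
  expect_error(trimmed_mean(numeric(0)), "no values")
  expect_error(trimmed_mean(1:3, 0.5), "trim_fraction")
})

test_that("multilocus FST recovers the generating differentiation", {
  ds <- generate_dataset(two_pop_config(seed = 101, n_loci = 2000, fst = 0.05))
  fr <- estimate_allele_freqs(ds$genotypes, ds$metadata$morphotype)
  ml <- multilocus_fst(fr)
  ok <- !is.na(ml$per_locus$fst)
  # jackknife standard error of the ratio-of-sums estimate
  num <- ml$per_locus$num[ok]; den <- ml$per_locus$den[ok]
  jk <- (sum(num) - num) / (sum(den) - den)
  se <- sqrt((length(jk) - 1) * mean((jk - mean(jk))^2))
  expect_lt(abs(ml$mean_fst - 0.05), 3 * se)
})

test_that("identical groups give a central permutation p value", {
  gm <- make_calls(20, 60, seed = 55)
  g2 <- genotype_matrix(rbind(unclass(gm),
                              `rownames<-`(unclass(gm), paste0(rownames(gm), "_c"))))
  labels <- rep(c("A", "B"), each = 20)
  r <- permutation_test_fst(g2, labels, n_perm = 199, seed = 3)
  expect_gt(r$p_value, 0.5)
})

test_that("fixed differences give the minimal permutation p value", {
  m <- rbind(matrix(0L, 15, 50), matrix(1L, 15, 50))
  rownames(m) <- sprintf("s%02d", 1:30)
  colnames(m) <- sprintf("L%02d", 1:50)
  # every locus has absence fraction 1/2, so the data-driven prior fit is
  # degenerate and falls back to uniform with a warning
  r <- suppressWarnings(
    permutation_test_fst(genotype_matrix(m), rep(c("A", "B"), each = 15),
                         n_perm = 1000, seed = 8))
  expect_equal(r$p_value, 1 / 1001)
  expect_equal(r$n_perm, 1000)
  expect_equal(formals(permutation_test_fst)$n_perm, 1000L)
})

test_that("permutation p values are super-uniform under the null", {
  set.seed(99)
  hits <- vapply(1:200, function(i) {
    m <- matrix(rbinom(24 * 40, 1L, runif(1, 0.3, 0.7)), 24, 40,
                dimnames = list(sprintf("s%02d", 1:24), sprintf("L%02d", 1:40)))
    gm <- filter_polymorphic(genotype_matrix(m))
    r <- permutation_test_fst(gm, rep(c("A", "B"), each = 12),
                              n_perm = 99, seed = i, prior = "uniform")
    r$p_value <= 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.08)
})
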