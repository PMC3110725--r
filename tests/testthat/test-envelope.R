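test_that("simulation defaults record the island-model parameters", {
  p <- simulation_params()
  expect_equal(p$effective_size, 10000)
  expect_equal(p$mutation_rate, 1e-5)
  expect_equal(p$n_sim_loci, 50000L)
})

test_that("the panmixia limit yields a mean FST near zero", {
  p <- simulation_params(migration_scaler = 1e5, n_sim_loci = 20000L,
                         seed = 61)
  cloud <- simulate_neutral_loci(p)
  expect_lt(abs(attr(cloud, "mean_fst")), 0.005)
})

test_that("the simulated cloud matches an independent forward-sampling oracle", {
  # naive re-implementation: same Balding-Nichols model, plain resampling,
  # with q estimated by direct grid integration (no shared package code)
  set.seed(71)
  n <- 40; F <- 0.05; L <- 20000; theta <- 0.4
  qhat_grid <- function(x) {
    q <- seq(1e-7, 1 - 1e-7, length.out = 20001)
    w <- exp(2 * x * log(q) + (n - x) * log1p(-q^2) -
               max(2 * x * log(q) + (n - x) * log1p(-q^2)))
    c(sum(q * w) / sum(w),
      sum(q^2 * w) / sum(w) - (sum(q * w) / sum(w))^2)
  }
  tab <- t(vapply(0:n, qhat_grid, c(0, 0)))
  x1 <- x2 <- integer(0)
  while (length(x1) < L) {
    p0 <- rbeta(L, theta, theta)
    pa <- rbeta(L, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
    pb <- rbeta(L, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
    a <- rbinom(L, n, (1 - pa)^2); b <- rbinom(L, n, (1 - pb)^2)
    keep <- (a + b > 0) & (a + b < 2 * n)
    x1 <- c(x1, a[keep]); x2 <- c(x2, b[keep])
  }
  x1 <- x1[1:L]; x2 <- x2[1:L]
  q1 <- tab[x1 + 1, 1]; q2 <- tab[x2 + 1, 1]
  s2 <- (q1 - q2)^2 / 2
  num <- s2 - (tab[x1 + 1, 2] + tab[x2 + 1, 2]) / 2
  den <- ((q1 + q2) / 2) * (1 - (q1 + q2) / 2)
  oracle_fst <- ifelse(den > 0, num / den, 0)

  # package cloud with the migration scaler solving F = 0.05
  d <- 100
  M <- (1 / F - 1) / (4 * (d / (d - 1))^2)
  p <- simulation_params(migration_scaler = M, n_sim_loci = L, seed = 72)
  cloud <- simulate_neutral_loci(p)

  se_mean <- sqrt(var(oracle_fst) / L + var(cloud$fst) / L)
  expect_lt(abs(mean(cloud$fst) - mean(oracle_fst)), 3 * se_mean)
  # variances agree within 3 SE (normal-theory SE of a variance)
  se_var <- sqrt(2 / L) * (var(oracle_fst) + var(cloud$fst)) / 2 * sqrt(2)
  expect_lt(abs(var(cloud$fst) - var(oracle_fst)), 3 * se_var)
})

test_that("calibration hits the requested trimmed mean from above", {
  p <- simulation_params(n_sim_loci = 8000L, seed = 81)
  cal <- calibrate_to_trimmed_mean(0.05, p)
  realized <- attr(cal, "realized_trimmed_fst")
  expect_gte(realized, 0.05)
  expect_lte(realized, 0.055)

  # already-calibrated target returns promptly and reproducibly
  cal2 <- calibrate_to_trimmed_mean(0.05, p)
  expect_identical(cal$migration_scaler, cal2$migration_scaler)
})

test_that("stronger targets calibrate to stronger differentiation", {
  p <- simulation_params(n_sim_loci = 6000L, seed = 82)
  cal_hi <- calibrate_to_trimmed_mean(0.10, p)
  cal_lo <- calibrate_to_trimmed_mean(0.02, p)
  # F decreases in the migration scaler
  expect_lt(cal_hi$migration_scaler, cal_lo$migration_scaler)
})

test_that("envelope p values and flags match a brute-force oracle", {
  set.seed(91)
  cloud <- data.frame(fst = c(rnorm(950, 0.05, 0.04),
                              sample(c(0.1, 0.2), 50, TRUE)),  # ties
                      mean_h = runif(1000, 0, 0.5))
  obs <- data.frame(locus_id = sprintf("L%02d", 1:50),
                    fst = c(cloud$fst[1:45] + 0.001, 0.1, 0.2, 0.9, -0.2, 0.05),
                    mean_h = runif(50, 0, 0.5))

  env <- envelope_p_values(obs, cloud, window_rule = "hbins", n_bins = 4)
  edges <- quantile(cloud$mean_h, probs = seq(0, 1, length.out = 5),
                    names = FALSE)
  edges[1] <- -Inf; edges[5] <- Inf
  for (j in seq_len(nrow(obs))) {
    b <- min(max(findInterval(obs$mean_h[j], edges), 1), 4)
    fw <- cloud$fst[findInterval(cloud$mean_h, edges, rightmost.closed = TRUE) == b]
    gt <- sum(fw > obs$fst[j]); eq <- sum(fw == obs$fst[j])
    p_oracle <- (gt + 0.5 * eq + 0.5) / (length(fw) + 1)
    expect_identical(env$p_value[j], p_oracle)
    expect_identical(env$outlier95[j], p_oracle <= 0.05)
    expect_identical(env$outlier99[j], p_oracle <= 0.01)
  }

  env_k <- envelope_p_values(obs, cloud, window_rule = "knn", k = 200)
  ord <- order(cloud$mean_h)
  for (j in seq_len(nrow(obs))) {
    d <- abs(cloud$mean_h[ord] - obs$mean_h[j])
    win <- ord[order(d)[1:200]]
    fw <- cloud$fst[win]
    gt <- sum(fw > obs$fst[j]); eq <- sum(fw == obs$fst[j])
    expect_equal(env_k$p_value[j], (gt + 0.5 * eq + 0.5) / 201)
  }
})

test_that("an extreme observed locus gets the smallest p and both flags", {
  cloud <- data.frame(fst = runif(2000, 0, 0.2), mean_h = runif(2000, 0, 0.5))
  obs <- data.frame(locus_id = "L1", fst = 0.99, mean_h = 0.25)
  env <- envelope_p_values(obs, cloud, n_bins = 4)
  n_bin <- sum(findInterval(cloud$mean_h,
    {e <- quantile(cloud$mean_h, seq(0, 1, .25), names = FALSE)
     e[1] <- -Inf; e[5] <- Inf; e}, rightmost.closed = TRUE) ==
    min(max(findInterval(0.25, {e <- quantile(cloud$mean_h, seq(0, 1, .25),
      names = FALSE); e[1] <- -Inf; e[5] <- Inf; e}), 1), 4))
  expect_equal(env$p_value, 0.5 / (n_bin + 1))
  expect_true(env$outlier95 && env$outlier99)

  mid <- data.frame(locus_id = "L2", fst = median(cloud$fst), mean_h = 0.25)
  env_mid <- envelope_p_values(mid, cloud, n_bins = 4)
  expect_lt(abs(env_mid$p_value - 0.5), 0.05)
})

test_that("99% outliers are always 95% outliers and windows have a floor", {
  set.seed(93)
  cloud <- data.frame(fst = rnorm(3000, 0.05, 0.05),
                      mean_h = runif(3000, 0, 0.5))
  obs <- data.frame(locus_id = sprintf("L%03d", 1:300),
                    fst = rnorm(300, 0.08, 0.08), mean_h = runif(300, 0, 0.5))
  env <- envelope_p_values(obs, cloud)
  expect_true(all(env$outlier95[env$outlier99]))
  expect_true(all(env$p_value > 0 & env$p_value < 1))
  expect_error(envelope_p_values(obs, cloud, window_rule = "knn", k = 50),
               "smaller than 100")
})

test_that("envelope results are reproducible under a fixed seed", {
  p <- simulation_params(n_sim_loci = 5000L, seed = 94)
  c1 <- simulate_neutral_loci(p)
  c2 <- simulate_neutral_loci(p)
  expect_identical(c1, c2)
})

test_that("p-value balance diagnostic matches the textbook t statistic", {
  balanced <- list(c(0.2, 0.8, 0.3, 0.7), c(0.1, 0.9))
  r <- pvalue_balance_diagnostic(balanced)
  expect_equal(r$mean_difference, 0)
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)

  # constant nonzero differences: degenerate variance, flagged
  envs <- lapply(1:4, function(i) c(0.6, 0.7, 0.4))  # diff = +1 each
  r2 <- pvalue_balance_diagnostic(envs)
  expect_true(r2$degenerate)
  expect_equal(r2$t_statistic, Inf)

  set.seed(5)
  for (i in 1:10) {
    m <- sample(3:8, 1)
    ps <- lapply(seq_len(m), function(j) runif(sample(5:40, 1)))
    r3 <- pvalue_balance_diagnostic(ps)
    d <- vapply(ps, function(p) sum(p > 0.5) - sum(p < 0.5), 0)
    tt <- mean(d) / (sd(d) / sqrt(m))
    if (sd(d) > 0) {
      expect_equal(r3$t_statistic, tt, tolerance = 1e-10)
      expect_equal(r3$p_value, t.test(d)$p.value, tolerance = 1e-10)
    }
  }
  expect_error(pvalue_balance_diagnostic(list(runif(5))), "at least two")
})

test_that("neutral envelope p values pool to an approximately uniform law", {
  set.seed(202)
  seeds <- sample.int(2^31 - 2, 48)
  pooled <- unlist(lapply(1:24, function(i) {
    ds <- generate_dataset(two_pop_config(seed = seeds[i], n_loci = 436))
    pair <- first_sympatric_pair(ds$metadata)
    sc <- neutral_scan(ds$genotypes, ds$metadata, pair, n_sim_loci = 20000L,
                       n_calibration_loci = 8000L, seed = seeds[24 + i])
    sc$envelope$p_value
  }))
  expect_gte(length(pooled), 10000)
  ks <- max(abs(sort(pooled) - seq_along(pooled) / length(pooled)),
            abs(sort(pooled) - (seq_along(pooled) - 1) / length(pooled)))
  expect_lt(ks, 0.05)
})
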