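make_outcome <- function(morph_a, morph_b, loc_a, loc_b, ids95, ids99,
                         n_loci = 100) {
  pair <- list(pop_a = paste0(morph_a, "@", loc_a),
               pop_b = paste0(morph_b, "@", loc_b),
               morphotype_a = morph_a, morphotype_b = morph_b,
               location_a = loc_a, location_b = loc_b,
               design_class = classify_pair(
                 list(morphotype = morph_a, location = loc_a),
                 list(morphotype = morph_b, location = loc_b)))
  env <- data.frame(locus_id = sprintf("L%03d", seq_len(n_loci)),
                    fst = 0, mean_h = 0.2, p_value = 0.5,
                    outlier95 = FALSE, outlier99 = FALSE)
  env$outlier95[match(ids95, env$locus_id)] <- TRUE
  env$outlier99[match(ids99, env$locus_id)] <- TRUE
  comparison_outcome(pair, env)
}

test_that("Mann-Whitney U matches brute-force pair counting", {
  x <- c(6, 7, 8); y <- c(5, 5, 5)
  r <- mann_whitney_u(x, y)
  brute <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(r$U, brute)
  expect_equal(r$U, 9)

  set.seed(14)
  for (i in 1:20) {
    x <- sample(0:10, sample(3:12, 1), replace = TRUE)
    y <- sample(0:10, sample(3:12, 1), replace = TRUE)
    r <- mann_whitney_u(x, y)
    expect_equal(r$U, sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "==")))
    if (stats::sd(c(x, y)) > 0) {
      ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                          correct = FALSE))
      expect_equal(r$U, unname(ref$statistic))
      expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("complete ties against the expectation give p = 1", {
  oc <- lapply(1:5, function(i)
    make_outcome("a", "b", paste0("loc", i), paste0("loc", i),
                 sprintf("L%03d", 1:5), sprintf("L%03d", 1:1)))
  tab <- outlier_frequency_table(oc)  # pct95 = 5, pct99 = 1 everywhere
  row95 <- tab[tab$design_class == "sympatric-different" & tab$level == "95", ]
  expect_equal(row95$observed_mean_pct, 5)
  expect_equal(row95$p_value, 1)
})

test_that("zero observed outliers give maximal one-sided dominance in U", {
  oc <- lapply(1:9, function(i)
    make_outcome("a", "b", paste0("loc", i), paste0("loc", i),
                 character(0), character(0)))
  tab <- outlier_frequency_table(oc)
  row95 <- tab[tab$design_class == "sympatric-different" & tab$level == "95", ]
  expect_equal(row95$observed_mean_pct, 0)
  expect_equal(row95$U, 0)  # no observed percentage exceeds the expectation
  expect_lt(row95$p_value, 0.001)
})

test_that("repeated outliers implement the Sel designation set algebra", {
  # flagged at 99% in c-vs-p at both locations -> 99Sel and 95Sel
  oc <- list(
    make_outcome("chlorurus", "puella", "Curacao", "Curacao",
                 c("L001", "L002", "L010"), c("L001", "L010")),
    make_outcome("chlorurus", "puella", "Panama", "Panama",
                 c("L001", "L003", "L010"), c("L001", "L002")))
  rep1 <- repeated_outliers(oc, c("chlorurus", "puella"), n_loci = 423)
  expect_setequal(rep1$sel95_ids, c("L001", "L010"))
  expect_setequal(rep1$sel99_ids, "L001")
  expect_true(all(rep1$sel99_ids %in% rep1$sel95_ids))

  # flagged at one location only -> not Sel at any level
  oc2 <- list(
    make_outcome("chlorurus", "puella", "Curacao", "Curacao",
                 "L005", character(0)),
    make_outcome("chlorurus", "puella", "Panama", "Panama",
                 character(0), character(0)))
  rep2 <- repeated_outliers(oc2, c("chlorurus", "puella"))
  expect_length(rep2$sel95_ids, 0)

  # single location: empty report, not an error
  rep3 <- repeated_outliers(oc[1], c("chlorurus", "puella"))
  expect_equal(rep3$n_comparisons, 1L)
  expect_length(rep3$sel95_ids, 0)
})

test_that("repeated outliers match a set-algebra oracle on random flags", {
  set.seed(33)
  ids <- sprintf("L%03d", 1:60)
  for (trial in 1:10) {
    flags <- function() sample(ids, rpois(1, 6))
    f99 <- function(f95) sample(f95, min(length(f95), rpois(1, 2)))
    oA95 <- flags(); oA99 <- f99(oA95)
    oB95 <- flags(); oB99 <- f99(oB95)
    gA95 <- flags(); gA99 <- f99(gA95)
    gB95 <- flags(); gB99 <- f99(gB95)
    oc <- list(
      make_outcome("m1", "m2", "X", "X", oA95, oA99),
      make_outcome("m1", "m2", "Y", "Y", oB95, oB99),
      make_outcome("m1", "m1", "X", "Y", gA95, gA99),
      make_outcome("m1", "m1", "X", "Z", gB95, gB99))
    r <- repeated_outliers(oc, c("m1", "m2"), n_loci = 60)
    expect_setequal(r$sel95_ids, intersect(oA95, oB95))
    expect_setequal(r$sel99_ids, intersect(oA99, oB99))
    expect_setequal(r$geo95_ids$m1,
                    setdiff(intersect(gA95, gB95), union(oA95, oB95)))
    expect_setequal(r$geo99_ids$m1,
                    setdiff(intersect(gA99, gB99), union(oA99, oB99)))
  }
})

test_that("expected repeated counts and the exact binomial tail are correct", {
  e <- expected_repeated_count(423, 0.05, 2)
  expect_equal(e$expected, 423 * 0.0025)
  expect_equal(e$expected, 1.0575)
  expect_equal(e$test(0), 1)

  # brute-force pmf summation oracle
  pmf_tail <- function(obs, n, p) sum(dbinom(obs:n, n, p))
  expect_equal(e$test(3), pmf_tail(3, 423, 0.0025), tolerance = 1e-12)
  e99 <- expected_repeated_count(423, 0.01, 2)
  for (obs in c(1, 2, 5)) {
    expect_equal(e99$test(obs), pmf_tail(obs, 423, 1e-4), tolerance = 1e-12)
  }
  expect_error(e$test(500), "exceeds")
})

test_that("consensus categories follow the threshold-count semantics", {
  recs <- data.frame(locus_id = c("Mctc309", "Mcac168", "Mcnone"),
                     envelope_level = c("95Sel", "95Sel", "99Sel"))
  recs$probs <- list(c(0.74, 0.80), c(0.75, 0.65), c(0.40, 0.10))
  out <- consensus(recs)
  expect_equal(out$category, c("Both", "One", "None"))
  expect_equal(out$n_support, c(2L, 1L, 0L))

  # threshold is strict: 0.7 itself is not support
  out2 <- consensus(data.frame(locus_id = "x", envelope_level = "95Sel",
                               probs = I(list(c(0.7, 0.9)))))
  expect_equal(out2$category, "One")

  recs_na <- data.frame(locus_id = c("a", "b"), envelope_level = "95Sel")
  recs_na$probs <- list(c(0.8, NA), c(0.9, 0.8))
  expect_warning(out3 <- consensus(recs_na), "missing probabilities")
  expect_equal(nrow(out3), 1L)
  expect_equal(out3$locus_id, "b")
})
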