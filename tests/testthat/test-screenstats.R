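test_that("strong-adhesion calls use a strict 0.2 cutoff", {
  expect_false(strong_adhesion_call(0.19))
  expect_false(strong_adhesion_call(0.2))
  expect_true(strong_adhesion_call(0.21))
})

test_that("percentile threshold uses linear interpolation", {
  expect_equal(percentile_threshold(1:100, 95), 95.05)
  expect_equal(percentile_threshold(rep(3.2, 10)), 3.2)
  expect_error(percentile_threshold(1), "at least 2")
})

test_that("percentile threshold separates planted positives from nulls", {
  scr <- simulate_screen(n_strains = 400, seed = 2)
  means <- tapply(scr$replicates$ratio, scr$replicates$strain, mean)
  thr <- percentile_threshold(as.numeric(means), 95)
  pos <- scr$truth$adhesive[match(names(means), scr$truth$strain)]
  expect_true(all(means[pos] > thr))
  expect_lt(mean(means[!pos] > thr), 0.01)
})

test_that("elbow threshold maximizes distance to the chord", {
  vals <- c(10, 9, 8, 1, 1, 1, 1, 1, 1)
  # brute-force oracle over all indices
  y <- sort(vals, decreasing = TRUE)
  n <- length(y)
  d <- vapply(seq_len(n), function(i) {
    abs((y[n] - y[1]) * (i - 1) - (n - 1) * (y[i] - y[1])) /
      sqrt((n - 1)^2 + (y[n] - y[1])^2)
  }, numeric(1))
  expect_equal(elbow_threshold(vals), y[which.max(d)])
  # the knee sits at the 8 -> 1 break: the first value after the drop, so
  # exactly the strains before the break exceed the threshold
  expect_equal(elbow_threshold(vals), 1)
  expect_equal(sum(vals > elbow_threshold(vals)), 3)

  expect_warning(mid <- elbow_threshold(seq(10, 1)), "linear|elbow")
  expect_equal(mid, 6)
  expect_warning(flat <- elbow_threshold(rep(2, 5)), "linear|elbow")
  expect_equal(flat, 2)
})

test_that("elbow threshold separates the components of a planted mixture", {
  hits <- 0
  for (s in 1:20) {
    strong <- withr::with_seed(s, rnorm(20, 10, 0.5))
    weak <- withr::with_seed(1000 + s, rnorm(200, 1, 0.3))
    thr <- elbow_threshold(c(strong, weak))
    separated <- all(strong > thr) && mean(weak > thr) <= 0.05
    if (separated) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("hit confirmation enforces repeat, density and ratio rules", {
  mk <- function(strain, n, pre, post, ratio)
    data.frame(strain = strain, pre = pre, post = post, ratio = ratio)[rep(1, n), ]
  tab <- rbind(
    mk("fourreps", 4, 0.5, 0.25, 0.5),
    mk("borderline", 6, 0.5, 0.25, 0.09),
    mk("nogrowth", 6, 0.05, 0.01, 0.2)
  )
  out <- confirm_hits(tab, min_repeats = 5, ratio_min = 0.086)
  expect_false(out$hit[out$strain == "fourreps"])   # only 4 valid repeats
  expect_true(out$hit[out$strain == "borderline"])  # 0.09 > 0.086
  expect_false(out$hit[out$strain == "nogrowth"])   # no valid replicates
  expect_equal(out$n_valid[out$strain == "nogrowth"], 0)

  # per-replicate rule is stricter than the mean rule
  mixed <- data.frame(strain = "m", pre = 0.5, post = 0.25,
                      ratio = c(0.05, rep(0.2, 5)))
  expect_true(confirm_hits(mixed, ratio_min = 0.086)$hit)
  expect_false(confirm_hits(mixed, ratio_min = 0.086, rule = "each")$hit)
})

test_that("relaxing any hit threshold never removes a hit", {
  scr <- simulate_screen(n_strains = 150, seed = 5)
  base <- confirm_hits(scr$replicates, min_repeats = 5, pre_min = 0.1,
                       post_min = 0.05, ratio_min = 0.086)
  for (relaxed in list(
    confirm_hits(scr$replicates, 4, 0.1, 0.05, 0.086),
    confirm_hits(scr$replicates, 5, 0.05, 0.05, 0.086),
    confirm_hits(scr$replicates, 5, 0.1, 0.01, 0.086),
    confirm_hits(scr$replicates, 5, 0.1, 0.05, 0.05))) {
    expect_true(all(relaxed$hit[base$hit]))
  }
})

test_that("exhaustive permutation p-values match full enumeration", {
  res <- permutation_t_test(c(1, 2), c(10, 11), alternative = "less")
  expect_true(res$exhaustive)
  expect_equal(res$p, 2 / 7)
  expect_equal(res$statistic, -9)

  # identical multisets tie with everything: two-sided p = 1
  same <- permutation_t_test(c(1, 2, 3), c(3, 1, 2))
  expect_equal(same$p, 1)

  expect_error(permutation_t_test(1, c(1, 2)), "at least 2")
})

test_that("sampled permutation p-values agree with exhaustive enumeration", {
  x <- withr::with_seed(1, rnorm(6))
  y <- withr::with_seed(2, rnorm(6, 1))
  exact <- permutation_t_test(x, y, n_perm = 1000, alternative = "greater")
  expect_true(exact$exhaustive)
  approx <- permutation_t_test(x, y, n_perm = 600, alternative = "greater",
                               seed = 9)
  expect_false(approx$exhaustive)
  se <- sqrt(exact$p * (1 - exact$p) / approx$n_permutations)
  expect_lt(abs(approx$p - exact$p), 3 * se + 1e-9)
})

test_that("multiple-testing corrections follow their formulas and orderings", {
  expect_equal(bonferroni(c(0.01, rep(0.5, 4)))[1], 0.05)
  expect_equal(bonferroni(c(0.5, rep(0.9, 4)))[1], 1)   # capped
  expect_equal(bonferroni(0.3), 0.3)                    # m = 1 identity
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  p <- withr::with_seed(3, runif(50, 0.001, 1))
  expect_true(all(bonferroni(p) >= p))
  expect_true(all(bh_fdr(p) >= p))
  expect_true(all(bh_fdr(p) <= bonferroni(p)))
})

test_that("median-of-ratios size factors match the textbook construction", {
  counts <- withr::with_seed(4, matrix(rnbinom(200, mu = 50, size = 2),
                                       50, 4))
  counts[1, ] <- c(0, 5, 5, 5)  # a gene absent from one sample is skipped
  sf <- median_ratio_size_factors(counts)
  # independent brute-force recomputation
  geo <- apply(counts, 1, function(g) exp(mean(log(g))))
  use <- apply(counts, 1, function(g) all(g > 0))
  oracle <- vapply(seq_len(4), function(j) {
    median(counts[use, j] / geo[use])
  }, numeric(1))
  expect_equal(sf, oracle)

  # doubling a sample doubles its factor relative to the original
  doubled <- cbind(counts[, 1], counts[, 1] * 2)
  sf2 <- median_ratio_size_factors(doubled)
  expect_equal(sf2[2] / sf2[1], 2)
  # identical samples get identical factors
  expect_equal(diff(median_ratio_size_factors(cbind(counts[, 1], counts[, 1]))), 0)
  expect_error(median_ratio_size_factors(rbind(c(0, 1), c(1, 0))),
               "nonzero")
})

test_that("size factors agree with the established reference implementation", {
  skip_if_not_installed("DESeq2")
  counts <- withr::with_seed(6, matrix(rnbinom(300, mu = 80, size = 3), 75, 4))
  expect_equal(median_ratio_size_factors(counts),
               unname(DESeq2::estimateSizeFactorsForMatrix(counts)),
               tolerance = 1e-8)
})

test_that("expression-phenotype correlation recovers planted genes at 5% FDR", {
  set.seed(11)
  n <- 50
  pheno <- rnorm(n)
  names(pheno) <- paste0("s", 1:n)
  n_signal <- 20; n_null <- 1000
  expr <- rbind(
    t(vapply(1:n_signal, function(i) pheno * 2 + rnorm(n, sd = 0.8),
             numeric(n))),
    matrix(rnorm(n_null * n), n_null, n)
  )
  rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  colnames(expr) <- names(pheno)
  res <- correlate_phenotype(expr, pheno)
  sig <- res$significant
  expect_gte(sum(sig[1:n_signal]), 18)
  expect_lte(mean(sig[-(1:n_signal)]), 0.05)

  # a gene identical to the phenotype correlates perfectly
  res1 <- correlate_phenotype(rbind(g1 = pheno, g2 = rnorm(n)), pheno,
                              method = "pearson")
  expect_equal(res1$r[1], 1)

  # constant genes are excluded from the FDR, not propagated
  resc <- correlate_phenotype(rbind(g1 = rep(1, n), g2 = pheno), pheno)
  expect_true(is.na(resc$r[1]))
  expect_false(is.na(resc$q[2]))
})

test_that("permuting the phenotype keeps the discovery rate at the FDR level", {
  set.seed(12)
  n <- 40
  pheno <- setNames(rnorm(n), paste0("s", 1:n))
  hits <- vapply(1:5, function(i) {
    expr <- matrix(rnorm(300 * n), 300, n,
                   dimnames = list(NULL, names(pheno)))
    mean(correlate_phenotype(expr, sample(pheno))$significant, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(hits), 0.05)
})
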