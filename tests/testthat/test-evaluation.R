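# Fold assignment, bootstrap, FDR, permutation definition, similarity, ICV.

test_that("folds partition subjects into near-equal disjoint sets", {
  fa <- assign_folds(letters[1:10], 5, seed = 3)
  expect_equal(sort(unique(fa$fold)), 1:5)
  expect_true(all(table(fa$fold) == 2))
  expect_identical(sort(names(fa$fold)), letters[1:10])
  fa2 <- assign_folds(letters[1:10], 5, seed = 3)
  expect_identical(fa$fold, fa2$fold)
  expect_error(assign_folds(letters[1:3], 5), "fewer subjects")
  # sizes differ by at most one when k does not divide n
  fa3 <- assign_folds(as.character(1:13), 5, seed = 1)
  expect_lte(diff(range(table(fa3$fold))), 1)
})

test_that("stratified folds keep minority representation near the global rate", {
  labels <- rep(c(0, 1), c(90, 10))
  for (s in 1:50) {
    fa <- assign_folds(sprintf("s%03d", 1:100), 5, seed = s, labels = labels)
    per_fold <- vapply(1:5, function(f) sum(labels[fa$fold == f] == 1),
                       numeric(1))
    expect_true(all(per_fold >= 1 & per_fold <= 3))
  }
})

test_that("bootstrap CIs are degenerate for perfect pairs and deterministic", {
  pairs <- cbind(rep(c(0, 1), 5), rep(c(0, 1), 5))
  ci <- bootstrap_ci(pairs, "accuracy", n_boot = 200, seed = 1)
  expect_equal(c(ci$lower, ci$upper), c(1, 1))
  obs <- withr::with_seed(2, cbind(rnorm(20), rnorm(20)))
  ci1 <- bootstrap_ci(obs, "pearson_r", n_boot = 500, seed = 9)
  ci2 <- bootstrap_ci(obs, "pearson_r", n_boot = 500, seed = 9)
  expect_identical(ci1$statistics, ci2$statistics)
  expect_lte(ci1$lower, ci1$upper)
})

test_that("exhaustive bootstrap matches full enumeration at n = 3", {
  pairs <- cbind(c(0, 1, 1), c(0, 1, 0))
  ci <- bootstrap_ci(pairs, "accuracy", exhaustive = TRUE)
  # oracle: all 27 equally likely index triples, by explicit loops
  stats <- c()
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    idx <- c(i, j, k)
    stats <- c(stats, mean(pairs[idx, 1] == pairs[idx, 2]))
  }
  q <- unname(quantile(stats, c(0.025, 0.975)))
  expect_equal(c(ci$lower, ci$upper), q, tolerance = 1e-12)
  expect_length(ci$statistics, 27)
})

test_that("undefined correlation resamples are redrawn and counted", {
  pairs <- cbind(c(1, 2, 2, 2), c(0.5, 1, 1.2, 0.9))
  ci <- bootstrap_ci(pairs, "pearson_r", n_boot = 300, seed = 4)
  expect_gt(ci$n_redrawn, 0)           # all-duplicate draws are constant
  expect_true(all(is.finite(ci$statistics)))
  expect_error(bootstrap_ci(pairs[1, , drop = FALSE], "accuracy"), "two pairs")
})

test_that("bootstrap percentile intervals cover the generating correlation", {
  rho <- 0.5; n <- 200
  covered <- vapply(1:200, function(s) {
    pairs <- withr::with_seed(s, {
      x <- rnorm(n)
      cbind(x, rho * x + sqrt(1 - rho^2) * rnorm(n))
    })
    ci <- bootstrap_ci(pairs, "pearson_r", n_boot = 400, seed = s)
    ci$lower <= rho && rho <= ci$upper
  }, logical(1))
  expect_gte(mean(covered), 0.90)  # nominal 95%, within 5 points
})

test_that("BH flags match the explicit step-up procedure", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_equal(fdr_adjust(c(0.9, 0.95), 0.05), rep(FALSE, 2))
  bh_oracle <- function(p, q) {
    m <- length(p); o <- order(p)
    below <- which(p[o] <= q * seq_len(m) / m)
    out <- rep(FALSE, m)
    if (length(below)) out[o[seq_len(max(below))]] <- TRUE
    out
  }
  for (s in 1:25) {
    p <- withr::with_seed(s, runif(12)^2)
    flags <- fdr_adjust(p, 0.1)
    expect_identical(flags, bh_oracle(p, 0.1))
    # monotone: rejecting a p rejects all smaller p
    if (any(flags)) expect_true(all(flags[p <= max(p[flags])]))
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1]")
})

test_that("the permutation p-value excludes undefined trials from its denominator", {
  nulls <- c(0.9, 0.8, NA, 0.1, NA, 0.2, NA, 0.15, NA, 0.05)
  expect_equal(permutation_pvalue(nulls, observed = 0.5), 2 / 6)
  expect_equal(permutation_pvalue(nulls, 0.5, conservative = TRUE), 2 / 10)
  expect_equal(permutation_pvalue(c(0.1, 0.2), 0.5), 0)
  expect_equal(permutation_pvalue(rep(NA_real_, 3), 0.5), NA_real_)
  # sign is ignored: the statistic is compared in magnitude
  expect_equal(permutation_pvalue(c(-0.9, 0.1), 0.5), 1 / 2)
})

test_that("a strong planted effect defeats every permutation trial", {
  co <- small_cohort(n = 60, p = 300, seed = 17, specs = list(
    attribute_spec("strong", "continuous", 1, 1, noise_sd = 0.1)))
  al <- align_and_drop_missing(co$fingerprints, co$attributes, "strong")
  pt <- permutation_test(al$X, al$icv, al$y, fast_config(seed = 5),
                         n_perm = 50, family = "linear")
  expect_gt(pt$observed, 0.8)
  expect_equal(pt$p_value, 0)
  pt2 <- permutation_test(al$X, al$icv, al$y, fast_config(seed = 5),
                          n_perm = 50, family = "linear")
  expect_identical(pt$null_stats, pt2$null_stats)  # seeded determinism
  expect_error(permutation_test(al$X, al$icv, al$y, fast_config(seed = 5),
                                n_perm = 0), "n_perm")
})

test_that("pairwise similarity is Pearson correlation over the upper triangle", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4) * 2, c = c(1, -1, 1, -1))
  ps <- pairwise_similarity(x)
  expect_equal(ps$matrix["a", "b"], 1)
  expect_equal(diag(ps$matrix), rep(1, 3), ignore_attr = TRUE)
  expect_true(isSymmetric(ps$matrix))
  # orthogonal mean-zero rows correlate at zero
  y <- rbind(c(1, 1, -1, -1), c(1, -1, 1, -1))
  expect_equal(pairwise_similarity(y)$mean, 0)
  expect_error(pairwise_similarity(rbind(c(1, 1, 1), c(1, 2, 3))), "constant")
  expect_equal(ps$mean, mean(ps$matrix[upper.tri(ps$matrix)]))
})

test_that("ICV-response association flags real and absent relationships", {
  icv <- withr::with_seed(40, rlnorm(500, log(1.5e6), 0.05))
  out <- icv_response_association(icv, icv, "linear")
  expect_true(out$flag)
  expect_equal(out$estimate, 1)
  flags <- vapply(1:50, function(s)
    icv_response_association(icv, withr::with_seed(s, rnorm(500)),
                             "linear")$flag, logical(1))
  expect_gte(mean(!flags), 0.90)
  # binary: Welch test on ICV split by class
  y <- as.integer(log(icv) > median(log(icv)))
  outb <- icv_response_association(icv, y, "logistic")
  expect_true(outb$flag)
  expect_error(icv_response_association(rep(1e6, 10), rnorm(10)), "constant")
})
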