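# Penalized component regression: selection, fitting, truncation.

test_that("orthogonal-design LASSO equals soft-thresholding of OLS coefficients", {
  n <- 40; r <- 8
  Z <- orthonormal_scores(n, r, seed = 3)
  y <- withr::with_seed(4, as.numeric(Z %*% c(3, -2, 1.5, rep(0, 5)) + rnorm(n, sd = 0.3)))
  for (lambda in c(0.005, 0.02, 0.06)) {
    m <- fit_sparse_model(Z, icv = NULL, y, "linear", lambda,
                          standardize = FALSE)
    # columns are orthonormal and orthogonal to the intercept, so each
    # coefficient is an independently soft-thresholded projection
    cj <- as.numeric(crossprod(Z, y))
    oracle <- sign(cj) * pmax(abs(cj) - n * lambda, 0)
    expect_equal(m$beta, oracle, tolerance = 1e-6)
    expect_equal(m$intercept, mean(y), tolerance = 1e-6)
    expect_equal(m$n_nonzero, sum(oracle != 0))
  }
})

test_that("a vanishing penalty recovers an exact linear dependence", {
  Z <- withr::with_seed(6, matrix(rnorm(30 * 5), 30, 5))
  y <- 2 * Z[, 1]
  m <- fit_sparse_model(Z, icv = NULL, y, "linear", lambda = 1e-8,
                        standardize = FALSE, thresh = 1e-12)
  expect_equal(m$beta[1], 2, tolerance = 1e-4)
  expect_true(all(abs(m$beta[-1]) < 1e-4))
})

test_that("above lambda_max the fit is the null model", {
  Z <- withr::with_seed(7, matrix(rnorm(50 * 6), 50, 6))
  icv <- withr::with_seed(8, rlnorm(50, log(1.5e6), 0.05))
  y <- withr::with_seed(9, rnorm(50) + 3)
  m <- fit_sparse_model(Z, icv, y, "linear", lambda = 1e9)
  expect_equal(m$n_nonzero, 0)
  expect_equal(m$beta_icv, 0)
  expect_equal(m$intercept, mean(y), tolerance = 1e-8)
  yb <- withr::with_seed(10, rbinom(50, 1, 0.3))
  mb <- fit_sparse_model(Z, icv, yb, "logistic", lambda = 1e9)
  expect_equal(mb$n_nonzero, 0)
  expect_equal(mb$intercept, qlogis(mean(yb)), tolerance = 1e-6)
})

test_that("the fitted objective beats random coefficient perturbations", {
  n <- 30; r <- 5; lambda <- 0.05
  Z <- withr::with_seed(12, matrix(rnorm(n * r), n, r))
  y <- withr::with_seed(13, as.numeric(Z %*% c(1, -1, 0, 0, 0) + rnorm(n)))
  m <- fit_sparse_model(Z, icv = NULL, y, "linear", lambda,
                        standardize = FALSE, thresh = 1e-12)
  obj <- function(b0, b)
    sum((y - b0 - Z %*% b)^2) / (2 * n) + lambda * sum(abs(b))
  fitted_obj <- obj(m$intercept, m$beta)
  worse <- withr::with_seed(14, vapply(1:1000, function(i) {
    obj(m$intercept + rnorm(1, sd = 0.05), m$beta + rnorm(r, sd = 0.05))
  }, numeric(1)))
  expect_true(all(fitted_obj <= worse + 1e-12))
})

test_that("penalty selection is deterministic and matches cv.glmnet exactly", {
  n <- 80; r <- 25
  Z <- withr::with_seed(20, matrix(rnorm(n * r), n, r))
  foldid <- withr::with_seed(21, sample(rep(1:10, length.out = n)))
  for (fam in c("linear", "logistic")) {
    y <- withr::with_seed(22, if (fam == "linear")
      as.numeric(Z[, 1] + rnorm(n)) else rbinom(n, 1, plogis(Z[, 1])))
    for (rule in c("min", "1se")) {
      lam <- select_penalty(Z, y, fam, rule, foldid = foldid)
      ref <- glmnet::cv.glmnet(
        Z, y, family = if (fam == "linear") "gaussian" else "binomial",
        foldid = foldid, nlambda = 100, lambda.min.ratio = 1e-4)
      expect_equal(as.numeric(lam),
                   if (rule == "min") ref$lambda.min else ref$lambda.1se,
                   tolerance = 1e-12)
    }
    # same seed, same lambda
    l1 <- select_penalty(Z, y, fam, "1se", seed = 99)
    l2 <- select_penalty(Z, y, fam, "1se", seed = 99)
    expect_identical(as.numeric(l1), as.numeric(l2))
  }
})

test_that("the one-SE rule yields intercept-only models on null responses", {
  n <- 60; r <- 30
  Z <- withr::with_seed(30, matrix(rnorm(n * r), n, r))
  null_fits <- vapply(1:50, function(s) {
    y <- withr::with_seed(1000 + s, rnorm(n))
    lam <- select_penalty(Z, y, "linear", "1se", seed = s)
    m <- fit_sparse_model(Z, NULL, y, "linear", as.numeric(lam))
    m$n_nonzero == 0
  }, logical(1))
  expect_gte(mean(null_fits), 0.90)
})

test_that("a strong component is selected with the correct sign", {
  n <- 80; r <- 10
  Z <- withr::with_seed(31, matrix(rnorm(n * r), n, r))
  y <- withr::with_seed(32, as.numeric(3 * Z[, 1] + rnorm(n, sd = 0.5)))
  lam <- select_penalty(Z, y, "linear", "1se", seed = 5)
  m <- fit_sparse_model(Z, NULL, y, "linear", as.numeric(lam))
  expect_gt(m$beta[1], 0)
  expect_gt(m$n_nonzero, 0)
})

test_that("sparsity is non-increasing along the penalty path", {
  n <- 60; r <- 15
  Z <- withr::with_seed(33, matrix(rnorm(n * r), n, r))
  y <- withr::with_seed(34, as.numeric(Z %*% rnorm(r, sd = 0.5) + rnorm(n)))
  lambdas <- 10^seq(-2, 0.5, length.out = 8)
  nnz <- vapply(lambdas, function(l)
    fit_sparse_model(Z, NULL, y, "linear", l, standardize = FALSE)$n_nonzero,
    numeric(1))
  expect_true(all(diff(nnz) <= 0))  # lambdas ascending, sparsity tightening
})

test_that("ICV truncation keeps component coefficients and refuses logistic", {
  m <- lcpr:::new_sparse_model("linear", c(0.3, 0, -1.2, 0.5), 0.1,
                               lambda = 0.2, rule = "1se", r = 3,
                               has_icv = TRUE)
  expect_equal(truncate_confound(m), c(0.3, 0, -1.2))
  m0 <- lcpr:::new_sparse_model("linear", c(0.3, 0, -1.2, 0), 0.1,
                                lambda = 0.2, rule = "1se", r = 3,
                                has_icv = TRUE)
  expect_equal(truncate_confound(m0), m0$beta)
  mlog <- lcpr:::new_sparse_model("logistic", c(1, 0.2), 0, lambda = 0.1,
                                  rule = "1se", r = 1, has_icv = TRUE)
  expect_error(truncate_confound(mlog), "unsupported")
})

test_that("models survive a JSON round-trip", {
  m <- lcpr:::new_sparse_model("linear", c(0, 1.25, 0, -0.5, 0.01), -0.7,
                               lambda = 0.123, rule = "min", r = 4,
                               has_icv = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_sparse_model(m, path)
  back <- read_sparse_model(path)
  expect_equal(back$beta, m$beta)
  expect_equal(back$beta_icv, m$beta_icv)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$lambda, m$lambda)
  expect_identical(back$family, m$family)
})

test_that("degenerate responses are rejected", {
  Z <- matrix(rnorm(40), 20, 2)
  expect_error(select_penalty(Z, rep(1, 20), "linear", seed = 1,
                              n_inner_folds = 5), "constant")
  expect_error(select_penalty(Z, rep(1, 20), "logistic", seed = 1,
                              n_inner_folds = 5), "single class|0/1")
  expect_error(fit_sparse_model(Z, NULL, c(rep(0, 19), NA), "linear", 0.1),
               "non-finite")
})
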