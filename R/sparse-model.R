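# L1-penalized regression of a response on component scores plus intracranial
# volume (ICV), with inner-CV penalty selection and confound truncation.
# Fitting is done with glmnet; coefficients are reported on the original
# score/ICV scale (glmnet standardizes internally and back-transforms).

glmnet_family <- function(family) {
  switch(family, linear = "gaussian", logistic = "binomial",
         stop2("family must be 'linear' or 'logistic'"))
}

check_response <- function(y, family) {
  if (any(!is.finite(y))) stop2("non-finite response values")
  if (family == "linear" && sd(y) == 0) stop2("response is constant")
  if (family == "logistic") {
    if (!all(y %in% c(0, 1))) stop2("logistic response must be coded 0/1")
    if (length(unique(y)) < 2) stop2("logistic response has a single class")
  }
  invisible(y)
}

# glmnet refuses single-column x; pad with an excluded zero column.
pad_single_column <- function(x, penalty_factor) {
  if (ncol(x) >= 2) return(list(x = x, pf = penalty_factor))
  list(x = cbind(x, pad = 0), pf = c(penalty_factor, Inf))
}

new_sparse_model <- function(family, coefs, intercept, lambda, rule, r,
                             has_icv) {
  beta <- coefs[seq_len(r)]
  beta_icv <- if (has_icv) coefs[r + 1] else 0
  structure(list(family = family, beta = unname(beta),
                 beta_icv = unname(beta_icv),
                 intercept = unname(intercept), lambda = lambda,
                 selection_rule = rule, n_nonzero = sum(beta != 0),
                 has_icv = has_icv),
            class = "lcp_sparse_model")
}

#' @export
print.lcp_sparse_model <- function(x, ...) {
  cat("<lcp_sparse_model> family=", x$family, ", lambda=",
      signif(x$lambda, 4), " (rule: ", x$selection_rule %||% "fixed",
      "), nonzero components=", x$n_nonzero,
      ", beta_icv=", signif(x$beta_icv, 4), "\n", sep = "")
  invisible(x)
}

# Extract an lcp_sparse_model from a fitted glmnet path at a path lambda.
model_from_path <- function(fit, lambda, family, rule, r, has_icv) {
  cf <- as_dense(coef(fit, s = lambda))
  new_sparse_model(family, cf[-1], cf[1], lambda, rule, r, has_icv)
}

#' Select the LASSO penalty by inner cross-validation
#'
#' Chooses lambda on a log-spaced path (`nlambda` values spanning
#' `-log10(lambda_min_ratio)` decades down from the smallest lambda that
#' zeroes all slopes) by `n_inner_folds`-fold cross-validated deviance on the
#' supplied rows only. `rule = "1se"` takes the largest lambda within one
#' standard error of the minimum (conservative; frequently yields
#' intercept-only models on weak signals), `"min"` the deviance minimizer.
#'
#' @param Z_aug Predictor matrix, typically `cbind(Z, icv)` with `Z = U S`.
#' @param y Response (numeric, or 0/1 for logistic).
#' @param family `"linear"` or `"logistic"`.
#' @param rule `"1se"` or `"min"`.
#' @param n_inner_folds Inner fold count (default 10).
#' @param seed Seed for the inner fold assignment.
#' @param penalty_factor Optional per-column penalty multipliers (`Inf`
#'   excludes a column entirely, e.g. for an ICV-only model).
#' @param nlambda,lambda_min_ratio Path length and depth.
#' @param standardize Standardize predictors internally (default `TRUE`;
#'   coefficients are always reported on the original scale).
#' @param foldid Optional explicit inner fold assignment (overrides `seed`);
#'   mainly for reproducibility checks.
#' @return Selected lambda (numeric scalar), with attributes: `"fit"` (the
#'   full-data glmnet path, whose grid the selection searched), `"cvm"` and
#'   `"cvsd"` (mean cross-validated deviance and its standard error per
#'   path point), `"lambda_path"`, and `"foldid"`.
#' @details The implementation mirrors `cv.glmnet` exactly for a shared fold
#'   assignment: each inner fold fits its own path and predictions are
#'   interpolated onto the full-data lambda grid; per-fold mean deviance is
#'   combined across folds by fold-size-weighted mean with its standard
#'   error, and fitted probabilities are clamped to `[1e-5, 1 - 1e-5]` for
#'   the binomial deviance.
#' @export
select_penalty <- function(Z_aug, y, family = "linear",
                           rule = c("1se", "min"), n_inner_folds = 10,
                           seed = 1, penalty_factor = NULL, nlambda = 100,
                           lambda_min_ratio = 1e-4, standardize = TRUE,
                           foldid = NULL) {
  rule <- match.arg(rule)
  family <- match.arg(family, c("linear", "logistic"))
  check_response(y, family)
  n <- nrow(Z_aug)
  if (n < 2 * n_inner_folds)
    stop2("need at least ", 2 * n_inner_folds, " rows for ", n_inner_folds,
          "-fold penalty selection")
  pf <- penalty_factor %||% rep(1, ncol(Z_aug))
  padded <- pad_single_column(as.matrix(Z_aug), pf)
  fam <- glmnet_family(family)
  fit <- glmnet::glmnet(padded$x, y, family = fam, penalty.factor = padded$pf,
                        nlambda = nlambda,
                        lambda.min.ratio = lambda_min_ratio,
                        standardize = standardize)
  grid <- fit$lambda
  foldid <- foldid %||%
    with_seed(seed, sample(rep(seq_len(n_inner_folds), length.out = n)))
  k <- max(foldid)
  fold_dev <- matrix(NA_real_, k, length(grid))
  for (f in seq_len(k)) {
    in_f <- foldid == f
    # each fold fits its own path; predictions are interpolated onto the
    # full-data grid (the cv.glmnet convention, reproduced exactly)
    fk <- glmnet::glmnet(padded$x[!in_f, , drop = FALSE], y[!in_f],
                         family = fam, penalty.factor = padded$pf,
                         nlambda = nlambda,
                         lambda.min.ratio = lambda_min_ratio,
                         standardize = standardize)
    pred <- predict(fk, padded$x[in_f, , drop = FALSE], s = grid,
                    type = if (fam == "binomial") "response" else "link")
    fold_dev[f, ] <- if (fam == "binomial") {
      pr <- pmin(pmax(pred, 1e-5), 1 - 1e-5)
      colMeans(-2 * (y[in_f] * log(pr) + (1 - y[in_f]) * log(1 - pr)))
    } else colMeans((y[in_f] - pred)^2)
  }
  w <- tabulate(foldid, k)
  cvm <- apply(fold_dev, 2, stats::weighted.mean, w = w)
  cvsd <- sqrt(apply((fold_dev - rep(cvm, each = k))^2, 2,
                     stats::weighted.mean, w = w) / (k - 1))
  i_min <- which.min(cvm)
  lambda <- if (rule == "min") grid[i_min]
            else max(grid[cvm <= cvm[i_min] + cvsd[i_min]])
  structure(lambda, fit = fit, cvm = cvm, cvsd = cvsd, lambda_path = grid,
            foldid = foldid)
}

#' Fit the sparse component regression at a fixed penalty
#'
#' Minimizes the L1-penalized squared-error (linear) or logistic deviance
#' over slopes on all component scores and ICV, with an unpenalized
#' intercept. ICV enters the model like any other predictor; its coefficient
#' is stored separately so [truncate_confound()] can drop it.
#'
#' @param Z Component-score matrix (n x r), typically `U S` from
#'   [economical_svd()].
#' @param icv Per-subject intracranial volume, or `NULL` to omit the
#'   confound column.
#' @param y Response.
#' @param family `"linear"` or `"logistic"`.
#' @param lambda Penalty value (>= 0), on the glmnet scale (objective
#'   `deviance/(2n) + lambda * ||beta||_1`).
#' @param penalty_factor,standardize,thresh Passed to glmnet.
#' @return An `lcp_sparse_model` with fields `family`, `beta` (length r, on
#'   the original score scale), `beta_icv`, `intercept`, `lambda`,
#'   `selection_rule`, `n_nonzero`.
#' @export
fit_sparse_model <- function(Z, icv, y, family = "linear", lambda,
                             penalty_factor = NULL, standardize = TRUE,
                             thresh = 1e-7) {
  family <- match.arg(family, c("linear", "logistic"))
  check_response(y, family)
  if (!is.null(icv) && length(icv) != nrow(Z))
    stop2("icv length does not match number of rows")
  x <- if (is.null(icv)) as.matrix(Z) else cbind(as.matrix(Z), icv = icv)
  check_finite_matrix(unname(x), "predictor matrix")
  if (lambda < 0) stop2("lambda must be >= 0")
  r <- ncol(Z)
  pf <- penalty_factor %||% rep(1, ncol(x))
  padded <- pad_single_column(x, pf)
  fit <- glmnet::glmnet(padded$x, y, family = glmnet_family(family),
                        penalty.factor = padded$pf, standardize = standardize,
                        thresh = thresh)
  cf <- as_dense(coef(fit, s = lambda, exact = TRUE, x = padded$x, y = y,
                      family = glmnet_family(family),
                      penalty.factor = padded$pf, standardize = standardize,
                      thresh = thresh))
  cf <- cf[seq_len(1 + ncol(x))]   # drop any padding column
  new_sparse_model(family, cf[-1], cf[1], as.numeric(lambda),
                   rule = NULL, r = r, has_icv = !is.null(icv))
}

#' Truncate the ICV confound from a fitted linear model
#'
#' Returns the component coefficients with the ICV coefficient (and the
#' intercept) excluded, so downstream predictions derive only from
#' fingerprint components. Only valid for linear models: dropping a
#' coefficient inside a logistic model distorts the nonlinear link, so
#' binary responses are instead assessed by comparing an ICV-only model with
#' the full model (see [run_cv_binary()]).
#'
#' @param m An `lcp_sparse_model`.
#' @return Numeric vector `beta_star` of length r.
#' @export
truncate_confound <- function(m) {
  stopifnot(inherits(m, "lcp_sparse_model"))
  if (m$family != "linear")
    stop2("ICV truncation is unsupported for logistic models; compare an ",
          "ICV-only model with the full model instead")
  m$beta
}

#' Serialize / restore a sparse model as JSON
#'
#' Stores family, lambda, selection rule, intercept, ICV coefficient and the
#' nonzero component coefficients as (index, value) pairs.
#'
#' @param m An `lcp_sparse_model`.
#' @param path JSON file path.
#' @export
write_sparse_model <- function(m, path) {
  nz <- which(m$beta != 0)
  jsonlite::write_json(
    list(family = m$family, lambda = m$lambda,
         selection_rule = m$selection_rule, intercept = m$intercept,
         beta_icv = m$beta_icv, has_icv = m$has_icv,
         n_components = length(m$beta),
         coefficients = data.frame(index = nz, value = m$beta[nz])),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sparse_model
#' @export
read_sparse_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- rep(0, j$n_components)
  if (length(j$coefficients)) beta[j$coefficients$index] <- j$coefficients$value
  new_sparse_model(j$family, c(beta, if (j$has_icv) j$beta_icv),
                   j$intercept, j$lambda, j$selection_rule,
                   r = j$n_components, has_icv = isTRUE(j$has_icv))
}
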