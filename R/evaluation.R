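# Cross-validated evaluation of the LASSO-PCR pipeline, plus permutation,
# bootstrap, FDR and cohort-similarity analyses.

#' Cross-validation configuration
#'
#' One object carries every tunable of the evaluation pipeline. The single
#' `seed` fans out deterministically (via [derive_seed()]) to the outer fold
#' assignment, each fold's inner penalty-selection folds, permutation trials
#' and bootstrap resampling.
#'
#' @param k Outer fold count (default 5: a unique 20% of subjects held out
#'   per fold).
#' @param seed Top-level seed.
#' @param rule Penalty selection rule, `"1se"` (conservative default) or
#'   `"min"`.
#' @param n_inner_folds Inner CV folds for penalty selection (default 10).
#' @param nlambda,lambda_min_ratio Penalty path: `nlambda` log-spaced values
#'   spanning `-log10(lambda_min_ratio)` decades below the null-model lambda.
#' @param standardize Standardize predictors inside the penalized fit.
#' @param center Column-center fingerprints before the SVD (default `FALSE`:
#'   the raw matrix is decomposed, so the mean fingerprint lies in the span
#'   of the leading axes).
#' @param pooled_decomposition If `TRUE`, decompose the full cohort once and
#'   reuse scores across folds (cheaper, but leaks the held-out rows into
#'   the axes; exploration only). Default `FALSE`: a fresh SVD per training
#'   split.
#' @param keep_fold_models Keep per-fold models/maps in the result.
#' @return A `cv_config` list.
#' @export
cv_config <- function(k = 5, seed = 1, rule = c("1se", "min"),
                      n_inner_folds = 10, nlambda = 100,
                      lambda_min_ratio = 1e-4, standardize = TRUE,
                      center = FALSE, pooled_decomposition = FALSE,
                      keep_fold_models = TRUE) {
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 rule = match.arg(rule),
                 n_inner_folds = as.integer(n_inner_folds),
                 nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio,
                 standardize = standardize, center = center,
                 pooled_decomposition = pooled_decomposition,
                 keep_fold_models = keep_fold_models),
            class = "cv_config")
}

#' Assign subjects to cross-validation folds
#'
#' Random partition into `k` folds with sizes differing by at most one. If
#' class `labels` are supplied, the draw is repeated (up to 100 attempts)
#' until every fold's minority-class fraction is within tolerance of the
#' global fraction: `max(0.25 * global_fraction, 1/fold_size)` absolute,
#' i.e. 25% relative slack widened to one subject for small folds.
#'
#' @param subject_ids Subject labels (n >= k).
#' @param k Fold count.
#' @param seed RNG seed; the assignment is deterministic given the seed.
#' @param labels Optional binary class labels for balance verification.
#' @return A `fold_assignment`: list with `fold` (named integer vector in
#'   1..k), `k`, `seed`.
#' @export
assign_folds <- function(subject_ids, k, seed = 1, labels = NULL) {
  n <- length(subject_ids)
  if (n < k) stop2("fewer subjects (", n, ") than folds (", k, ")")
  if (!is.null(labels) && length(labels) != n)
    stop2("labels length does not match subject_ids")
  draw <- function(s) with_seed(s, sample(rep(seq_len(k), length.out = n)))
  fold <- NULL
  if (is.null(labels)) {
    fold <- draw(seed)
  } else {
    tab <- table(labels)
    minority <- names(tab)[which.min(tab)]
    gf <- mean(labels == minority)
    for (attempt in seq_len(100)) {
      cand <- draw(derive_seed(seed, "fold-attempt", attempt))
      ok <- vapply(seq_len(k), function(f) {
        in_f <- cand == f
        tol <- max(0.25 * gf, 1 / sum(in_f))
        abs(mean(labels[in_f] == minority) - gf) <= tol
      }, logical(1))
      if (all(ok)) { fold <- cand; break }
    }
    if (is.null(fold))
      stop2("could not achieve near-even class distributions in ", k,
            " folds after 100 attempts")
  }
  names(fold) <- subject_ids
  structure(list(fold = fold, k = as.integer(k), seed = as.integer(seed)),
            class = "fold_assignment")
}

# ---- shared CV core --------------------------------------------------------

# Per-fold training decompositions and held-out slices, computed once so that
# permutation trials (which only relabel y) can reuse them. All training-side
# statistics (SVD axes, penalty path, standardization) derive from the
# training rows only.
prepare_cv <- function(X, icv, folds, config) {
  x <- if (inherits(X, "fingerprint_matrix")) fp_values(X) else as.matrix(X)
  pooled <- if (config$pooled_decomposition)
    economical_svd(x, center = config$center) else NULL
  lapply(seq_len(folds$k), function(f) {
    test <- which(folds$fold == f)
    train <- which(folds$fold != f)
    d <- pooled %||% economical_svd(x[train, , drop = FALSE],
                                    center = config$center)
    Z <- if (config$pooled_decomposition)
      component_scores(d, x[train, , drop = FALSE]) else training_scores(d)
    list(fold = f, train = train, test = test, d = d, Z = Z,
         icv_train = icv[train], X_test = x[test, , drop = FALSE],
         icv_test = icv[test])
  })
}

# One continuous-response CV pass over prepared folds: per fold select the
# penalty, fit, truncate ICV, back-project, and predict the held-out rows
# through the phenotype map.
cv_continuous_pass <- function(prep, y, config, response_name = "y",
                               keep = FALSE) {
  n <- length(y)
  yhat <- rep(NA_real_, n)
  fold_models <- if (keep) vector("list", length(prep)) else NULL
  for (pf in prep) {
    y_tr <- y[pf$train]
    lambda <- select_penalty(cbind(pf$Z, icv = pf$icv_train), y_tr,
                             family = "linear", rule = config$rule,
                             n_inner_folds = config$n_inner_folds,
                             seed = derive_seed(config$seed, "inner", pf$fold),
                             nlambda = config$nlambda,
                             lambda_min_ratio = config$lambda_min_ratio,
                             standardize = config$standardize)
    m <- model_from_path(attr(lambda, "fit"), as.numeric(lambda), "linear",
                         config$rule, r = ncol(pf$Z), has_icv = TRUE)
    map <- build_phenotype_map(pf$d, truncate_confound(m), response_name,
                               fold_id = pf$fold)
    yhat[pf$test] <- predict_from_map(map, pf$X_test)
    if (keep) fold_models[[pf$fold]] <-
      list(model = m, map = map, lambda = as.numeric(lambda))
  }
  list(yhat = yhat, fold_models = fold_models)
}

# One binary-response CV pass: per fold fit an ICV-only and a full
# (ICV + components) logistic model, and predict held-out labels with each.
cv_binary_pass <- function(prep, y, config, keep = FALSE) {
  n <- length(y)
  label_full <- rep(NA_integer_, n)
  label_icv <- rep(NA_integer_, n)
  fold_models <- if (keep) vector("list", length(prep)) else NULL
  for (pf in prep) {
    y_tr <- y[pf$train]
    if (length(unique(y_tr)) < 2)
      stop2("single-class training split in fold ", pf$fold)
    x_aug <- cbind(pf$Z, icv = pf$icv_train)
    r <- ncol(pf$Z)
    fit_one <- function(pfac, tag) {
      lambda <- select_penalty(x_aug, y_tr, family = "logistic",
                               rule = config$rule,
                               n_inner_folds = config$n_inner_folds,
                               seed = derive_seed(config$seed, tag, pf$fold),
                               penalty_factor = pfac,
                               nlambda = config$nlambda,
                               lambda_min_ratio = config$lambda_min_ratio,
                               standardize = config$standardize)
      model_from_path(attr(lambda, "fit"), as.numeric(lambda),
                      "logistic", config$rule, r = r, has_icv = TRUE)
    }
    m_full <- fit_one(rep(1, r + 1), "inner")
    m_icv <- fit_one(c(rep(Inf, r), 1), "inner-icv")
    label_full[pf$test] <-
      predict_binary(m_full, pf$d, pf$X_test, pf$icv_test)$label
    label_icv[pf$test] <-
      predict_binary(m_icv, pf$d, pf$X_test, pf$icv_test)$label
    if (keep) fold_models[[pf$fold]] <- list(model = m_full,
                                             model_icv_only = m_icv)
  }
  list(label_full = label_full, label_icv = label_icv,
       fold_models = fold_models)
}

new_cv_result <- function(response_name, family, y, yhat, folds, metric,
                          extra = list()) {
  structure(c(list(response_name = response_name, family = family,
                   y = y, yhat = yhat, folds = folds, metric = metric,
                   n = length(y)), extra),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> '", x$response_name, "' (", x$family, "), n=", x$n,
      ", k=", x$folds$k, "\n", sep = "")
  if (x$family == "linear") {
    if (isTRUE(x$undefined))
      cat("  observed-vs-predicted r: undefined (constant predictions)\n")
    else
      cat("  observed-vs-predicted r:", round(x$metric, 4), "\n")
  } else {
    cat("  CV accuracy (ICV + components):", round(x$metric, 4),
        "| ICV only:", round(x$metric_icv_only, 4),
        "| training:", round(x$training_accuracy, 4), "\n")
  }
  invisible(x)
}

#' Cross-validated continuous prediction
#'
#' Runs the full pipeline under k-fold cross-validation: per fold, an
#' economical SVD of the training fingerprints, inner-CV penalty selection,
#' a sparse fit on component scores plus ICV, ICV truncation, phenotype-map
#' construction, and map-based prediction of the held-out subjects. Every
#' subject is predicted exactly once; the metric is the Pearson correlation
#' between observed and held-out predicted values. If all predictions are
#' constant (every fold intercept-only) the metric is flagged undefined
#' rather than raising an error.
#'
#' @param X [fingerprint_matrix()] (rows already unit-variance scaled).
#' @param icv Per-subject intracranial volume.
#' @param y Continuous response, aligned with `X` rows.
#' @param config A [cv_config()].
#' @param response_name Label for the result.
#' @return A `cv_result` with fields `y`, `yhat`, `folds`, `metric`
#'   (Pearson r), `undefined`, and per-fold models/maps when
#'   `config$keep_fold_models`.
#' @export
run_cv_continuous <- function(X, icv, y, config = cv_config(),
                              response_name = "y") {
  n <- nrow(X)
  stopifnot(length(icv) == n, length(y) == n)
  if (n < 2 * config$k) stop2("too few subjects for ", config$k, " folds")
  folds <- assign_folds(rownames(X) %||% seq_len(n), config$k,
                        seed = derive_seed(config$seed, "folds"))
  prep <- prepare_cv(X, icv, folds, config)
  pass <- cv_continuous_pass(prep, y, config, response_name,
                             keep = config$keep_fold_models)
  undefined <- sd(pass$yhat) == 0
  metric <- if (undefined) NA_real_ else cor(y, pass$yhat)
  new_cv_result(response_name, "linear", y, pass$yhat, folds, metric,
                list(undefined = undefined, fold_models = pass$fold_models))
}

#' Cross-validated binary classification
#'
#' Per fold fits two logistic LASSO models on the training split — ICV-only,
#' and ICV plus fingerprint component scores — and predicts the held-out
#' labels with each. Because logistic coefficients cannot be truncated
#' without distorting the link, the fingerprint's added value is read from
#' the accuracy difference between the two models. Folds are stratified:
#' the assignment is redrawn until each fold's class mix is near the global
#' mix. A training accuracy (full-sample refit) is reported as a
#' model-fit measure.
#'
#' @param X,icv,config As in [run_cv_continuous()].
#' @param y Binary response coded 0/1 (see [prepare_binary_response()]).
#' @param response_name Label for the result.
#' @return A `cv_result` with `metric` (held-out accuracy of the full
#'   model), `metric_icv_only`, `training_accuracy`, `base_rate`, and
#'   per-fold models when requested.
#' @export
run_cv_binary <- function(X, icv, y, config = cv_config(),
                          response_name = "y") {
  n <- nrow(X)
  stopifnot(length(icv) == n, length(y) == n)
  check_response(y, "logistic")
  folds <- assign_folds(rownames(X) %||% seq_len(n), config$k,
                        seed = derive_seed(config$seed, "folds"), labels = y)
  prep <- prepare_cv(X, icv, folds, config)
  pass <- cv_binary_pass(prep, y, config, keep = config$keep_fold_models)
  full_fit <- fit_lcp(X, icv, y, family = "logistic", config = config,
                      response_name = response_name)
  new_cv_result(response_name, "logistic", y, pass$label_full, folds,
                mean(pass$label_full == y),
                list(metric_icv_only = mean(pass$label_icv == y),
                     training_accuracy = full_fit$training_metric,
                     base_rate = max(mean(y == 0), mean(y == 1)),
                     fold_models = pass$fold_models,
                     full_fit = full_fit))
}

#' Fit the pipeline on the full sample
#'
#' Full-sample decomposition, penalty selection and sparse fit; used for
#' training metrics (measure of model fit) and for phenotype maps refit on
#' all subjects. For linear models the training metric is the correlation
#' between observed values and truncated-map predictions (undefined if the
#' fit is intercept-only); for logistic models it is the training accuracy
#' of the full model.
#'
#' @param X,icv,y,config,response_name As in [run_cv_continuous()].
#' @param family `"linear"` or `"logistic"`.
#' @return List with `decomposition`, `model`, `map`, `training_metric`.
#' @export
fit_lcp <- function(X, icv, y, family = "linear", config = cv_config(),
                    response_name = "y") {
  d <- economical_svd(X, center = config$center)
  Z <- training_scores(d)
  lambda <- select_penalty(cbind(Z, icv = icv), y, family = family,
                           rule = config$rule,
                           n_inner_folds = config$n_inner_folds,
                           seed = derive_seed(config$seed, "full"),
                           nlambda = config$nlambda,
                           lambda_min_ratio = config$lambda_min_ratio,
                           standardize = config$standardize)
  m <- model_from_path(attr(lambda, "fit"), as.numeric(lambda),
                       family, config$rule, r = ncol(Z), has_icv = TRUE)
  if (family == "linear") {
    map <- build_phenotype_map(d, truncate_confound(m), response_name)
    pred <- predict_from_map(map, X)
    metric <- if (sd(pred) == 0) NA_real_ else cor(y, pred)
  } else {
    # maps are still constructed for categorical responses (component
    # coefficients back-projected); accuracy is the fit measure
    map <- build_phenotype_map(d, m$beta, response_name)
    metric <- mean(predict_binary(m, d, X, icv)$label == y)
  }
  list(decomposition = d, model = m, map = map, training_metric = metric)
}

# ---- inference -------------------------------------------------------------

#' Permutation p-value from null statistics
#'
#' Implements the definition used throughout: the proportion of defined
#' null trials whose |statistic| meets or exceeds |observed|. Trials with an
#' undefined statistic (intercept-only models producing constant
#' predictions, coded `NA`) are excluded from the denominator; with
#' `conservative = TRUE` they instead count as non-exceeding.
#'
#' @param null_stats Numeric vector of null statistics, `NA` for undefined
#'   trials.
#' @param observed Observed statistic.
#' @param conservative Use all trials in the denominator.
#' @return p-value in `[0, 1]` (NA if no defined trials and not
#'   conservative).
#' @export
permutation_pvalue <- function(null_stats, observed, conservative = FALSE) {
  if (is.na(observed)) return(NA_real_)
  n_def <- sum(!is.na(null_stats))
  hits <- sum(abs(null_stats) >= abs(observed), na.rm = TRUE)
  if (conservative) return(hits / length(null_stats))
  if (n_def == 0) return(NA_real_)
  hits / n_def
}

#' Permutation test of the cross-validated pipeline
#'
#' Permutes the response (fingerprint/ICV rows stay paired), reruns the full
#' model-fitting procedure — inner penalty selection, sparse fit, truncation
#' and held-out prediction on every fold — and records the null statistic
#' (|r| for continuous responses, accuracy of the full model for binary).
#' The outer fold assignment and per-fold training decompositions depend
#' only on X, so they are computed once and shared across trials.
#'
#' @param X,icv,y,config As in [run_cv_continuous()].
#' @param family `"linear"` or `"logistic"`.
#' @param n_perm Number of permutation trials (>= 1).
#' @param observed Optionally, a precomputed `cv_result` for the unpermuted
#'   response (must use the same config); recomputed when `NULL`.
#' @param conservative Passed to [permutation_pvalue()].
#' @return A `permutation_result`: `n_trials`, `null_stats` (NA for
#'   undefined trials), `n_undefined`, `observed`, `p_value`.
#' @export
permutation_test <- function(X, icv, y, config = cv_config(), n_perm = 1000,
                             family = "linear", observed = NULL,
                             conservative = FALSE) {
  if (n_perm < 1) stop2("n_perm must be >= 1")
  n <- nrow(X)
  folds <- if (family == "linear")
    assign_folds(rownames(X) %||% seq_len(n), config$k,
                 seed = derive_seed(config$seed, "folds"))
  else
    assign_folds(rownames(X) %||% seq_len(n), config$k,
                 seed = derive_seed(config$seed, "folds"), labels = y)
  prep <- prepare_cv(X, icv, folds, config)
  stat_of <- function(yy) {
    if (family == "linear") {
      yhat <- cv_continuous_pass(prep, yy, config)$yhat
      if (sd(yhat) == 0) NA_real_ else abs(cor(yy, yhat))
    } else {
      mean(cv_binary_pass(prep, yy, config)$label_full == yy)
    }
  }
  obs_stat <- if (!is.null(observed)) {
    if (isTRUE(observed$undefined)) NA_real_
    else if (family == "linear") abs(observed$metric) else observed$metric
  } else stat_of(y)
  null_stats <- vapply(seq_len(n_perm), function(t) {
    yp <- with_seed(derive_seed(config$seed, "perm", t), sample(y))
    stat_of(yp)
  }, numeric(1))
  structure(list(n_trials = n_perm, null_stats = null_stats,
                 n_undefined = sum(is.na(null_stats)),
                 observed = obs_stat,
                 p_value = permutation_pvalue(null_stats, obs_stat,
                                              conservative)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> ", x$n_trials, " trials (", x$n_undefined,
      " undefined), observed |stat| = ", signif(x$observed, 4),
      ", p = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' Bootstrap percentile confidence interval
#'
#' Resamples prediction-observation pairs with replacement and reports the
#' 2.5th and 97.5th percentiles of the statistic across resamples. Resamples
#' on which the statistic is undefined (e.g. a constant vector for Pearson
#' r) are redrawn and counted. With `exhaustive = TRUE` (n <= 7) all `n^n`
#' equally likely resamples are enumerated instead of drawn.
#'
#' @param pairs A `cv_result`, or a two-column object (observed, predicted).
#' @param statistic `"pearson_r"` or `"accuracy"`.
#' @param n_boot Number of resamples (default 10000).
#' @param seed RNG seed.
#' @param exhaustive Enumerate all resamples (small n only).
#' @param level Confidence level (default 0.95).
#' @return List with `lower`, `upper`, `n_redrawn`, `statistics`.
#' @export
bootstrap_ci <- function(pairs, statistic = c("pearson_r", "accuracy"),
                         n_boot = 10000, seed = 1, exhaustive = FALSE,
                         level = 0.95) {
  statistic <- match.arg(statistic)
  if (inherits(pairs, "cv_result")) pairs <- cbind(pairs$y, pairs$yhat)
  pairs <- as.matrix(pairs)
  n <- nrow(pairs)
  if (n < 2) stop2("need at least two pairs")
  stat_fun <- if (statistic == "accuracy") {
    function(idx) mean(pairs[idx, 1] == pairs[idx, 2])
  } else {
    function(idx) {
      if (sd(pairs[idx, 1]) == 0 || sd(pairs[idx, 2]) == 0) NA_real_
      else cor(pairs[idx, 1], pairs[idx, 2])
    }
  }
  n_redrawn <- 0
  if (exhaustive) {
    if (n > 7) stop2("exhaustive enumeration only for n <= 7")
    grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    stats <- apply(grid, 1, stat_fun)
    n_redrawn <- sum(is.na(stats))
    stats <- stats[!is.na(stats)]
    if (!length(stats)) stop2("statistic undefined on every resample")
  } else {
    stats <- with_seed(seed, {
      out <- numeric(n_boot)
      for (b in seq_len(n_boot)) {
        repeat {
          s <- stat_fun(sample.int(n, n, replace = TRUE))
          if (!is.na(s)) break
          n_redrawn <- n_redrawn + 1
          if (n_redrawn > 100 * n_boot)
            stop2("statistic undefined on almost every resample")
        }
        out[b] <- s
      }
      out
    })
  }
  alpha <- (1 - level) / 2
  q <- unname(quantile(stats, c(alpha, 1 - alpha)))
  list(lower = q[1], upper = q[2], n_redrawn = n_redrawn, statistics = stats)
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up FDR control at level `q` over a family of p-values.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Logical rejection flags (monotone: rejecting a p-value rejects
#'   all smaller ones).
#' @export
fdr_adjust <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop2("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH") <= q
}

#' Pairwise fingerprint similarity
#'
#' Pearson correlation between every pair of fingerprints, summarized over
#' the strict upper triangle (mean and middle-95% interval). When `groups`
#' is supplied (e.g. the `repeat_of` labels of [generate_repeat_scans()]),
#' within-group (intra-subject) and between-group (inter-subject) pairs are
#' summarized separately.
#'
#' @param X [fingerprint_matrix()] or matrix, n >= 2 non-constant rows.
#' @param groups Optional per-row group labels.
#' @return List with `matrix`, `mean`, `interval` (2.5th/97.5th
#'   percentiles), and, given groups, `intra` and `inter` summaries
#'   (mean/median).
#' @export
pairwise_similarity <- function(X, groups = NULL) {
  x <- if (inherits(X, "fingerprint_matrix")) {
    groups <- groups %||% attr(X, "repeat_of")
    fp_values(X)
  } else as.matrix(X)
  if (nrow(x) < 2) stop2("need at least two fingerprints")
  if (any(apply(x, 1, sd) == 0)) stop2("constant fingerprint row(s)")
  C <- cor(t(x))
  up <- upper.tri(C)
  vals <- C[up]
  out <- list(matrix = C, mean = mean(vals),
              interval = unname(quantile(vals, c(0.025, 0.975))))
  if (!is.null(groups)) {
    same <- outer(groups, groups, `==`)[up]
    out$intra <- list(mean = mean(vals[same]), median = median(vals[same]))
    out$inter <- list(mean = mean(vals[!same]), median = median(vals[!same]))
  }
  out
}

#' Association between ICV and a response
#'
#' Continuous responses: Pearson correlation test. Binary responses: Welch
#' two-sample t-test on ICV by class. The flag reports `p < 0.05`
#' (unadjusted), matching the per-response confound screen reported
#' alongside model results.
#'
#' @param icv Intracranial volumes (non-constant).
#' @param y Response (numeric, or 0/1 / two-level for binary).
#' @param family `"linear"` or `"logistic"`.
#' @return List with `flag`, `p`, `estimate` (correlation or mean
#'   difference).
#' @export
icv_response_association <- function(icv, y, family = "linear") {
  if (sd(icv) == 0) stop2("constant icv")
  if (family == "linear") {
    if (sd(y) == 0) stop2("constant response")
    ct <- cor.test(icv, y)
    list(flag = ct$p.value < 0.05, p = ct$p.value,
         estimate = unname(ct$estimate))
  } else {
    g <- split(icv, y)
    if (length(g) != 2) stop2("binary response must have two classes")
    tt <- t.test(g[[1]], g[[2]])
    list(flag = tt$p.value < 0.05, p = tt$p.value,
         estimate = unname(diff(rev(tt$estimate))))
  }
}
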