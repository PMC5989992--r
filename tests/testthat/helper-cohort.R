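# Shared fixtures: everything is generated in code at test time.

small_cohort <- function(n = 60, p = 300, seed = 42, specs = list(), ...) {
  generate_cohort(cohort_config(n, p, seed = seed, ...), specs)
}

# Economical settings for tests that loop over many pipeline runs.
fast_config <- function(...) {
  args <- list(n_inner_folds = 5, nlambda = 30, lambda_min_ratio = 0.01,
               keep_fold_models = FALSE)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cv_config, args)
}

# Random matrix with mean-zero orthonormal columns (orthogonal to the
# intercept), the natural regime for component scores.
orthonormal_scores <- function(n, r, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * r), n, r)
    qr.Q(qr(scale(m, scale = FALSE)))
  })
}
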