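#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor quantile rnorm rlnorm rbinom coef predict var sd
#'   p.adjust cor.test t.test plogis qnorm runif median setNames
#' @importFrom utils head
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stop2 <- function(...) stop(..., call. = FALSE)

#' Derive a child seed from a top-level seed
#'
#' All randomized stages (fold assignment, inner penalty-selection folds,
#' permutation trials, bootstrap resampling, cohort simulation) draw their
#' seeds through this one scheme so that a single top-level seed reproduces a
#' whole analysis. The child seed is a deterministic 31-bit hash of the parent
#' seed and a purpose string, so unrelated stages get effectively independent
#' streams.
#'
#' @param seed Parent integer seed.
#' @param ... Purpose labels (coerced to character and concatenated), e.g.
#'   `derive_seed(7, "inner", fold)`.
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(7, "folds")
#' derive_seed(7, "inner", 3)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Dense numeric vector from a glmnet sparse coefficient column.
as_dense <- function(x) as.numeric(Matrix::as.matrix(x))

check_finite_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop2(what, " must be a numeric matrix")
  if (!all(is.finite(x)))
    stop2(what, " contains non-finite entries")
  invisible(x)
}
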