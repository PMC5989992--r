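# Economical SVD of the training fingerprint matrix and component-score
# projection (dimensionality-reduction step of the LASSO-PCR pipeline).

#' Economical singular value decomposition of a fingerprint matrix
#'
#' Decomposes the raw (uncentered) training matrix `X = U S V'` keeping only
#' the `min(n, p)` economical factors. No column centering is applied: the
#' shared mean fingerprint then lies in the span of the leading principal
#' axes, so the cohort mean is recoverable as a linear combination of
#' components. The component scores `Z = U S` (equivalently `X V`) are the
#' regression inputs downstream.
#'
#' Sign ambiguity is fixed deterministically: each principal axis (column of
#' V) is flipped so its largest-magnitude entry is positive. Singular values
#' below `1e-10 * max(S)` are truncated to control numerical rank.
#'
#' @param X A [fingerprint_matrix()] or numeric matrix (n >= 2 rows).
#' @param center Logical; default `FALSE` (decompose raw X). `TRUE` performs
#'   column-centered PCA for comparison.
#' @return An `lcp_decomposition` with fields `U` (n x r), `d` (r singular
#'   values, non-increasing), `V` (p x r), `r`, `training_subject_ids`,
#'   `center` and `col_means`.
#' @export
economical_svd <- function(X, center = FALSE) {
  ids <- if (inherits(X, "fingerprint_matrix")) subject_ids(X) else rownames(X)
  x <- if (inherits(X, "fingerprint_matrix")) fp_values(X) else as.matrix(X)
  check_finite_matrix(x, "fingerprint matrix")
  if (nrow(x) < 2) stop2("need at least two subjects")
  col_means <- NULL
  if (center) {
    col_means <- colMeans(x)
    x <- sweep(x, 2, col_means)
  }
  s <- svd(x)                     # economical: min(n, p) factors
  keep <- s$d > 1e-10 * s$d[1]
  U <- s$u[, keep, drop = FALSE]
  V <- s$v[, keep, drop = FALSE]
  d <- s$d[keep]
  # deterministic sign convention
  for (j in seq_along(d)) {
    m <- which.max(abs(V[, j]))
    if (V[m, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  structure(list(U = U, d = d, V = V, r = length(d),
                 training_subject_ids = ids,
                 center = center, col_means = col_means),
            class = "lcp_decomposition")
}

#' @export
print.lcp_decomposition <- function(x, ...) {
  cat("<lcp_decomposition> rank ", x$r, " (", length(x$training_subject_ids),
      " training subjects x ", nrow(x$V), " fiber elements)\n", sep = "")
  invisible(x)
}

# Training-set component scores Z = U S.
training_scores <- function(d) {
  sweep(d$U, 2, d$d, `*`)
}

#' Project fingerprints onto the principal axes
#'
#' Computes component scores `Z_new = X_new V`. For the training rows this
#' equals the corresponding rows of `U S`.
#'
#' @param d An `lcp_decomposition`.
#' @param X_new Matrix (or [fingerprint_matrix()]) with `p` columns.
#' @return Scores matrix (rows subjects, columns components).
#' @export
component_scores <- function(d, X_new) {
  x <- if (inherits(X_new, "fingerprint_matrix")) fp_values(X_new) else as.matrix(X_new)
  if (ncol(x) != nrow(d$V))
    stop2("feature count (", ncol(x), ") does not match decomposition (",
          nrow(d$V), ")")
  if (d$center) x <- sweep(x, 2, d$col_means)
  x %*% d$V
}

#' Variance explained by the components
#'
#' @param d An `lcp_decomposition`.
#' @return Numeric vector of cumulative variance fractions
#'   `cumsum(S^2) / sum(S^2)` (non-decreasing, last element 1).
#' @export
variance_explained <- function(d) {
  if (all(d$d == 0)) stop2("all singular values are zero")
  cumsum(d$d^2) / sum(d$d^2)
}

#' Smallest number of components reaching a variance fraction
#'
#' @param d An `lcp_decomposition`.
#' @param f Target cumulative variance fraction in (0, 1].
#' @return Integer k: smallest component count whose cumulative variance
#'   fraction is at least `f`.
#' @export
components_for_fraction <- function(d, f) {
  if (f <= 0 || f > 1) stop2("f must lie in (0, 1]")
  as.integer(which(variance_explained(d) >= f - 1e-12)[1])
}

#' Rank-k reconstruction of the training matrix
#'
#' @param d An `lcp_decomposition`.
#' @param k Number of leading components to keep (1 <= k <= r).
#' @return The rank-k approximation of the training matrix (uncentering is
#'   undone if the decomposition was centered).
#' @export
reconstruct <- function(d, k = d$r) {
  if (k < 1 || k > d$r) stop2("k must lie in 1..", d$r)
  idx <- seq_len(k)
  x <- d$U[, idx, drop = FALSE] %*% (d$d[idx] * t(d$V[, idx, drop = FALSE]))
  if (d$center) x <- sweep(x, 2, d$col_means, `+`)
  rownames(x) <- d$training_subject_ids
  x
}
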