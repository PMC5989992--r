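# Local connectome phenotype maps: back-projection of component coefficients
# into fiber space, held-out prediction, and voxel-space rendering.

#' Build a local connectome phenotype map
#'
#' Back-projects truncated component coefficients into fiber space:
#' `w = V beta_star`, one weight per fiber element. The map is the phenotype:
#' the fiber-wise influence of local white-matter architecture on the
#' response.
#'
#' @param d An [economical_svd()] decomposition.
#' @param beta_star Component coefficient vector of length `d$r` (from
#'   [truncate_confound()]).
#' @param response_name Label carried in the map.
#' @param fold_id Fold identifier, or `"full"` for a full-sample fit.
#' @return An `lcp_map` with fields `weights` (p-vector), `response_name`,
#'   `fold_id`.
#' @export
build_phenotype_map <- function(d, beta_star, response_name = "response",
                                fold_id = "full") {
  beta_star <- as.numeric(beta_star)
  if (length(beta_star) != d$r)
    stop2("beta_star length (", length(beta_star),
          ") does not match decomposition rank (", d$r, ")")
  nz <- which(beta_star != 0)
  w <- if (length(nz))
    as.numeric(d$V[, nz, drop = FALSE] %*% beta_star[nz])
  else rep(0, nrow(d$V))
  structure(list(weights = w, response_name = response_name,
                 fold_id = fold_id), class = "lcp_map")
}

#' @export
print.lcp_map <- function(x, ...) {
  cat("<lcp_map> '", x$response_name, "' (fold ", x$fold_id, "), ",
      length(x$weights), " fiber weights, ", sum(x$weights != 0),
      " nonzero\n", sep = "")
  invisible(x)
}

#' Predict a continuous response from a phenotype map
#'
#' `yhat_i = x_i . w`: the fingerprint is projected onto the phenotype map.
#' No intercept and no ICV term enter the prediction; performance is
#' assessed by correlating predictions with observations, which is
#' location/scale invariant.
#'
#' @param lcp An `lcp_map`.
#' @param X_new [fingerprint_matrix()] or matrix with matching feature count.
#' @return Numeric vector of per-subject predictions.
#' @export
predict_from_map <- function(lcp, X_new) {
  x <- if (inherits(X_new, "fingerprint_matrix")) fp_values(X_new) else as.matrix(X_new)
  if (ncol(x) != length(lcp$weights))
    stop2("feature count (", ncol(x), ") does not match map length (",
          length(lcp$weights), ")")
  as.numeric(x %*% lcp$weights)
}

#' Predict a binary response from a fitted logistic model
#'
#' Evaluates `p = plogis(intercept + z . beta + beta_icv * icv)` with
#' `z = X_new V`, and labels class 1 when `p >= 0.5` (ties go to class 1).
#' ICV truncation is invalid for logistic models, so the full model
#' (including ICV) is used.
#'
#' @param m A logistic `lcp_sparse_model`.
#' @param d The decomposition the model was fitted on.
#' @param X_new Fingerprints to predict.
#' @param icv_new Matching ICV values (required if the model includes ICV).
#' @return List with `probability` and `label` (0/1 integer).
#' @export
predict_binary <- function(m, d, X_new, icv_new = NULL) {
  stopifnot(inherits(m, "lcp_sparse_model"))
  if (m$family != "logistic")
    stop2("predict_binary requires a logistic model")
  z <- component_scores(d, X_new)
  eta <- m$intercept + as.numeric(z %*% m$beta)
  if (m$has_icv) {
    if (is.null(icv_new)) stop2("model includes ICV; supply icv_new")
    if (length(icv_new) != nrow(z)) stop2("icv_new length mismatch")
    eta <- eta + m$beta_icv * icv_new
  }
  prob <- plogis(eta)
  list(probability = prob, label = as.integer(prob >= 0.5))
}

#' Project a phenotype map into voxel space
#'
#' Each voxel's value is the mean weight of the fiber populations mapped to
#' it; voxels containing no fibers get `background`.
#'
#' @param lcp An `lcp_map`.
#' @param em An [element_map()] covering all `p` features.
#' @param dims Volume dimensions (defaults to the element map's).
#' @param background Value for fiber-free voxels (default 0).
#' @return A `voxel_map`: list with `values` (3-D array), `dims`,
#'   `background`.
#' @export
project_to_voxels <- function(lcp, em, dims = em$dims, background = 0) {
  if (length(em) != length(lcp$weights))
    stop2("element map length (", length(em),
          ") does not match map length (", length(lcp$weights), ")")
  dims <- as.integer(dims)
  co <- em$coords
  if (any(co$i >= dims[1] | co$j >= dims[2] | co$k >= dims[3]))
    stop2("element map coordinates outside dims")
  lin <- 1L + co$i + dims[1] * (co$j + dims[2] * co$k)
  sums <- rowsum(lcp$weights, lin)
  counts <- rowsum(rep(1, length(lin)), lin)
  vals <- array(background, dims)
  vals[as.integer(rownames(sums))] <- sums / counts
  structure(list(values = vals, dims = dims, background = background,
                 response_name = lcp$response_name), class = "voxel_map")
}

#' @export
print.voxel_map <- function(x, ...) {
  cat("<voxel_map> '", x$response_name %||% "", "' ",
      paste(x$dims, collapse = " x "), " volume, ",
      sum(x$values != x$background), " mapped voxels\n", sep = "")
  invisible(x)
}

#' Export a voxel map as NIfTI-1
#'
#' Written as float32 with an identity affine unless a reference image is
#' supplied.
#'
#' @param vm A `voxel_map`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param reference Optional reference NIfTI image or path supplying header
#'   geometry.
#' @export
write_voxel_map_nifti <- function(vm, path, reference = NULL) {
  img <- if (is.null(reference)) RNifti::asNifti(vm$values)
         else RNifti::asNifti(RNifti::updateNifti(vm$values,
                                                  RNifti::readNifti(reference)))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Pairwise correlation between phenotype maps
#'
#' Pearson correlations between the fiber-weight vectors of two or more
#' phenotype maps; the specificity analysis of the pipeline (near-zero
#' off-diagonals mean each phenotype captures attribute-specific structure).
#'
#' @param maps List of `lcp_map`s of equal length, each non-constant.
#' @return Symmetric correlation matrix with unit diagonal, labeled by
#'   response names.
#' @export
phenotype_correlation_matrix <- function(maps) {
  if (length(maps) < 2) stop2("need at least two maps")
  W <- vapply(maps, function(m) m$weights, numeric(length(maps[[1]]$weights)))
  if (any(apply(W, 2, sd) == 0)) stop2("constant map(s)")
  C <- cor(W)
  nm <- vapply(maps, function(m) m$response_name, character(1))
  dimnames(C) <- list(nm, nm)
  C
}
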