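# Data model and I/O for local connectome fingerprint matrices, element maps,
# and subject attribute tables.

#' Construct a fingerprint matrix
#'
#' A fingerprint matrix holds one local connectome fingerprint per row: a
#' p-length vector of fiber-wise diffusion-density estimates sampled along
#' atlas-defined axonal directions. Values are in arbitrary density units
#' until [scale_to_unit_variance()] is applied.
#'
#' @param values Numeric n x p matrix, one subject per row.
#' @param subject_ids Character vector of n unique subject labels.
#' @return An object of class `fingerprint_matrix` (a numeric matrix with
#'   rownames set to the subject IDs).
#' @export
fingerprint_matrix <- function(values, subject_ids = rownames(values)) {
  check_finite_matrix(values, "fingerprint values")
  if (is.null(subject_ids))
    stop2("subject_ids are required (field: subject_ids)")
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != nrow(values))
    stop2("length of subject_ids (", length(subject_ids),
          ") does not match number of rows (", nrow(values), ")")
  if (anyDuplicated(subject_ids))
    stop2("duplicate subject IDs: ",
          paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  rownames(values) <- subject_ids
  structure(values, class = c("fingerprint_matrix", "matrix", "array"))
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat("<fingerprint_matrix> ", nrow(x), " subjects x ", ncol(x),
      " fiber elements\n", sep = "")
  invisible(x)
}

subject_ids <- function(fp) rownames(fp)

# Strip the class so plain matrix algebra applies.
fp_values <- function(fp) {
  x <- unclass(fp)
  attr(x, "repeat_of") <- NULL
  x
}

#' Construct an element map
#'
#' Maps each fingerprint feature (fiber element) to its voxel coordinate and
#' fiber-direction index. Coordinates are 0-based voxel indices; the atlas
#' left-posterior-superior scan order is a property of how features were
#' enumerated and is carried as metadata only.
#'
#' @param coords Data frame or matrix with columns `i`, `j`, `k` (0-based
#'   voxel indices) and `dir` (fiber population index within the voxel).
#' @param dims Integer volume dimensions `c(ni, nj, nk)`.
#' @return An object of class `element_map`.
#' @export
element_map <- function(coords, dims) {
  coords <- as.data.frame(coords)
  need <- c("i", "j", "k", "dir")
  if (!all(need %in% names(coords)))
    stop2("element map needs columns ", paste(need, collapse = ", "))
  coords <- coords[need]
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims < 1))
    stop2("dims must be three positive integers")
  for (ax in 1:3) {
    v <- coords[[ax]]
    if (any(v < 0 | v >= dims[ax]))
      stop2("voxel coordinates outside volume dimensions on axis ", ax)
  }
  key <- paste(coords$i, coords$j, coords$k, coords$dir)
  if (anyDuplicated(key))
    stop2("duplicate (voxel, direction) pairs in element map")
  structure(list(coords = coords, dims = dims, axis_order = "LPS"),
            class = "element_map")
}

#' @export
print.element_map <- function(x, ...) {
  cat("<element_map> ", nrow(x$coords), " fiber elements in a ",
      paste(x$dims, collapse = " x "), " volume (", x$axis_order, ")\n",
      sep = "")
  invisible(x)
}

#' @export
length.element_map <- function(x) nrow(x$coords)

#' Construct a subject attribute table
#'
#' @param data Data frame with a `subject_id` column, an `icv` column
#'   (intracranial volume, mm^3, positive), and one column per response
#'   variable. Missing values are permitted in response columns and handled
#'   per response by [align_and_drop_missing()].
#' @param families Named character vector tagging each response column as
#'   `"continuous"` or `"categorical"`. Columns not named default to
#'   `"continuous"` for numeric and `"categorical"` otherwise.
#' @return An object of class `attribute_table` (a data frame).
#' @export
attribute_table <- function(data, families = NULL) {
  data <- as.data.frame(data)
  if (!"subject_id" %in% names(data)) stop2("missing column: subject_id")
  if (!"icv" %in% names(data)) stop2("missing column: icv")
  data$subject_id <- as.character(data$subject_id)
  if (anyDuplicated(data$subject_id)) stop2("duplicate subject IDs")
  if (any(!is.na(data$icv) & data$icv <= 0)) stop2("icv must be positive")
  resp <- setdiff(names(data), c("subject_id", "icv"))
  fam <- vapply(data[resp], function(x)
    if (is.numeric(x)) "continuous" else "categorical", character(1))
  if (!is.null(families)) {
    bad <- setdiff(names(families), resp)
    if (length(bad)) stop2("families given for unknown columns: ",
                           paste(bad, collapse = ", "))
    fam[names(families)] <- unname(families)
  }
  if (!all(fam %in% c("continuous", "categorical")))
    stop2("families must be 'continuous' or 'categorical'")
  attr(data, "families") <- fam
  class(data) <- c("attribute_table", "data.frame")
  data
}

attribute_families <- function(table) attr(table, "families")

#' Scale each fingerprint to unit variance
#'
#' Density estimates are in arbitrary units, so each subject's fingerprint
#' vector is rescaled to sample variance 1. The operation multiplies each row
#' by a positive constant (no centering), so row direction is preserved, and
#' it is idempotent.
#'
#' @param fp A [fingerprint_matrix()].
#' @return The rescaled `fingerprint_matrix`.
#' @export
scale_to_unit_variance <- function(fp) {
  x <- fp_values(fp)
  s <- apply(x, 1, sd)
  if (any(s == 0))
    stop2("constant fingerprint row(s): ",
          paste(rownames(x)[s == 0], collapse = ", "))
  fingerprint_matrix(x / s, rownames(x))
}

# ---- container I/O ---------------------------------------------------------

#' Save / load a fingerprint container
#'
#' The container is a directory of plain-text files: `matrix.tsv` (one row
#' per subject, `%.17g` formatting so doubles round-trip bit-exactly),
#' `subject_ids.txt`, `element_map.tsv`, and `meta.json`.
#'
#' @param fp A [fingerprint_matrix()].
#' @param em An [element_map()] of length `ncol(fp)`, or `NULL`.
#' @param path Directory to write (created if needed).
#' @return `save_fingerprints` returns `path` invisibly; `load_fingerprints`
#'   returns `list(fingerprints, element_map)`.
#' @export
save_fingerprints <- function(fp, em, path) {
  if (!is.null(em) && length(em) != ncol(fp))
    stop2("element map length (", length(em),
          ") does not match feature count (", ncol(fp), ")")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  x <- fp_values(fp)
  lines <- apply(x, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, file.path(path, "matrix.tsv"))
  writeLines(rownames(x), file.path(path, "subject_ids.txt"))
  meta <- list(n = nrow(x), p = ncol(x), format = "lcpr-container-1")
  if (!is.null(em)) {
    utils::write.table(em$coords, file.path(path, "element_map.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    meta$dims <- em$dims
    meta$axis_order <- em$axis_order
  }
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_fingerprints
#' @export
load_fingerprints <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  idf <- file.path(path, "subject_ids.txt")
  if (!file.exists(idf)) stop2("container missing field: subject_ids")
  ids <- readLines(idf)
  lines <- readLines(file.path(path, "matrix.tsv"))
  x <- do.call(rbind, lapply(strsplit(lines, "\t", fixed = TRUE), as.numeric))
  if (nrow(x) != meta$n || ncol(x) != meta$p)
    stop2("matrix dimensions disagree with container metadata")
  fp <- fingerprint_matrix(x, ids)
  em <- NULL
  emf <- file.path(path, "element_map.tsv")
  if (file.exists(emf)) {
    coords <- utils::read.table(emf, header = TRUE, sep = "\t")
    if (nrow(coords) != ncol(x))
      stop2("element map length (", nrow(coords),
            ") does not match feature count (", ncol(x), ")")
    em <- element_map(coords, meta$dims)
  }
  list(fingerprints = fp, element_map = em)
}

#' Read / write an attribute table as CSV
#'
#' UTF-8 CSV with a header row, `subject_id` key column and `icv` column.
#'
#' @param table An [attribute_table()].
#' @param path CSV file path.
#' @param families Optional family tags passed to [attribute_table()] on read.
#' @export
write_attributes <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_attributes
#' @export
read_attributes <- function(path, families = NULL) {
  attribute_table(utils::read.csv(path, fileEncoding = "UTF-8"), families)
}

# ---- response preparation --------------------------------------------------

#' Prepare a binary response from a categorical column
#'
#' Keeps the two largest categories that each contain at least
#' `min_class_count` subjects and drops subjects in all other categories.
#' The larger retained class is encoded 0 and the smaller 1; ties in class
#' size are broken lexicographically (earlier label becomes class 0).
#'
#' @param table An [attribute_table()].
#' @param column Name of a categorical column.
#' @param min_class_count Minimum subjects a category needs to be retained.
#' @return List with `y` (named 0/1 integer vector), `subject_ids`, `classes`
#'   (labels of class 0 and 1), and `n_dropped`.
#' @export
prepare_binary_response <- function(table, column, min_class_count = 50) {
  fam <- attribute_families(table)
  if (!column %in% names(fam)) stop2("unknown response column: ", column)
  if (fam[[column]] != "categorical")
    stop2("column ", column, " is not categorical")
  v <- as.character(table[[column]])
  ok <- !is.na(v)
  counts <- sort(table(v[ok]), decreasing = TRUE)
  counts <- counts[counts >= min_class_count]
  if (length(counts) < 2)
    stop2("fewer than two classes with at least ", min_class_count,
          " subjects in ", column)
  # two largest; size-then-lexicographic tie-break
  ord <- order(-as.integer(counts), names(counts))
  keep <- names(counts)[ord][1:2]
  sel <- ok & v %in% keep
  y <- as.integer(v[sel] == keep[2])
  names(y) <- table$subject_id[sel]
  list(y = y, subject_ids = table$subject_id[sel], classes = keep,
       n_dropped = sum(!sel))
}

#' Align fingerprints with a response and drop incomplete cases
#'
#' Restricts to subjects present in both the fingerprint matrix and the
#' attribute table with a non-missing response and ICV (per-response
#' complete-case deletion, so each response keeps its own sample size).
#' Output order is the fingerprint row order restricted to retained subjects.
#'
#' @param fp A [fingerprint_matrix()].
#' @param table An [attribute_table()].
#' @param response Response column name, or a named vector as returned in
#'   `prepare_binary_response()$y`.
#' @return List with `X` (fingerprint_matrix), `icv`, `y`, `subject_ids`, `n`.
#' @export
align_and_drop_missing <- function(fp, table, response) {
  if (is.character(response) && length(response) == 1) {
    y_all <- table[[response]]
    if (is.null(y_all)) stop2("unknown response column: ", response)
    names(y_all) <- table$subject_id
  } else {
    y_all <- response
    if (is.null(names(y_all))) stop2("response vector must be named by subject")
  }
  icv_all <- table$icv
  names(icv_all) <- table$subject_id
  ids <- subject_ids(fp)
  keep <- ids[ids %in% names(y_all)]
  keep <- keep[!is.na(y_all[keep]) & !is.na(icv_all[keep])]
  if (!length(keep)) stop2("no subjects shared between fingerprints and response")
  list(X = fingerprint_matrix(fp_values(fp)[keep, , drop = FALSE], keep),
       icv = unname(icv_all[keep]), y = unname(y_all[keep]),
       subject_ids = keep, n = length(keep))
}
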