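#' Sparse cells-by-features count container
#'
#' A `counts_triplet` bundles the three pieces a guide/barcode-aware screen
#' needs: a sparse UMI matrix over all features, a feature table tagging each
#' feature as `gene`, `guide` or `organoid_bc`, and a parallel sparse read
#' matrix defined for the guide and organoid-barcode features (direct-capture
#' libraries report both deduplicated UMIs and raw reads, and both enter the
#' assignment rules).
#'
#' @param umi sparse or dense numeric matrix, cells in rows, features in
#'   columns; coerced to `dgCMatrix`. Row and column names are required.
#' @param features data frame with columns `feature_id` and `class`
#'   (`"gene"`, `"guide"` or `"organoid_bc"`), one row per column of `umi`.
#' @param reads sparse matrix of read counts for the guide/organoid-BC
#'   feature subset (columns named after those features). Entrywise
#'   `reads >= umi` is enforced. May be `NULL` when no read counts exist.
#' @return An object of class `counts_triplet`.
#' @export
counts_triplet <- function(umi, features, reads = NULL) {
  umi <- methods::as(methods::as(methods::as(umi, "dMatrix"), "generalMatrix"),
                     "CsparseMatrix")
  features <- tibble::as_tibble(features)
  stopifnot(all(c("feature_id", "class") %in% names(features)))
  if (is.null(colnames(umi)) || is.null(rownames(umi))) {
    stop("`umi` must carry cell (row) and feature (column) names")
  }
  if (!identical(colnames(umi), features$feature_id)) {
    stop("feature table must match `umi` columns (same ids, same order)")
  }
  bad <- setdiff(unique(features$class), c("gene", "guide", "organoid_bc"))
  if (length(bad) > 0) {
    stop("unknown feature class: ", paste(bad, collapse = ", "))
  }
  if (any(umi@x < 0) || any(umi@x != round(umi@x))) {
    stop("UMI counts must be non-negative integers")
  }
  if (!is.null(reads)) {
    reads <- methods::as(methods::as(methods::as(reads, "dMatrix"), "generalMatrix"),
                         "CsparseMatrix")
    tagged <- features$feature_id[features$class %in% c("guide", "organoid_bc")]
    if (!all(colnames(reads) %in% tagged)) {
      stop("read counts are only defined for guide/organoid_bc features")
    }
    if (!identical(rownames(reads), rownames(umi))) {
      stop("`reads` rows must match `umi` rows")
    }
    if (any(reads@x < 0) || any(reads@x != round(reads@x))) {
      stop("read counts must be non-negative integers")
    }
    diff <- reads - umi[, colnames(reads), drop = FALSE]
    if (any(diff@x < -1e-9)) stop("read count < UMI count for some entries")
  }
  structure(
    list(umi = umi, reads = reads, features = features, cells = rownames(umi)),
    class = "counts_triplet"
  )
}

#' @export
print.counts_triplet <- function(x, ...) {
  cls <- table(x$features$class)
  cat("<counts_triplet> ", length(x$cells), " cells x ", nrow(x$features),
      " features (", paste(names(cls), cls, sep = ":", collapse = ", "), ")",
      if (!is.null(x$reads)) paste0("; read counts for ", ncol(x$reads), " features"),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.counts_triplet <- function(x) dim(x$umi)

#' Extract the UMI (or read) submatrix for a feature class
#'
#' @param x a [counts_triplet()].
#' @param class feature class to keep (`NULL` keeps all).
#' @return A `dgCMatrix`, cells in rows.
#' @export
ct_umi <- function(x, class = NULL) {
  stopifnot(inherits(x, "counts_triplet"))
  if (is.null(class)) return(x$umi)
  x$umi[, x$features$feature_id[x$features$class %in% class], drop = FALSE]
}

#' @rdname ct_umi
#' @export
ct_reads <- function(x, class = NULL) {
  stopifnot(inherits(x, "counts_triplet"))
  if (is.null(x$reads)) stop("this counts_triplet carries no read counts")
  if (is.null(class)) return(x$reads)
  keep <- intersect(colnames(x$reads),
                    x$features$feature_id[x$features$class %in% class])
  x$reads[, keep, drop = FALSE]
}

#' Subset a counts_triplet by cells and/or features
#'
#' @param x a [counts_triplet()].
#' @param cells character vector of cell ids to keep (default all).
#' @param features character vector of feature ids to keep (default all).
#' @return A [counts_triplet()].
#' @export
ct_subset <- function(x, cells = NULL, features = NULL) {
  stopifnot(inherits(x, "counts_triplet"))
  if (is.null(cells)) cells <- x$cells
  if (is.null(features)) features <- x$features$feature_id
  umi <- x$umi[cells, features, drop = FALSE]
  reads <- NULL
  if (!is.null(x$reads)) {
    keep <- intersect(colnames(x$reads), features)
    reads <- x$reads[cells, keep, drop = FALSE]
    if (ncol(reads) == 0) reads <- NULL
  }
  counts_triplet(umi, x$features[match(features, x$features$feature_id), ], reads)
}

#' Write a counts_triplet as MatrixMarket + TSV sidecars
#'
#' Writes `matrix.mtx` (UMIs over all features, 1-based MatrixMarket
#' coordinates), `barcodes.tsv` (cell ids), `features.tsv` (feature id and
#' class) and, when read counts exist, `reads.mtx` + `read_features.tsv` for
#' the guide/organoid-BC subset.
#'
#' @param x a [counts_triplet()].
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_counts_triplet <- function(x, dir) {
  stopifnot(inherits(x, "counts_triplet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$umi, file.path(dir, "matrix.mtx"))
  readr::write_lines(x$cells, file.path(dir, "barcodes.tsv"))
  readr::write_tsv(x$features, file.path(dir, "features.tsv"), col_names = FALSE)
  if (!is.null(x$reads)) {
    Matrix::writeMM(x$reads, file.path(dir, "reads.mtx"))
    readr::write_lines(colnames(x$reads), file.path(dir, "read_features.tsv"))
  }
  invisible(dir)
}

#' Read a counts_triplet written by [write_counts_triplet()]
#'
#' @param dir directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv` and optionally `reads.mtx` + `read_features.tsv`.
#' @return A [counts_triplet()].
#' @export
read_counts_triplet <- function(dir) {
  umi <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  cells <- readr::read_lines(file.path(dir, "barcodes.tsv"))
  features <- readr::read_tsv(file.path(dir, "features.tsv"),
                              col_names = c("feature_id", "class"),
                              col_types = "cc", progress = FALSE)
  dimnames(umi) <- list(cells, features$feature_id)
  reads <- NULL
  rf <- file.path(dir, "reads.mtx")
  if (file.exists(rf)) {
    reads <- methods::as(Matrix::readMM(rf), "CsparseMatrix")
    dimnames(reads) <- list(cells, readr::read_lines(file.path(dir, "read_features.tsv")))
  }
  counts_triplet(umi, features, reads)
}
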