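#' Marker gene union for one cell type
#'
#' The union of (a) the `n_top` genes most highly expressed in the target
#' type and (b) the `n_top` most specific genes, specificity being the
#' target's expression minus the mean expression of all other types. Ties
#' break deterministically by gene id.
#'
#' @param profiles numeric matrix of mean log-normalised expression, cell
#'   types in rows, genes in columns (a pseudobulk profile matrix).
#' @param target_type row name of the target type.
#' @param n_top genes per criterion (default 1500); when fewer genes exist
#'   all are used, with a warning.
#' @return Character vector of gene ids.
#' @export
marker_gene_union <- function(profiles, target_type, n_top = 1500) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop("need at least 2 cell types")
  if (!target_type %in% rownames(profiles)) {
    stop("unknown target type: ", target_type)
  }
  genes <- colnames(profiles)
  if (length(genes) < n_top) {
    warning("fewer genes than `n_top`; using all ", length(genes), " genes")
    n_top <- length(genes)
  }
  expr <- profiles[target_type, ]
  others <- profiles[setdiff(rownames(profiles), target_type), , drop = FALSE]
  spec <- expr - colMeans(others)
  top_expr <- genes[order(-expr, genes)][seq_len(n_top)]
  top_spec <- genes[order(-spec, genes)][seq_len(n_top)]
  union(top_expr, top_spec)
}

## NNLS with a free intercept: the intercept column is split into +/- parts
## so the non-negativity constraint never binds it
nnls_with_intercept <- function(y, X) {
  A <- cbind(`(Intercept)+` = 1, `(Intercept)-` = -1, X)
  fit <- pracma::lsqnonneg(A, y)
  w <- fit$x
  list(intercept = w[1] - w[2], coef = stats::setNames(w[-(1:2)], colnames(X)))
}

#' Reciprocal NNLS cell-type correspondence between two datasets
#'
#' For each target type `a` in dataset A, its pseudobulk profile over the
#' marker gene union ([marker_gene_union()]) is regressed on all of B's
#' type profiles by non-negative least squares with a free intercept,
#' `T_a = beta_0a + beta_1a * M_b`; the reverse direction is fitted
#' likewise, and the two coefficients are combined as
#' `beta = 2 * (beta_ab + eps) * (beta_ba + eps)`, so high values require
#' reciprocal, specific predictivity. Gene universes are intersected
#' before selection.
#'
#' @param a,b numeric matrices of mean log-normalised expression, cell
#'   types x genes, with dimnames.
#' @param n_top marker genes per criterion (default 1500).
#' @param eps stabiliser in the combined coefficient (default 0.01;
#'   mutually orthogonal profiles give `2 * eps^2`).
#' @return Tibble of class `correspondence`: `type_a`, `type_b`,
#'   `beta_ab`, `beta_ba`, `combined`.
#' @export
nnls_correspondence <- function(a, b, n_top = 1500, eps = 0.01) {
  a <- as.matrix(a); b <- as.matrix(b)
  shared <- intersect(colnames(a), colnames(b))
  if (length(shared) == 0) stop("no shared genes between the two datasets")
  dropped <- (ncol(a) - length(shared)) + (ncol(b) - length(shared))
  if (dropped > 0) {
    message(dropped, " unmatched gene column(s) dropped before selection")
  }
  a <- a[, shared, drop = FALSE]; b <- b[, shared, drop = FALSE]

  fit_direction <- function(from, to) {
    # predict each type of `from` using all types of `to`
    out <- matrix(0, nrow(from), nrow(to),
                  dimnames = list(rownames(from), rownames(to)))
    for (ty in rownames(from)) {
      if (all(from[ty, ] == 0)) {
        warning("all-zero profile for type '", ty, "'; coefficients set to 0")
        next
      }
      genes <- marker_gene_union(from, ty, n_top)
      fit <- nnls_with_intercept(from[ty, genes], t(to[, genes, drop = FALSE]))
      out[ty, ] <- fit$coef[rownames(to)]
    }
    out
  }
  beta_ab <- fit_direction(a, b)   # T_a ~ M_b
  beta_ba <- fit_direction(b, a)   # T_b ~ M_a
  grid <- expand.grid(type_a = rownames(a), type_b = rownames(b),
                      stringsAsFactors = FALSE)
  out <- tibble::tibble(
    type_a = grid$type_a, type_b = grid$type_b,
    beta_ab = beta_ab[cbind(grid$type_a, grid$type_b)],
    beta_ba = beta_ba[cbind(grid$type_b, grid$type_a)]
  )
  out$combined <- 2 * (out$beta_ab + eps) * (out$beta_ba + eps)
  class(out) <- c("correspondence", class(out))
  out
}
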