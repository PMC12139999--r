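## goodness-of-fit chi-square of observed counts against fixed background
## proportions; categories with zero background probability are dropped by
## the caller. Direct formula so the statistic is exactly sum((O-E)^2/E).
chisq_stat <- function(obs, bg_prop) {
  e <- sum(obs) * bg_prop
  sum((obs - e)^2 / e)
}

#' Cell-type composition screen with an NTC-mimicking empirical null
#'
#' Tests each target's cell-type composition against the pooled
#' non-targeting-control (NTC) background with a chi-square goodness-of-fit
#' test, and calibrates significance empirically: retained NTC guides are
#' randomly partitioned into groups of `ntc_group_size` (mimicking the
#' guides-per-target structure), every tested unit is downsampled without
#' replacement to `downsample` cells, and the significance cutoff is the
#' `q`-quantile of the NTC groups' p-values, so a unit is flagged iff its
#' p-value undercuts what matched negative controls achieve.
#'
#' Filtering follows the screen conventions: targets (pooling their guides)
#' need `min_target_cells` cells, individual NTC guides `min_ntc_cells`.
#' The background pools all retained NTC cells, including a tested NTC
#' group's own cells. Cell types absent from the background are dropped
#' with a warning; the full remaining category set is kept for every unit
#' (zero observed counts allowed), so the degrees of freedom are constant.
#'
#' With `clonotype_aware = TRUE` (monoclonal designs, where clone identity
#' is known) the analytic chi-square null - which assumes cells are
#' independent draws and is badly anti-conservative when cells cluster in
#' clones - is replaced by a clonotype-level resampling null: each unit's
#' statistic is compared against `n_null` statistics of randomly drawn,
#' size-matched sets of NTC clonotypes, extending the NTC-mimicking
#' philosophy from guides to whole clones.
#'
#' @param cells data frame with one row per assigned cell and columns
#'   `target_id`, `guide_id`, `is_ntc`, `cell_type`, plus `clonotype_id`
#'   when `clonotype_aware`.
#' @param min_target_cells minimum cells per target (default 50).
#' @param min_ntc_cells minimum cells per NTC guide (default 20).
#' @param ntc_group_size NTC guides per null group (default 3).
#' @param downsample cells per tested unit (default 100); units at or under
#'   the size pass through unchanged.
#' @param q quantile of NTC-group p-values used as empirical cutoff
#'   (default 0.05, type-7 interpolation).
#' @param seed RNG seed for grouping and downsampling.
#' @param clonotype_aware use the clonotype resampling null (default FALSE).
#' @param n_null resampling draws per unit when `clonotype_aware`
#'   (default 199).
#' @return Object of class `screen_test`: list with `targets` (tibble
#'   `target_id`, `n_cells`, `statistic`, `df`, `p_value`, `significant`),
#'   `ntc_groups` (tibble `group_id`, `guides`, `n_cells`, `statistic`,
#'   `p_value`), `cutoff`, `q`, `background` (tibble `cell_type`, `prop`),
#'   `seed`.
#' @export
screen_composition <- function(cells, min_target_cells = 50,
                               min_ntc_cells = 20, ntc_group_size = 3,
                               downsample = 100, q = 0.05, seed = NULL,
                               clonotype_aware = FALSE, n_null = 199) {
  needed <- c("target_id", "guide_id", "is_ntc", "cell_type")
  stopifnot(all(needed %in% names(cells)))
  if (clonotype_aware && !"clonotype_id" %in% names(cells)) {
    stop("`clonotype_aware` testing needs a `clonotype_id` column")
  }
  if (!is.null(seed)) set.seed(seed)
  cells <- tibble::as_tibble(cells)

  ntc <- dplyr::filter(cells, .data$is_ntc)
  per_guide <- table(ntc$guide_id)
  keep_ntc <- names(per_guide)[per_guide >= min_ntc_cells]
  ntc <- dplyr::filter(ntc, .data$guide_id %in% keep_ntc)
  n_groups <- floor(length(keep_ntc) / ntc_group_size)
  if (n_groups < 2) stop("fewer than 2 NTC groups: empirical null not estimable")

  types <- sort(unique(cells$cell_type))
  bg_counts <- table(factor(ntc$cell_type, levels = types))
  if (any(bg_counts == 0)) {
    warning("cell type(s) absent from NTC background dropped: ",
            paste(types[bg_counts == 0], collapse = ", "))
    types <- types[bg_counts > 0]
    bg_counts <- bg_counts[bg_counts > 0]
  }
  bg_prop <- as.vector(bg_counts) / sum(bg_counts)
  df <- length(types) - 1

  ds <- function(idx) if (length(idx) > downsample) sample(idx, downsample) else idx
  tab_types <- function(ct) table(factor(ct, levels = types))

  tg <- dplyr::filter(cells, !.data$is_ntc)
  per_target <- table(tg$target_id)
  targets <- names(per_target)[per_target >= min_target_cells]
  shuffled <- sample(keep_ntc)
  groups <- split(shuffled[seq_len(n_groups * ntc_group_size)],
                  rep(seq_len(n_groups), each = ntc_group_size))

  if (clonotype_aware) {
    ntc_clones <- split(ntc$cell_type, ntc$clonotype_id)
    # per-clonotype type counts, so a draw's own cells can be removed from
    # the background it is compared against
    clone_counts <- t(vapply(ntc_clones,
                             function(ct) as.vector(tab_types(ct)),
                             numeric(length(types))))
    bg_total <- as.vector(bg_counts)
    null_p <- function(obs_stat, n_cl, exclude_from_bg) {
      n_draw <- min(n_cl, length(ntc_clones) - 2L)
      draws <- vapply(seq_len(n_null), function(b) {
        idx <- sample.int(length(ntc_clones), n_draw)
        ct <- unlist(ntc_clones[idx], use.names = FALSE)
        p_b <- bg_prop
        if (exclude_from_bg) {
          # a target unit is independent of the NTC background; its null
          # draws must be too, or their statistics are shrunk
          left <- bg_total - colSums(clone_counts[idx, , drop = FALSE])
          p_b <- left / sum(left)
        }
        chisq_stat(tab_types(ds(ct)), p_b)
      }, numeric(1))
      (1 + sum(draws >= obs_stat)) / (n_null + 1)
    }
  }

  unit_test <- function(sub, in_background) {
    idx <- ds(seq_len(nrow(sub)))
    stat <- chisq_stat(tab_types(sub$cell_type[idx]), bg_prop)
    if (clonotype_aware) {
      p <- null_p(stat, dplyr::n_distinct(sub$clonotype_id),
                  exclude_from_bg = !in_background)
    } else {
      p <- stats::pchisq(stat, df, lower.tail = FALSE)
    }
    c(statistic = stat, p_value = p)
  }

  t_res <- lapply(targets,
                  function(t) unit_test(tg[tg$target_id == t, ], FALSE))
  n_res <- lapply(groups,
                  function(g) unit_test(ntc[ntc$guide_id %in% g, ], TRUE))

  target_tbl <- tibble::tibble(
    target_id = targets,
    n_cells = as.vector(per_target[targets]),
    statistic = vapply(t_res, `[[`, numeric(1), "statistic"),
    df = df,
    p_value = vapply(t_res, `[[`, numeric(1), "p_value")
  )
  ntc_tbl <- tibble::tibble(
    group_id = paste0("ntc_group_", seq_along(groups)),
    guides = vapply(groups, paste, character(1), collapse = ","),
    n_cells = vapply(groups, function(g) sum(ntc$guide_id %in% g), numeric(1)),
    statistic = vapply(n_res, `[[`, numeric(1), "statistic"),
    p_value = vapply(n_res, `[[`, numeric(1), "p_value")
  )
  cutoff <- stats::quantile(ntc_tbl$p_value, q, type = 7, names = FALSE)
  target_tbl$significant <- target_tbl$p_value < cutoff
  structure(list(targets = target_tbl, ntc_groups = ntc_tbl, cutoff = cutoff,
                 q = q, background = tibble::tibble(cell_type = types,
                                                    prop = bg_prop),
                 seed = seed, clonotype_aware = clonotype_aware),
            class = "screen_test")
}

#' @export
print.screen_test <- function(x, ...) {
  cat("<screen_test> ", nrow(x$targets), " targets vs ", nrow(x$ntc_groups),
      " NTC groups; empirical cutoff p < ", signif(x$cutoff, 3), " (q = ",
      x$q, "); ", sum(x$targets$significant), " targets flagged\n", sep = "")
  invisible(x)
}

#' Per-cell-type odds ratios of a target against the NTC pool
#'
#' For each cell type, the 2x2 table (in/out of the type) x (target/NTC)
#' gives an odds ratio; tables containing a zero get `haldane` added to all
#' four counts (Haldane-Anscombe correction) so ratios stay finite.
#'
#' @param cells data frame with `target_id`, `is_ntc`, `cell_type`.
#' @param target the target to contrast against all NTC cells.
#' @param haldane correction added to zero-containing tables (default 0.5).
#' @return Tibble `cell_type`, `n_target`, `n_ntc`, `odds_ratio`,
#'   `log2_odds_ratio`.
#' @export
celltype_odds_ratios <- function(cells, target, haldane = 0.5) {
  stopifnot(all(c("target_id", "is_ntc", "cell_type") %in% names(cells)))
  tg <- cells$cell_type[cells$target_id == target & !cells$is_ntc]
  nt <- cells$cell_type[cells$is_ntc]
  if (length(tg) == 0 || length(nt) == 0) stop("both groups must be non-empty")
  types <- sort(unique(c(tg, nt)))
  purrr::map_dfr(types, function(ct) {
    a <- sum(tg == ct); b <- length(tg) - a
    c_ <- sum(nt == ct); d <- length(nt) - c_
    if (any(c(a, b, c_, d) == 0)) {
      a <- a + haldane; b <- b + haldane; c_ <- c_ + haldane; d <- d + haldane
    }
    or <- (a * d) / (b * c_)
    tibble::tibble(cell_type = ct, n_target = sum(tg == ct),
                   n_ntc = sum(nt == ct), odds_ratio = or,
                   log2_odds_ratio = log2(or))
  })
}

## exact k nearest neighbours by blockwise Euclidean distance
knn_indices <- function(x, k, block = 512) {
  n <- nrow(x)
  if (k >= n) stop("`k` must be smaller than the number of cells")
  sq <- rowSums(x^2)
  out <- matrix(NA_integer_, n, k)
  for (start in seq(1, n, by = block)) {
    idx <- start:min(start + block - 1, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * x[idx, , drop = FALSE] %*% t(x)
    for (r in seq_along(idx)) {
      d2[r, idx[r]] <- Inf  # self excluded
      out[idx[r], ] <- order(d2[r, ])[seq_len(k)]
    }
  }
  out
}

#' k-nearest-neighbour perturbation enrichment
#'
#' Measures local clustering of perturbations in an embedding without using
#' cell-type annotations: targets with at least `min_target_cells` cells
#' are each downsampled to `per_target_downsample`, and for every retained
#' cell the fraction of its `k` exact Euclidean nearest neighbours (within
#' the full retained set, self excluded) sharing its target is computed.
#' The per-target mean is reported next to the random-label expectation
#' (the target's fraction of retained cells).
#'
#' @param embedding numeric matrix, cells x dimensions (e.g. top PCs), with
#'   cell ids as row names.
#' @param labels character vector of per-cell target labels, parallel to
#'   the embedding rows.
#' @param k neighbours per cell (default 20).
#' @param per_target_downsample cells retained per target (default 200).
#' @param min_target_cells minimum cells for a target to enter (default 50).
#' @param seed RNG seed for downsampling.
#' @return Tibble of class `knn_enrichment`: `target_id`, `score`,
#'   `expected`, `n_cells`, `k`.
#' @export
knn_enrichment <- function(embedding, labels, k = 20,
                           per_target_downsample = 200,
                           min_target_cells = 50, seed = NULL) {
  embedding <- as.matrix(embedding)
  stopifnot(nrow(embedding) == length(labels), ncol(embedding) >= 1)
  if (!is.null(seed)) set.seed(seed)
  tab <- table(labels)
  targets <- names(tab)[tab >= min_target_cells]
  keep <- unlist(lapply(targets, function(t) {
    idx <- which(labels == t)
    if (length(idx) > per_target_downsample) sample(idx, per_target_downsample)
    else idx
  }))
  keep <- sort(keep)
  emb <- embedding[keep, , drop = FALSE]
  lab <- labels[keep]
  nn <- knn_indices(emb, k)
  same <- rowMeans(matrix(lab[nn] == rep(lab, ncol(nn)), nrow(nn), ncol(nn)))
  out <- tibble::tibble(
    target_id = targets,
    score = vapply(targets, function(t) mean(same[lab == t]), numeric(1),
                   USE.NAMES = FALSE),
    expected = vapply(targets, function(t) mean(lab == t), numeric(1),
                      USE.NAMES = FALSE),
    n_cells = vapply(targets, function(t) sum(lab == t), numeric(1),
                     USE.NAMES = FALSE),
    k = k
  )
  class(out) <- c("knn_enrichment", class(out))
  out
}

#' Compare per-clonotype cell-type fractions between a target and NTC
#'
#' Treats each clonotype (one monoclonal EB) as the replicate: the fraction
#' of its cells in `cell_type` is computed, and the target and NTC
#' clonotype fractions are compared by a two-sided Wilcoxon rank-sum test
#' (exact for small untied samples, normal approximation with tie
#' correction otherwise).
#'
#' @param cells data frame with `clonotype_id`, `target_id`, `cell_type`.
#' @param target,ntc the two `target_id` values to compare (the NTC pool is
#'   usually labelled `"NTC"`).
#' @param cell_type the cell type whose fraction is tested.
#' @return Object of class `fraction_test`: `p_value`, `statistic`,
#'   `method`, `cell_type`, and `fractions` (tibble `clonotype_id`,
#'   `group`, `n_cells`, `fraction`).
#' @export
clonotype_fraction_test <- function(cells, target, ntc = "NTC", cell_type) {
  stopifnot(all(c("clonotype_id", "target_id", "cell_type") %in% names(cells)))
  sub <- dplyr::filter(cells, .data$target_id %in% c(target, ntc))
  fr <- sub |>
    dplyr::group_by(.data$clonotype_id, .data$target_id) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     fraction = mean(.data$cell_type == .env$cell_type),
                     .groups = "drop") |>
    dplyr::mutate(group = ifelse(.data$target_id == target, "target", "ntc"))
  if (sum(fr$group == "target") < 2 || sum(fr$group == "ntc") < 2) {
    stop("need at least 2 clonotypes in each group")
  }
  ht <- suppressWarnings(stats::wilcox.test(
    fr$fraction[fr$group == "target"], fr$fraction[fr$group == "ntc"],
    alternative = "two.sided"
  ))
  structure(list(p_value = ht$p.value, statistic = unname(ht$statistic),
                 method = ht$method, cell_type = cell_type, target = target,
                 ntc = ntc,
                 fractions = fr[, c("clonotype_id", "group", "n_cells",
                                    "fraction")]),
            class = "fraction_test")
}

#' @export
print.fraction_test <- function(x, ...) {
  cat("<fraction_test> ", x$target, " vs ", x$ntc, " in ", x$cell_type,
      ": W = ", x$statistic, ", p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

## vectorised per-gene two-sided rank-sum p-values (normal approximation
## with tie correction), columns of `mat` are genes
ranksum_p_matrix <- function(mat, grp1) {
  n1 <- sum(grp1); n2 <- sum(!grp1); n <- n1 + n2
  apply(mat, 2, function(v) {
    r <- rank(v)
    w <- sum(r[grp1]) - n1 * (n1 + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 == 0) return(1)
    z <- (w - n1 * n2 / 2 - sign(w - n1 * n2 / 2) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  })
}

#' Single-cell versus clonotype-replicate differential expression
#'
#' Quantifies how many single-cell differential-expression calls survive
#' when individual clonotypes (monoclonal EBs) are treated as the
#' biological replicates. The single-cell track tests each gene across
#' cells (target vs NTC) on log1p counts-per-10k with a two-sided rank-sum
#' test; the clonotype track sums counts per clonotype, normalises to
#' counts-per-million, log1p-transforms and rank-sum-tests across
#' clonotypes. Both tracks are Benjamini-Hochberg corrected at `alpha`.
#' The unsupported fraction - single-cell calls absent from the clonotype
#' track - estimates how many single-cell hits are driven by EB-to-EB
#' heterogeneity rather than the perturbation.
#'
#' @param gene_umi sparse/dense cells x genes UMI matrix with cell ids as
#'   row names (or a [counts_triplet()], whose `gene` features are used).
#' @param cells data frame with `cell_id`, `clonotype_id`, `target_id`.
#' @param target,ntc the `target_id` values compared.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return Object of class `de_compare`: `sc_genes`, `clonotype_genes`,
#'   `unsupported_genes`, `unsupported_fraction` (`NA` when there are no
#'   single-cell calls), and `table` (per-gene p-values and calls).
#' @export
pseudobulk_de_compare <- function(gene_umi, cells, target, ntc = "NTC",
                                  alpha = 0.05) {
  if (inherits(gene_umi, "counts_triplet")) gene_umi <- ct_umi(gene_umi, "gene")
  stopifnot(all(c("cell_id", "clonotype_id", "target_id") %in% names(cells)))
  sub <- dplyr::filter(cells, .data$target_id %in% c(target, ntc),
                       !is.na(.data$clonotype_id))
  if (dplyr::n_distinct(sub$clonotype_id[sub$target_id == target]) < 2 ||
      dplyr::n_distinct(sub$clonotype_id[sub$target_id == ntc]) < 2) {
    stop("need at least 2 clonotypes per group")
  }
  m <- gene_umi[sub$cell_id, , drop = FALSE]
  grp1 <- sub$target_id == target

  # single-cell track: log1p CP10K
  tot <- pmax(Matrix::rowSums(m), 1)
  norm <- log1p(as.matrix(m) / tot * 1e4)
  p_sc <- ranksum_p_matrix(norm, grp1)
  padj_sc <- stats::p.adjust(p_sc, "BH")

  # clonotype track: pseudobulk CPM, log1p
  cl <- factor(sub$clonotype_id)
  ind <- Matrix::sparseMatrix(i = seq_len(nrow(sub)), j = as.integer(cl), x = 1,
                              dims = c(nrow(sub), nlevels(cl)))
  pb <- as.matrix(Matrix::t(ind) %*% m)
  rownames(pb) <- levels(cl)
  pb_norm <- log1p(pb / pmax(rowSums(pb), 1) * 1e6)
  cl_grp <- (sub$target_id[match(levels(cl), sub$clonotype_id)]) == target
  p_pb <- apply(pb_norm, 2, function(v) {
    suppressWarnings(stats::wilcox.test(v[cl_grp], v[!cl_grp])$p.value)
  })
  padj_pb <- stats::p.adjust(p_pb, "BH")

  genes <- colnames(m)
  sc_genes <- genes[padj_sc <= alpha]
  pb_genes <- genes[padj_pb <= alpha]
  unsupported <- setdiff(sc_genes, pb_genes)
  structure(list(
    sc_genes = sc_genes, clonotype_genes = pb_genes,
    unsupported_genes = unsupported,
    unsupported_fraction = if (length(sc_genes) == 0) NA_real_
                           else length(unsupported) / length(sc_genes),
    table = tibble::tibble(gene = genes, p_sc = p_sc, padj_sc = padj_sc,
                           p_clonotype = p_pb, padj_clonotype = padj_pb,
                           call_sc = padj_sc <= alpha,
                           call_clonotype = padj_pb <= alpha)
  ), class = "de_compare")
}

#' @export
print.de_compare <- function(x, ...) {
  cat("<de_compare> ", length(x$sc_genes), " single-cell calls, ",
      length(x$clonotype_genes), " clonotype-replicate calls; unsupported ",
      "fraction ", signif(x$unsupported_fraction, 3), "\n", sep = "")
  invisible(x)
}

#' PCA-style embedding of a gene count matrix
#'
#' log1p counts-per-10k, the `n_top` highest-variance genes, centred, and
#' the top `n_pc` principal components via the gene-gene covariance
#' eigendecomposition (mirroring the usual "top 30 PCs" input to
#' neighbourhood analyses).
#'
#' @param gene_umi sparse/dense cells x genes UMI matrix (or
#'   [counts_triplet()]).
#' @param n_top number of high-variance genes (default 2500).
#' @param n_pc number of components (default 30).
#' @return Numeric matrix, cells x `n_pc`, rownames = cell ids.
#' @export
pca_embedding <- function(gene_umi, n_top = 2500, n_pc = 30) {
  if (inherits(gene_umi, "counts_triplet")) gene_umi <- ct_umi(gene_umi, "gene")
  tot <- pmax(Matrix::rowSums(gene_umi), 1)
  norm <- log1p(as.matrix(gene_umi) / tot * 1e4)
  v <- apply(norm, 2, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_top, ncol(norm)))]
  x <- scale(norm[, keep, drop = FALSE], center = TRUE, scale = FALSE)
  n_pc <- min(n_pc, ncol(x), nrow(x) - 1)
  ev <- eigen(crossprod(x) / (nrow(x) - 1), symmetric = TRUE)
  pcs <- x %*% ev$vectors[, seq_len(n_pc), drop = FALSE]
  colnames(pcs) <- paste0("PC", seq_len(n_pc))
  pcs
}
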