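# small deterministic builders shared across the suite

# cells x guides counts_triplet from dense matrices
toy_guide_triplet <- function(umi, reads = NULL, class = "guide") {
  if (is.null(rownames(umi))) rownames(umi) <- paste0("c", seq_len(nrow(umi)))
  if (is.null(colnames(umi))) colnames(umi) <- paste0("g", seq_len(ncol(umi)))
  if (is.null(reads)) reads <- umi
  dimnames(reads) <- dimnames(umi)
  counts_triplet(Matrix::Matrix(umi, sparse = TRUE),
                 tibble::tibble(feature_id = colnames(umi), class = class),
                 Matrix::Matrix(reads, sparse = TRUE))
}

random_bc <- function(n, len = 17, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# the 26-barcode monoclonal fixture: pairs (1,21), (3,24), (5,22), (20,26)
# co-occur within cells, barcodes 23 and 25 mark undersized groups
bc26_fixture <- function(n_cells_major = 60, n_cells_minor = 40,
                         umi_per_cell = 20, reads_per_umi = 2000) {
  bcs <- random_bc(26, seed = 7)
  pairs <- list(c(1, 21), c(3, 24), c(5, 22), c(20, 26))
  paired <- unlist(pairs)
  small <- c(23, 25)
  groups <- c(pairs,
              as.list(setdiff(seq_len(26), c(paired, small))),
              as.list(small))
  rows <- list(); cell <- 0L
  cell_ids <- character(0)
  for (g in groups) {
    n <- if (any(g %in% small)) n_cells_minor else n_cells_major
    for (i in seq_len(n)) {
      cell <- cell + 1L
      id <- sprintf("cell%05d", cell)
      cell_ids <- c(cell_ids, id)
      rows[[length(rows) + 1]] <- tibble::tibble(cell = id, bc = bcs[g],
                                                 umi = umi_per_cell)
    }
  }
  long <- dplyr::bind_rows(rows)
  umi <- Matrix::sparseMatrix(
    i = match(long$cell, cell_ids), j = match(long$bc, bcs), x = long$umi,
    dims = c(length(cell_ids), 26), dimnames = list(cell_ids, bcs)
  )
  counts_triplet(umi,
                 tibble::tibble(feature_id = bcs, class = "organoid_bc"),
                 umi * reads_per_umi)
}

# gene counts with clonotype-level random effects (EB-to-EB heterogeneity);
# `shift` multiplies given genes in given cells
make_gene_counts <- function(cells, n_genes = 120, clone_sd = 0.5,
                             depth = 2, seed = 1,
                             shift_genes = character(0), shift_cells = character(0),
                             fold = 1) {
  set.seed(seed)
  genes <- sprintf("gene%03d", seq_len(n_genes))
  base <- stats::rlnorm(n_genes, log(depth), 0.8)
  clones <- unique(cells$clonotype_id)
  cfac <- matrix(stats::rlnorm(length(clones) * n_genes, 0, clone_sd),
                 length(clones), n_genes, dimnames = list(clones, genes))
  mu <- t(t(cfac[cells$clonotype_id, , drop = FALSE]) * base)
  if (length(shift_genes) > 0) {
    mu[cells$cell_id %in% shift_cells, shift_genes] <-
      mu[cells$cell_id %in% shift_cells, shift_genes] * fold
  }
  counts <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu),
                   dimnames = list(cells$cell_id, genes))
  Matrix::Matrix(counts, sparse = TRUE)
}

# truth-labelled cell table (one row per cell) from a simulation,
# restricted to single-guide cells
truth_cells <- function(sim) {
  tr <- sim$truth[!grepl(",", sim$truth$guide_id), ]
  lib <- sim$library
  tibble::tibble(
    cell_id = tr$cell_id,
    guide_id = tr$guide_id,
    target_id = lib$target_id[match(tr$guide_id, lib$guide_id)],
    is_ntc = lib$is_ntc[match(tr$guide_id, lib$guide_id)],
    cell_type = tr$cell_type,
    clonotype_id = tr$eb_id
  )
}

# per-cell table from assigned guide calls joined to truth cell types
assigned_cells <- function(sim, rule = "alltf", policy = "alltf_keep") {
  lib <- sim$library
  calls <- assign_guides(sim$counts, rule,
                         ntc_guides = lib$guide_id[lib$is_ntc])
  calls <- resolve_multi_guides(calls, policy)
  one_target <- vapply(calls$guides, function(g) {
    tg <- unique(lib$target_id[match(g, lib$guide_id)])
    if (length(tg) == 1) tg else NA_character_
  }, character(1))
  guide1 <- vapply(calls$guides, function(g) {
    if (length(g) >= 1) g[[1]] else NA_character_
  }, character(1))
  keep <- !is.na(one_target)
  tibble::tibble(
    cell_id = calls$cell_id[keep],
    guide_id = guide1[keep],
    target_id = one_target[keep],
    is_ntc = one_target[keep] == "NTC",
    cell_type = sim$truth$cell_type[match(calls$cell_id[keep],
                                          sim$truth$cell_id)]
  )
}
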