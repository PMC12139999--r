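#' Correct organoid barcodes by abundance and Hamming distance
#'
#' First removes barcode features below both count floors (total UMIs
#' < `min_umi` and total reads < `min_reads`), then merges each surviving
#' low-abundance barcode lying within Hamming distance 1 of exactly one
#' higher-abundance barcode into that barcode (counts summed). A barcode
#' equidistant from two or more candidate parents is left unmerged and
#' reported, rather than guessed.
#'
#' @param counts a [counts_triplet()] with `organoid_bc` features whose ids
#'   are equal-length sequences over \{A,C,G,T\}.
#' @param min_umi,min_reads count floors below which a barcode is removed
#'   (both must fail; defaults 10 and 10).
#' @return A corrected [counts_triplet()] with attributes `merged`
#'   (tibble `from`, `into`) and `ambiguous` (character vector of barcodes
#'   left unmerged because of ties).
#' @export
correct_barcodes <- function(counts, min_umi = 10, min_reads = 10) {
  stopifnot(inherits(counts, "counts_triplet"))
  umi <- ct_umi(counts, "organoid_bc")
  reads <- ct_reads(counts, "organoid_bc")[, colnames(umi), drop = FALSE]
  bcs <- colnames(umi)
  if (length(unique(nchar(bcs))) > 1) {
    stop("organoid barcodes must all have the same length")
  }
  tot_u <- Matrix::colSums(umi)
  tot_r <- Matrix::colSums(reads)
  keep <- !(tot_u < min_umi & tot_r < min_reads)
  bcs <- bcs[keep]
  if (length(bcs) == 0) stop("no organoid barcodes survive the count floors")
  tot_u <- tot_u[bcs]
  # Hamming distance via per-position mismatch counts
  chars <- do.call(rbind, strsplit(bcs, ""))
  hd1 <- function(a, b) sum(chars[a, ] != chars[b, ]) == 1
  ord <- order(tot_u, bcs)   # ascending: try to merge rare into common
  merged_into <- stats::setNames(bcs, bcs)
  merged_log <- list()
  ambiguous <- character()
  for (a in ord) {
    richer <- which(tot_u > tot_u[a])
    if (length(richer) == 0) next
    parents <- richer[vapply(richer, hd1, logical(1), a = a)]
    if (length(parents) == 1) {
      merged_into[bcs[a]] <- bcs[parents]
      merged_log[[length(merged_log) + 1]] <-
        tibble::tibble(from = bcs[a], into = bcs[parents])
    } else if (length(parents) > 1) {
      ambiguous <- c(ambiguous, bcs[a])
    }
  }
  # resolve chains (a -> b -> c) to final parents
  final <- merged_into
  repeat {
    nxt <- merged_into[final]
    if (identical(unname(nxt), unname(final))) break
    final <- nxt
  }
  new_bcs <- sort(unique(unname(final)))
  # sparse member-to-group indicator sums merged columns in one product
  ind <- Matrix::sparseMatrix(i = match(names(final), bcs),
                              j = match(unname(final), new_bcs),
                              x = 1, dims = c(length(bcs), length(new_bcs)),
                              dimnames = list(bcs, new_bcs))
  bc_umi_old <- ct_umi(counts, "organoid_bc")
  umi_new <- bc_umi_old[, bcs, drop = FALSE] %*% ind
  reads_new <- reads[, bcs, drop = FALSE] %*% ind
  keep_feats <- counts$features$feature_id[counts$features$class != "organoid_bc"]
  umi_all <- cbind(counts$umi[, keep_feats, drop = FALSE], umi_new)
  feats <- dplyr::bind_rows(
    counts$features[counts$features$class != "organoid_bc", ],
    tibble::tibble(feature_id = new_bcs, class = "organoid_bc")
  )
  reads_keep <- NULL
  if (!is.null(counts$reads)) {
    old_other_reads <- counts$reads[, setdiff(colnames(counts$reads),
                                              colnames(bc_umi_old)), drop = FALSE]
    reads_keep <- cbind(old_other_reads, reads_new)
  }
  out <- counts_triplet(umi_all, feats, reads_keep)
  attr(out, "merged") <- if (length(merged_log) > 0) dplyr::bind_rows(merged_log)
                         else tibble::tibble(from = character(), into = character())
  attr(out, "ambiguous") <- ambiguous
  out
}

#' Assign organoid barcodes to cells
#'
#' Restricts the barcode universe to barcodes whose log2 total read count
#' reaches `min_log2_reads` (separating true organoid barcodes from noise),
#' then assigns a barcode to a cell iff the cell's UMI count for it is at
#' least `min_umi` and its share of the cell's UMIs over the restricted
#' barcode set is at least `min_prop`.
#'
#' @param counts a (corrected) [counts_triplet()] with `organoid_bc`
#'   features.
#' @param min_log2_reads log2 total-read floor for the barcode universe
#'   (default 15; sci-RNA-seq-style data uses 10).
#' @param min_umi per-cell UMI floor (default 10).
#' @param min_prop per-cell UMI proportion floor (default 0.30).
#' @return Tibble `cell_id`, `bc`, `umi`, `prop`, one row per assignment,
#'   with attributes `selected_bcs` (the restricted universe) and `cells`
#'   (all cell ids, so unassigned cells are recoverable).
#' @export
assign_bcs_to_cells <- function(counts, min_log2_reads = 15, min_umi = 10,
                                min_prop = 0.30) {
  stopifnot(inherits(counts, "counts_triplet"))
  umi <- ct_umi(counts, "organoid_bc")
  reads <- ct_reads(counts, "organoid_bc")[, colnames(umi), drop = FALSE]
  sel <- colnames(umi)[log2(Matrix::colSums(reads)) >= min_log2_reads]
  umi <- umi[, sel, drop = FALSE]
  cell_tot <- Matrix::rowSums(umi)
  tu <- Matrix::summary(umi)
  prop <- tu$x / cell_tot[tu$i]
  ok <- tu$x >= min_umi & prop >= min_prop
  out <- tibble::tibble(cell_id = rownames(umi)[tu$i[ok]],
                        bc = colnames(umi)[tu$j[ok]],
                        umi = tu$x[ok], prop = prop[ok]) |>
    dplyr::arrange(match(.data$cell_id, rownames(umi)), .data$bc)
  attr(out, "selected_bcs") <- sel
  attr(out, "cells") <- rownames(umi)
  out
}

#' Merge correlated organoid barcodes
#'
#' Cells without assigned barcodes are excluded; each remaining cell's UMI
#' vector over the selected barcodes is normalised by the cell total and
#' each barcode column standardised (zero mean, unit variance) before
#' pairwise Pearson correlation over cells. Cells assigned multiple
#' barcodes are excluded unless every pair among their barcodes correlates
#' above `r_threshold`, in which case those pairs are merged (these are
#' EBs founded by a cell with multiple integrations, whose barcodes
#' co-occur). Merging is closed transitively so the result partitions the
#' barcodes.
#'
#' @param counts the [counts_triplet()] used for [assign_bcs_to_cells()].
#' @param assignments the tibble returned by [assign_bcs_to_cells()].
#' @param r_threshold correlation threshold for merging (default 0.1).
#' @return List: `groups` (tibble `bc`, `group_id`), `cells` (tibble
#'   `cell_id`, `group_id`; multi-barcode cells that failed the correlation
#'   rule appear with `NA`), `correlations` (the barcode correlation
#'   matrix), `zero_variance` (barcodes with undefined correlations, never
#'   merged).
#' @export
merge_correlated_bcs <- function(counts, assignments, r_threshold = 0.1) {
  sel <- attr(assignments, "selected_bcs")
  stopifnot(!is.null(sel))
  umi <- ct_umi(counts, "organoid_bc")[, sel, drop = FALSE]
  assigned_cells <- unique(assignments$cell_id)
  m <- as.matrix(umi[assigned_cells, , drop = FALSE])
  m <- m / pmax(rowSums(m), 1)
  sdv <- apply(m, 2, stats::sd)
  zero_var <- colnames(m)[sdv == 0 | is.na(sdv)]
  cm <- suppressWarnings(stats::cor(m))
  # union-find over barcodes
  parent <- stats::setNames(seq_along(sel), sel)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  per_cell <- split(assignments$bc, assignments$cell_id)
  multi <- per_cell[lengths(per_cell) > 1]
  cell_ok <- stats::setNames(rep(TRUE, length(per_cell)), names(per_cell))
  for (cell in names(multi)) {
    b <- multi[[cell]]
    prs <- utils::combn(b, 2)
    r_ok <- apply(prs, 2, function(p) {
      if (p[1] %in% zero_var || p[2] %in% zero_var) return(FALSE)
      isTRUE(cm[p[1], p[2]] > r_threshold)
    })
    if (all(r_ok)) {
      apply(prs, 2, function(p) unite(match(p[1], sel), match(p[2], sel)))
    } else {
      cell_ok[cell] <- FALSE
    }
  }
  root <- vapply(seq_along(sel), find, numeric(1))
  group_id <- paste0("bcgrp_", match(root, sort(unique(root))))
  groups <- tibble::tibble(bc = sel, group_id = group_id)
  cell_groups <- tibble::tibble(
    cell_id = names(per_cell),
    group_id = vapply(seq_along(per_cell), function(k) {
      if (!cell_ok[k]) return(NA_character_)
      g <- unique(groups$group_id[match(per_cell[[k]], groups$bc)])
      if (length(g) == 1) g else NA_character_
    }, character(1))
  )
  list(groups = groups, cells = cell_groups, correlations = cm,
       zero_variance = zero_var)
}

#' Call clonotypes from merged barcode groups
#'
#' Cells are grouped by their unique-or-merged barcode group; groups with
#' fewer than `min_cells` cells are dropped (their cells become
#' unassigned). Remaining clonotypes are numbered by descending size, ties
#' broken by the lexicographically smallest member barcode, so ids are
#' stable across reruns.
#'
#' @param merged result of [merge_correlated_bcs()].
#' @param min_cells minimum cells per clonotype (default 50).
#' @param all_cells optional character vector of every profiled cell id, so
#'   that cells without any assigned barcode are reported with status
#'   `no_bc` instead of being silently absent.
#' @return A tibble of class `clonotype_map`: `clonotype_id`, `bcs` (list),
#'   `n_cells`, `cell_ids` (list); attribute `cells` holds a per-cell
#'   tibble (`cell_id`, `clonotype_id`, `status` in
#'   `assigned`/`too_small`/`ambiguous_multi_bc`/`no_bc`).
#' @export
call_clonotypes <- function(merged, min_cells = 50, all_cells = NULL) {
  cg <- merged$cells
  ok <- !is.na(cg$group_id)
  grp <- split(cg$cell_id[ok], cg$group_id[ok])
  sizes <- lengths(grp)
  bcs_of <- split(merged$groups$bc, merged$groups$group_id)
  first_bc <- vapply(bcs_of, function(b) min(b), character(1))[names(grp)]
  keep <- names(grp)[sizes >= min_cells]
  ord <- keep[order(-sizes[keep], first_bc[keep])]
  map <- tibble::tibble(
    clonotype_id = paste0("clonotype_", seq_along(ord)),
    bcs = unname(bcs_of[ord]),
    n_cells = unname(sizes[ord]),
    cell_ids = unname(grp[ord])
  )
  status <- tibble::tibble(cell_id = cg$cell_id)
  cl_of <- stats::setNames(rep(map$clonotype_id, map$n_cells),
                           unlist(map$cell_ids))
  status$clonotype_id <- unname(cl_of[status$cell_id])
  status$status <- dplyr::case_when(
    !is.na(status$clonotype_id) ~ "assigned",
    is.na(cg$group_id) ~ "ambiguous_multi_bc",
    TRUE ~ "too_small"
  )
  if (!is.null(all_cells)) {
    extra <- setdiff(all_cells, status$cell_id)
    status <- dplyr::bind_rows(status, tibble::tibble(
      cell_id = extra, clonotype_id = NA_character_, status = "no_bc"
    ))
  }
  class(map) <- c("clonotype_map", class(map))
  attr(map, "cells") <- status
  map
}

#' Assign a guide RNA to each clonotype from direct-capture counts
#'
#' Eligible cells are those whose total guide UMIs reach `cell_umi_floor`;
#' clonotypes with fewer than `min_eligible_cells` eligible cells are
#' discarded. Within each remaining clonotype the per-cell guide UMI
#' proportions are averaged; if one guide's mean proportion exceeds
#' `unique_threshold` the clonotype gets a unique assignment, otherwise its
#' top two guides are retained as a double assignment.
#'
#' @param map a `clonotype_map` from [call_clonotypes()].
#' @param counts a [counts_triplet()] with guide features (direct capture).
#' @param min_eligible_cells minimum eligible cells (default 10).
#' @param cell_umi_floor per-cell total guide UMI floor (default 10).
#' @param unique_threshold mean-proportion threshold for a unique call
#'   (default 0.70, strict).
#' @return The `clonotype_map` with columns `guide_call` (list of guide
#'   ids), `call_class` (`unique`/`double`/`discarded`) and `mean_props`
#'   (list of named mean proportion vectors).
#' @export
assign_guide_to_clonotype <- function(map, counts, min_eligible_cells = 10,
                                      cell_umi_floor = 10,
                                      unique_threshold = 0.70) {
  stopifnot(inherits(map, "clonotype_map"), inherits(counts, "counts_triplet"))
  umi <- ct_umi(counts, "guide")
  tot <- Matrix::rowSums(umi)
  res <- lapply(seq_len(nrow(map)), function(k) {
    cells <- intersect(map$cell_ids[[k]], rownames(umi))
    cells <- cells[tot[cells] >= cell_umi_floor]
    if (length(cells) < min_eligible_cells) {
      return(list(call = character(0), class = "discarded",
                  props = stats::setNames(numeric(0), character(0))))
    }
    props <- umi[cells, , drop = FALSE] / tot[cells]
    mp <- Matrix::colMeans(props)
    mp <- sort(mp[mp > 0], decreasing = TRUE)
    if (length(mp) >= 1 && mp[1] > unique_threshold) {
      list(call = names(mp)[1], class = "unique", props = mp)
    } else {
      list(call = names(mp)[seq_len(min(2, length(mp)))], class = "double",
           props = mp)
    }
  })
  map$guide_call <- lapply(res, `[[`, "call")
  map$call_class <- vapply(res, `[[`, character(1), "class")
  map$mean_props <- lapply(res, `[[`, "props")
  map
}

#' Run the full organoid-barcode clonotype pipeline
#'
#' Chains [correct_barcodes()], [assign_bcs_to_cells()],
#' [merge_correlated_bcs()], [call_clonotypes()] and
#' [assign_guide_to_clonotype()] with their standard thresholds.
#'
#' @param counts a [counts_triplet()] with `organoid_bc` (and, for guide
#'   calling, `guide`) features.
#' @param min_log2_reads,min_umi,min_prop,r_threshold,min_cells
#'   thresholds passed to the component steps.
#' @param guide_calls if `TRUE` (default) and guide features exist, also
#'   assign guides to clonotypes.
#' @param ... passed to [assign_guide_to_clonotype()].
#' @return List: `map` (the `clonotype_map`), `assignments`, `merged`,
#'   `corrected`.
#' @export
run_clonotype_pipeline <- function(counts, min_log2_reads = 15, min_umi = 10,
                                   min_prop = 0.30, r_threshold = 0.1,
                                   min_cells = 50, guide_calls = TRUE, ...) {
  corrected <- correct_barcodes(counts)
  assignments <- assign_bcs_to_cells(corrected, min_log2_reads = min_log2_reads,
                                     min_umi = min_umi, min_prop = min_prop)
  merged <- merge_correlated_bcs(corrected, assignments,
                                 r_threshold = r_threshold)
  map <- call_clonotypes(merged, min_cells = min_cells,
                         all_cells = attr(assignments, "cells"))
  if (guide_calls && any(counts$features$class == "guide")) {
    map <- assign_guide_to_clonotype(map, counts, ...)
  }
  list(map = map, assignments = assignments, merged = merged,
       corrected = corrected)
}

#' Summarise a clonotype map as a flat tibble
#'
#' @param x a `clonotype_map`.
#' @param ... unused.
#' @return Tibble with comma-joined barcode and guide columns.
#' @method tidy clonotype_map
#' @export
tidy.clonotype_map <- function(x, ...) {
  tibble::tibble(
    clonotype_id = x$clonotype_id,
    bcs = vapply(x$bcs, paste, character(1), collapse = ","),
    n_cells = x$n_cells,
    guide_call = if ("guide_call" %in% names(x)) {
      vapply(x$guide_call, paste, character(1), collapse = ",")
    } else NA_character_,
    call_class = if ("call_class" %in% names(x)) x$call_class else NA_character_
  )
}
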