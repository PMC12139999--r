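#' Assign guide RNAs to cells from UMI and read counts
#'
#' Two threshold rules, named after the screens that used them. Writing
#' `u` for a cell's UMI count of a guide and `r` for its read count:
#' * `pilot`: assigned iff `log2(u + 1) >= 2` and `log2(r + 1) >= 5`.
#' * `alltf`: assigned iff `log2(u + 1) >= 2` and
#'   `log2(u + 1) < 1.25 * log2(r + 1) - 5`
#'   (guards against chimeric high-UMI/low-read artefacts).
#'
#' Comparisons are exactly as printed: `>=` inclusive, `<` strict. Cells
#' with no guide passing are `unassigned`, never an error.
#'
#' @param counts a [counts_triplet()] whose guide features carry both UMI
#'   and read counts.
#' @param rule `"pilot"` or `"alltf"`.
#' @param ntc_guides character vector of non-targeting guide ids (used only
#'   to label the per-cell status).
#' @return Tibble of class `guide_calls`: `cell_id`, `guides` (list column
#'   of assigned guide ids), `status` (`unique_tf`, `multi_tf`, `ntc`,
#'   `unassigned`).
#' @export
assign_guides <- function(counts, rule = c("pilot", "alltf"),
                          ntc_guides = character()) {
  rule <- match.arg(rule)
  stopifnot(inherits(counts, "counts_triplet"))
  umi <- ct_umi(counts, "guide")
  reads <- ct_reads(counts, "guide")
  reads <- reads[, colnames(umi), drop = FALSE]
  tu <- Matrix::summary(umi)
  # reads share the sparsity pattern wherever umi > 0
  r <- reads[cbind(tu$i, tu$j)]
  lu <- log2(tu$x + 1)
  lr <- log2(r + 1)
  ok <- if (rule == "pilot") lu >= 2 & lr >= 5 else lu >= 2 & lu < 1.25 * lr - 5
  hits <- tibble::tibble(cell = rownames(umi)[tu$i[ok]],
                         guide = colnames(umi)[tu$j[ok]])
  per_cell <- split(hits$guide, factor(hits$cell, levels = rownames(umi)))
  calls <- tibble::tibble(cell_id = rownames(umi),
                          guides = unname(lapply(per_cell, as.character)))
  calls$status <- guide_status(calls$guides, ntc_guides)
  class(calls) <- c("guide_calls", class(calls))
  attr(calls, "ntc_guides") <- ntc_guides
  calls
}

guide_status <- function(guide_sets, ntc_guides) {
  vapply(guide_sets, function(g) {
    if (length(g) == 0) return("unassigned")
    tf <- setdiff(g, ntc_guides)
    if (length(tf) == 0) return("ntc")
    if (length(tf) == 1 && length(g) == 1) return("unique_tf")
    "multi_tf"
  }, character(1))
}

#' Resolve cells assigned multiple guides
#'
#' * `pilot_strict`: only single-guide cells survive; any other assigned set
#'   becomes `unassigned` (the pilot screen's single-gRNA rule).
#' * `alltf_keep`: when a cell carries both targeting and NTC guides the
#'   NTCs are dropped; multiple targeting guides are all retained
#'   (`multi_tf`); cells with only NTC guides stay `ntc`.
#'
#' @param calls a `guide_calls` tibble from [assign_guides()].
#' @param policy `"pilot_strict"` or `"alltf_keep"`.
#' @param ntc_guides non-targeting guide ids; defaults to the set recorded
#'   by [assign_guides()].
#' @return A `guide_calls` tibble with updated `guides` and `status`.
#' @export
resolve_multi_guides <- function(calls, policy = c("pilot_strict", "alltf_keep"),
                                 ntc_guides = NULL) {
  policy <- match.arg(policy)
  stopifnot(inherits(calls, "guide_calls"))
  if (is.null(ntc_guides)) ntc_guides <- attr(calls, "ntc_guides") %||% character()
  out <- calls
  if (policy == "pilot_strict") {
    out$guides <- lapply(calls$guides, function(g) {
      if (length(g) == 1) g else character(0)
    })
  } else {
    out$guides <- lapply(calls$guides, function(g) {
      tf <- setdiff(g, ntc_guides)
      if (length(tf) > 0) tf else g
    })
  }
  out$status <- guide_status(out$guides, ntc_guides)
  attr(out, "ntc_guides") <- ntc_guides
  out
}

#' Remove guide features detected in too few cells
#'
#' Guides with nonzero UMIs in fewer than `min_cell_fraction` of cells are
#' dropped (they typically derive from single floating cells in the medium
#' rather than from EBs). Other features are untouched.
#'
#' @param counts a [counts_triplet()].
#' @param min_cell_fraction prevalence threshold (default 0.01); guides
#'   present in `< min_cell_fraction * n_cells` cells are removed.
#' @return A [counts_triplet()] without the low-prevalence guide features.
#' @export
filter_guides_prevalence <- function(counts, min_cell_fraction = 0.01) {
  stopifnot(inherits(counts, "counts_triplet"),
            min_cell_fraction >= 0, min_cell_fraction < 1)
  umi <- ct_umi(counts, "guide")
  prevalence <- Matrix::colSums(umi > 0)
  drop <- colnames(umi)[prevalence < min_cell_fraction * nrow(umi)]
  keep <- setdiff(counts$features$feature_id, drop)
  ct_subset(counts, features = keep)
}
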