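#' Filter cells on standard quality-control metrics
#'
#' Applies the per-cell filters used throughout droplet EB screens: minimum
#' total UMI, removal of cells exceeding the top `top_umi_quantile` of UMI
#' counts (likely multiplets), Scrublet-style doublet score, mitochondrial
#' and ribosomal read percentages. Doublet scores are consumed, never
#' computed. A cell is removed iff it violates at least one rule, and every
#' removed cell carries the list of rules it violated; the function is
#' order-independent and idempotent on the retained set.
#'
#' The top-UMI rule removes cells strictly above the inverse-ECDF
#' (type-1) `1 - top_umi_quantile` quantile, so on distinct values exactly
#' `floor(n * top_umi_quantile)` cells go.
#'
#' @param metrics data frame with columns `cell_id`, `total_umi`,
#'   `doublet_score`, `pct_mt`, `pct_ribo` (percentages in 0-100,
#'   doublet score in 0-1).
#' @param min_umi minimum total UMI (default 2000; cells with fewer are
#'   removed).
#' @param top_umi_quantile top fraction of cells by UMI to remove
#'   (default 0.005).
#' @param max_doublet maximum doublet score (default 0.2; strictly greater
#'   removed).
#' @param max_mt,max_ribo maximum MT% / Ribo% (defaults 20 and 40; strictly
#'   greater removed).
#' @return Tibble `cell_id`, `keep`, `reasons` (comma-joined rule names,
#'   `NA` for kept cells), one row per input cell in input order.
#' @export
filter_cells_qc <- function(metrics, min_umi = 2000, top_umi_quantile = 0.005,
                            max_doublet = 0.2, max_mt = 20, max_ribo = 40) {
  if (is.null(metrics) || nrow(metrics) == 0) stop("`metrics` is empty")
  needed <- c("cell_id", "total_umi", "doublet_score", "pct_mt", "pct_ribo")
  miss <- setdiff(needed, names(metrics))
  if (length(miss) > 0) {
    stop("missing metric column(s): ", paste(miss, collapse = ", "))
  }
  stopifnot(is.finite(min_umi), is.finite(top_umi_quantile),
            is.finite(max_doublet), is.finite(max_mt), is.finite(max_ribo))
  umi_cut <- stats::quantile(metrics$total_umi, 1 - top_umi_quantile,
                             type = 1, names = FALSE)
  rules <- list(
    min_umi = metrics$total_umi < min_umi,
    top_umi = metrics$total_umi > umi_cut,
    doublet = metrics$doublet_score > max_doublet,
    mt = metrics$pct_mt > max_mt,
    ribo = metrics$pct_ribo > max_ribo
  )
  hit <- do.call(cbind, rules)
  reasons <- apply(hit, 1, function(z) {
    if (!any(z)) NA_character_ else paste(names(rules)[z], collapse = ",")
  })
  tibble::tibble(cell_id = metrics$cell_id, keep = !rowSums(hit) > 0,
                 reasons = reasons)
}

#' Load an organoid-barcode-to-guide lookup table
#'
#' Reads a TSV whose first two columns are a barcode key (the full organoid
#' barcode, or its fixed guide-identifying prefix) and a guide id. Duplicate
#' identical rows collapse to one entry; a key claimed by two different
#' guides is excluded from the mapping and reported in the ambiguity table,
#' keeping the mapping a function.
#'
#' @param path TSV file; lines starting `#` are skipped. A header line is
#'   detected when the first field is `key`, `bc` or `barcode`.
#' @param provenance `"sequenced"` (pairing read off a plasmid library) or
#'   `"predefined"` (fixed-prefix scheme).
#' @return Tibble `key`, `guide_id`, `provenance` of class `lookup_table`
#'   with attribute `ambiguous`: tibble of dropped keys and their claimed
#'   guides.
#' @export
load_lookup_table <- function(path, provenance = c("sequenced", "predefined")) {
  provenance <- match.arg(provenance)
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(parts) > 0 &&
      tolower(parts[[1]][1]) %in% c("key", "bc", "barcode")) {
    parts <- parts[-1]; rows <- rows[-1]
  }
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    stop("malformed lookup row (need >= 2 tab-separated fields) at line ",
         rows[bad[1]])
  }
  key <- vapply(parts, `[[`, character(1), 1)
  guide <- vapply(parts, `[[`, character(1), 2)
  if (any(!grepl("^[ACGT]+$", key))) {
    stop("lookup keys must be sequences over {A,C,G,T}; offending line ",
         rows[which(!grepl("^[ACGT]+$", key))[1]])
  }
  tab <- dplyr::distinct(tibble::tibble(key = key, guide_id = guide))
  dup <- tab$key[duplicated(tab$key)]
  ambiguous <- dplyr::filter(tab, .data$key %in% dup) |>
    dplyr::arrange(.data$key, .data$guide_id)
  tab <- dplyr::filter(tab, !.data$key %in% dup)
  tab$provenance <- provenance
  structure(tab, ambiguous = ambiguous,
            class = c("lookup_table", class(tab)))
}

#' Lookup table from a library design's fixed prefixes
#'
#' @param library a [library_design()].
#' @return A `lookup_table` mapping each guide's fixed barcode prefix to the
#'   guide id (bijective by design).
#' @export
lookup_from_design <- function(library) {
  stopifnot(inherits(library, "library_design"))
  tab <- tibble::tibble(key = library$bc_prefix, guide_id = library$guide_id,
                        provenance = "predefined")
  structure(tab, ambiguous = tab[0, c("key", "guide_id")],
            class = c("lookup_table", class(tab)))
}
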