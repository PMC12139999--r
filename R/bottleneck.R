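#' Deduplicate amplicon reads by UMI
#'
#' Collapses read-level records to molecule counts: each guide's count is
#' the number of distinct (UMI, guide) pairs, so PCR duplicates of one
#' template collapse while the same UMI sequence attached to different
#' guides still counts once per guide. Records whose UMI is not a fixed-
#' length A/C/G/T string are skipped and counted.
#'
#' @param reads data frame with columns `umi` and `guide_id`, one row per
#'   read.
#' @return Tibble `guide_id`, `n_umi`, with attribute `n_skipped`.
#' @export
dedup_reads_by_umi <- function(reads) {
  stopifnot(all(c("umi", "guide_id") %in% names(reads)))
  len <- stats::median(nchar(reads$umi))
  ok <- grepl("^[ACGT]+$", reads$umi) & nchar(reads$umi) == len
  skipped <- sum(!ok)
  out <- tibble::as_tibble(reads[ok, c("umi", "guide_id")]) |>
    dplyr::distinct() |>
    dplyr::count(.data$guide_id, name = "n_umi") |>
    dplyr::arrange(.data$guide_id)
  attr(out, "n_skipped") <- skipped
  out
}

#' Clonal complexity of a per-guide count vector
#'
#' Ranks guides by abundance (ties broken by guide id for determinism) and
#' reports the metrics used to diagnose clonal bottlenecks in individual
#' EBs: the number of distinct guides, the cumulative abundance curve, the
#' minimal number of top guides covering a fraction `f` of counts (the
#' "dominance" count; jackpotted EBs have 2-10 at f = 0.9), and the ratio
#' of the top guide to the median detected guide.
#'
#' @param counts named numeric vector of per-guide counts, or a data frame
#'   with `guide_id` and a count column (`count`, `reads`, `umi` or
#'   `n_umi`).
#' @param f coverage fraction for the dominance count (default 0.9).
#' @return Object of class `clonal_complexity`: `n_distinct`, `dominance`,
#'   `top_to_median_ratio`, `f`, and `curve` (tibble `rank`, `guide_id`,
#'   `count`, `cum_fraction`).
#' @export
clonal_complexity <- function(counts, f = 0.9) {
  if (is.data.frame(counts)) {
    col <- intersect(c("count", "reads", "umi", "n_umi"), names(counts))[1]
    if (is.na(col)) stop("no count column found")
    counts <- stats::setNames(counts[[col]], counts$guide_id)
  }
  stopifnot(f > 0, f <= 1)
  if (any(counts < 0)) stop("counts must be non-negative")
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("all counts are zero")
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  cum <- cumsum(counts) / sum(counts)
  dominance <- unname(which(cum >= f)[1])
  structure(list(
    n_distinct = length(counts),
    dominance = dominance,
    top_to_median_ratio = unname(counts[1] / stats::median(counts)),
    f = f,
    curve = tibble::tibble(rank = seq_along(counts),
                           guide_id = names(counts),
                           count = unname(counts),
                           cum_fraction = unname(cum))
  ), class = "clonal_complexity")
}

#' @export
print.clonal_complexity <- function(x, ...) {
  cat("<clonal_complexity> ", x$n_distinct, " guides; top ", x$dominance,
      " cover ", round(100 * x$f), "% of counts; top/median ratio ",
      signif(x$top_to_median_ratio, 3), "\n", sep = "")
  invisible(x)
}

#' Per-EB clonal complexity reports
#'
#' Convenience wrapper applying [clonal_complexity()] to each EB of a
#' per-EB guide count table (e.g. from [eb_guide_counts()]).
#'
#' @param eb_counts tibble with `eb_id`, `guide_id` and a count column.
#' @param f coverage fraction (default 0.9).
#' @param count_col which column to rank on (default `"reads"`).
#' @return Tibble `eb_id`, `n_distinct`, `dominance`,
#'   `top_to_median_ratio`.
#' @export
eb_clonal_complexity <- function(eb_counts, f = 0.9, count_col = "reads") {
  stopifnot(all(c("eb_id", "guide_id", count_col) %in% names(eb_counts)))
  eb_counts |>
    dplyr::group_by(.data$eb_id) |>
    dplyr::group_modify(function(d, key) {
      cc <- clonal_complexity(stats::setNames(d[[count_col]], d$guide_id), f)
      tibble::tibble(n_distinct = cc$n_distinct, dominance = cc$dominance,
                     top_to_median_ratio = cc$top_to_median_ratio)
    }) |>
    dplyr::ungroup()
}

#' Log2 fold change of guide frequencies against a reference library
#'
#' Adds `pseudocount` to every raw count, renormalises both vectors to
#' proportions and reports `log2(sample / reference)` per guide, so guides
#' that drop out of the sample get strongly negative but finite values.
#'
#' @param sample_counts,ref_counts named numeric vectors of raw counts over
#'   the same guide universe.
#' @param pseudocount added to each raw count before renormalisation
#'   (default 0.5).
#' @return Tibble `guide_id`, `sample_prop`, `ref_prop`, `log2fc`.
#' @export
guide_log2fc <- function(sample_counts, ref_counts, pseudocount = 0.5) {
  if (!setequal(names(sample_counts), names(ref_counts))) {
    diff <- c(setdiff(names(sample_counts), names(ref_counts)),
              setdiff(names(ref_counts), names(sample_counts)))
    stop("guide universes differ: ", paste(diff, collapse = ", "))
  }
  ref_counts <- ref_counts[names(sample_counts)]
  sp <- (sample_counts + pseudocount) / sum(sample_counts + pseudocount)
  rp <- (ref_counts + pseudocount) / sum(ref_counts + pseudocount)
  tibble::tibble(guide_id = names(sample_counts),
                 sample_prop = unname(sp), ref_prop = unname(rp),
                 log2fc = unname(log2(sp) - log2(rp)))
}
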