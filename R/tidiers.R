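#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a composition screen result
#'
#' @param x a `screen_test` from [screen_composition()].
#' @param ... unused.
#' @return Per-unit tibble: targets and NTC groups with statistics,
#'   p-values and the empirical significance flag.
#' @method tidy screen_test
#' @export
tidy.screen_test <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$targets, unit = "target", .before = 1),
    x$ntc_groups |>
      dplyr::transmute(unit = "ntc_group", target_id = .data$group_id,
                       n_cells = .data$n_cells, statistic = .data$statistic,
                       df = x$targets$df[1] %||% NA_real_,
                       p_value = .data$p_value,
                       significant = .data$p_value < x$cutoff)
  )
}

#' @rdname tidy.screen_test
#' @method glance screen_test
#' @export
glance.screen_test <- function(x, ...) {
  tibble::tibble(
    n_targets = nrow(x$targets),
    n_ntc_groups = nrow(x$ntc_groups),
    cutoff = x$cutoff,
    q = x$q,
    n_significant = sum(x$targets$significant),
    frac_significant = mean(x$targets$significant),
    frac_nominal = mean(x$targets$p_value < x$q),
    clonotype_aware = x$clonotype_aware
  )
}

#' QQ plot of a composition screen
#'
#' Observed versus expected -log10 p-values for targets and NTC groups,
#' with the empirical significance cutoff; inflation of both series above
#' the diagonal is the signature of clonally confounded mosaic screens.
#'
#' @param object a `screen_test`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot screen_test
#' @export
autoplot.screen_test <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::group_by(.data$unit) |>
    dplyr::arrange(.data$p_value, .by_group = TRUE) |>
    dplyr::mutate(expected = -log10(stats::ppoints(dplyr::n())),
                  observed = -log10(pmax(.data$p_value, 1e-300))) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(.data$expected, .data$observed,
                                  colour = .data$unit)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(object$cutoff), linetype = 3) +
    ggplot2::labs(x = "expected -log10 p", y = "observed -log10 p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy a clonotype fraction test
#'
#' @param x a `fraction_test`.
#' @param ... unused.
#' @return One-row tibble of the test, or set `fractions = TRUE` for the
#'   per-clonotype fractions.
#' @param fractions return the per-clonotype fractions instead.
#' @method tidy fraction_test
#' @export
tidy.fraction_test <- function(x, fractions = FALSE, ...) {
  if (fractions) return(x$fractions)
  tibble::tibble(target = x$target, ntc = x$ntc, cell_type = x$cell_type,
                 statistic = x$statistic, p_value = x$p_value,
                 method = x$method)
}

#' Boxplot of per-clonotype fractions
#'
#' @param object a `fraction_test`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot fraction_test
#' @export
autoplot.fraction_test <- function(object, ...) {
  ggplot2::ggplot(object$fractions,
                  ggplot2::aes(.data$group, .data$fraction)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::labs(y = paste("fraction of cells:", object$cell_type),
                  x = NULL,
                  subtitle = paste0("Wilcoxon p = ", signif(object$p_value, 3))) +
    ggplot2::theme_minimal()
}

#' Cumulative guide-abundance curve of an EB
#'
#' @param object a `clonal_complexity` report.
#' @param ... unused.
#' @return A ggplot object (rank on a log2 axis, as these curves are
#'   usually drawn).
#' @method autoplot clonal_complexity
#' @export
autoplot.clonal_complexity <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(.data$rank, .data$cum_fraction)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$f, linetype = 3) +
    ggplot2::geom_vline(xintercept = object$dominance, linetype = 3) +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "guides ranked by abundance",
                  y = "cumulative fraction of counts") +
    ggplot2::theme_minimal()
}

#' @method tidy clonal_complexity
#' @export
tidy.clonal_complexity <- function(x, ...) {
  tibble::tibble(n_distinct = x$n_distinct, dominance = x$dominance,
                 f = x$f, top_to_median_ratio = x$top_to_median_ratio)
}

#' Heatmap of reciprocal NNLS correspondence
#'
#' @param object a `correspondence` tibble from [nnls_correspondence()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot correspondence
#' @export
autoplot.correspondence <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$type_b, .data$type_a,
                                       fill = .data$combined)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "dataset B", y = "dataset A", fill = "combined beta") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method tidy de_compare
#' @export
tidy.de_compare <- function(x, ...) x$table

#' @method glance de_compare
#' @export
glance.de_compare <- function(x, ...) {
  tibble::tibble(n_sc = length(x$sc_genes),
                 n_clonotype = length(x$clonotype_genes),
                 n_unsupported = length(x$unsupported_genes),
                 unsupported_fraction = x$unsupported_fraction)
}
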