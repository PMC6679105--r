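# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_col geom_point geom_boxplot geom_line
#'   geom_tile facet_wrap labs scale_fill_viridis_c theme_minimal
NULL

#' Peak-month barplot of detected SeMCs
#'
#' @param object A `semc_result`.
#' @param ... Unused.
#' @return A ggplot: number of SeMCs peaking in each month, per context.
#' @method autoplot semc_result
#' @export
autoplot.semc_result <- function(object, ...) {
  d <- object$calls |>
    filter(.data$is_semc) |>
    count(.data$context, .data$peak_month) |>
    mutate(peak_month = factor(.data$peak_month, levels = month.name))
  ggplot(d, aes(x = .data$peak_month, y = .data$n)) +
    geom_col() +
    facet_wrap(~context, scales = "free_y") +
    labs(x = "peak month", y = "SeMCs") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Windowed methylation level against repeat density
#'
#' @param profiles Output of [window_profiles()].
#' @param date Sampling date to show.
#' @return A ggplot: one point per window, faceted by context.
#' @export
plot_window_levels <- function(profiles, date) {
  d <- filter(profiles, .data$date == as.Date(!!date), !is.na(.data$level))
  ggplot(d, aes(x = .data$repeat_density, y = .data$level)) +
    geom_point(alpha = 0.5) +
    facet_wrap(~context) +
    labs(x = "repeat density", y = "methylation level") +
    theme_minimal()
}

#' Seasonal ratio heatmap of SeMCs in cluster order
#'
#' @param x A `semc_result`.
#' @param clustering Optional `semc_clustering` providing the row order.
#' @param max_rows Cap on rows shown.
#' @return A ggplot tile heatmap (rows = SeMCs, columns = dates).
#' @export
plot_semc_heatmap <- function(x, clustering = NULL, max_rows = 2000) {
  keep <- which(x$calls$is_semc)
  mat <- x$ratios[keep, , drop = FALSE]
  if (!is.null(clustering)) {
    lab <- paste(x$calls$seq_id[keep], x$calls$pos[keep],
                 x$calls$strand[keep], sep = ":")
    ord <- match(clustering$labels[clustering$order], lab)
    ord <- ord[!is.na(ord)]
    mat <- mat[ord, , drop = FALSE]
  }
  if (nrow(mat) > max_rows) mat <- mat[seq_len(max_rows), , drop = FALSE]
  d <- tibble(row = rep(seq_len(nrow(mat)), ncol(mat)),
              date = rep(x$dates, each = nrow(mat)),
              ratio = as.vector(mat))
  ggplot(d, aes(x = factor(.data$date), y = .data$row, fill = .data$ratio)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = "date", y = NULL, fill = "ratio") +
    theme_minimal()
}

#' Expression average / range across gbM quintile bins
#'
#' @param bins Output of [quintile_bins()].
#' @param what `"range"` or `"average"`.
#' @return A ggplot boxplot by bin.
#' @export
plot_bin_distribution <- function(bins, what = c("range", "average")) {
  what <- match.arg(what)
  ggplot(bins, aes(x = factor(.data$bin), y = .data[[what]])) +
    geom_boxplot() +
    labs(x = "gbM quintile (1 = lowest)", y = paste("seasonal", what)) +
    theme_minimal()
}

#' Paired feature methylation and gene expression across dates
#'
#' @param fa Output of [feature_association()].
#' @return A ggplot with both series over time (expression on a secondary
#'   scale would hide the anti-phase; both are shown rescaled to `[0, 1]`).
#' @export
plot_feature_association <- function(fa) {
  rescale01 <- function(x) {
    if (max(x) == min(x)) return(rep(0.5, length(x)))
    (x - min(x)) / (max(x) - min(x))
  }
  d <- fa$table |>
    mutate(methylation = rescale01(.data$level),
           expression = rescale01(.data$expr)) |>
    pivot_longer(c("methylation", "expression"),
                 names_to = "series", values_to = "value")
  ggplot(d, aes(x = .data$date, y = .data$value, colour = .data$series)) +
    geom_line() + geom_point() +
    labs(x = NULL, y = "rescaled value", colour = NULL) +
    theme_minimal()
}
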