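# Gene-body CG methylation and its association with the seasonal average and
# range of RNA expression.

#' Gene-body methylation per gene
#'
#' Pools methylation of all sites of `context` within each gene body (full
#' annotated span, introns included, unless `exon_only`) per date, then
#' averages the per-date pooled levels across dates. Genes without any site
#' of the context, or without coverage at any date, are excluded with a
#' message.
#'
#' @param series A `methylome_series`.
#' @param annotation A [genome_annotation()].
#' @param context Context to pool (default CG; gene-body methylation is a CG
#'   phenomenon).
#' @param exon_only Restrict to exons instead of the full gene span.
#' @param per_date Return the per-date pooled levels (long tibble) instead of
#'   the across-date mean, so seasonal stability of gbM can be inspected.
#' @return Tibble `gene_id`, `gbm`, `n_sites`; or `gene_id`, `date`, `level`,
#'   `n_sites` when `per_date`.
#' @export
gene_body_methylation <- function(series, annotation, context = "CG",
                                  exon_only = FALSE, per_date = FALSE) {
  if (nrow(annotation$genes) == 0) abort("no genes annotated")
  ser <- subset_series(series, contexts = context)
  feats <- if (exon_only) annotation$exons else annotation$genes
  hit <- overlap_hit(ser$sites$pos - 1L, ser$sites$seq_id, feats)
  keep <- !is.na(hit)
  gid <- feats$gene_id[hit[keep]]
  m <- rowsum(ser$meth[keep, , drop = FALSE], gid)
  t <- rowsum(ser$total[keep, , drop = FALSE], gid)
  ns <- as.vector(table(gid)[rownames(m)])
  no_sites <- setdiff(annotation$genes$gene_id, rownames(m))
  if (length(no_sites) > 0) {
    inform(sprintf("%d gene(s) without %s sites excluded",
                   length(no_sites), context))
  }
  lvl <- m / ifelse(t > 0, t, NA)
  if (per_date) {
    return(tibble(gene_id = rep(rownames(m), ncol(m)),
                  date = rep(ser$dates, each = nrow(m)),
                  level = as.vector(lvl),
                  n_sites = rep(ns, ncol(m))) |>
             arrange(.data$gene_id, .data$date))
  }
  gbm <- rowMeans(lvl, na.rm = TRUE)
  covered <- rowSums(t) > 0
  if (any(!covered)) {
    inform(sprintf("%d gene(s) with no %s coverage at any date excluded",
                   sum(!covered), context))
  }
  tibble(gene_id = rownames(m), gbm = unname(gbm),
         n_sites = ns)[covered, ]
}

moving_average <- function(x, w) {
  if (w == 1L) return(x) # exact pass-through, no cumsum round-off
  n <- length(x)
  h <- (w - 1L) %/% 2L
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  cs <- c(0, cumsum(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Seasonal average and range of expression
#'
#' Per gene: the arithmetic mean of log2(RPM + 1) across dates, and the range
#' (max minus min) of the centred moving average of the date-ordered series.
#' The smoothing window is truncated at the edges; `smooth_window = 1`
#' disables smoothing so the range is the raw max minus min.
#'
#' @param expression Long tibble `gene_id`, `date`, `expr` with `expr >= 0`.
#' @param smooth_window Odd window width in dates (default 3).
#' @return Tibble `gene_id`, `average`, `range`, `n_dates`.
#' @export
#' @examples
#' seasonal_summary(tibble::tibble(gene_id = "g", date = as.Date("2015-01-01") + 0:4,
#'                                 expr = c(0, 0, 6, 0, 0)))$range # 2
seasonal_summary <- function(expression, smooth_window = 3) {
  if (smooth_window < 1 || smooth_window %% 2 == 0) {
    abort("smooth_window must be a positive odd integer")
  }
  if (any(expression$expr < 0, na.rm = TRUE)) {
    abort("expression values are log2(RPM + 1) and must be >= 0")
  }
  if (length(unique(expression$date)) < 2) abort("need at least 2 dates")
  expression |>
    group_by(.data$gene_id) |>
    arrange(.data$date, .by_group = TRUE) |>
    summarise(
      average = mean(.data$expr),
      range = {
        sm <- moving_average(.data$expr, smooth_window)
        max(sm) - min(sm)
      },
      n_dates = dplyr::n(),
      .groups = "drop"
    )
}

#' Quintile bins of gene-body methylation among expressed genes
#'
#' Keeps genes whose seasonal average expression exceeds `expressed_min`
#' (log2(RPM + 1) > 1 by default), splits them into five bins at the
#' 20/40/60/80 gbM percentiles; a gene whose gbM ties a boundary goes to the
#' lower bin.
#'
#' @param gbm_records Output of [gene_body_methylation()].
#' @param summaries Output of [seasonal_summary()].
#' @param expressed_min Expression filter threshold (strictly greater than).
#' @return Tibble `gene_id`, `gbm`, `average`, `range`, `bin` (1 = lowest
#'   gbM).
#' @export
quintile_bins <- function(gbm_records, summaries, expressed_min = 1.0) {
  d <- inner_join(gbm_records, summaries, by = "gene_id") |>
    filter(.data$average > expressed_min)
  if (nrow(d) < 5) abort("fewer than 5 expressed genes: quintiles undefined")
  if (length(unique(d$gbm)) == 1) {
    abort("all gbM values identical: quintiles undefined")
  }
  breaks <- quantile(d$gbm, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  d |>
    mutate(bin = 1L + rowSums(outer(.data$gbm, breaks, `>`))) |>
    select("gene_id", "gbm", "average", "range", "bin")
}

# compact letter display by insert-and-absorb on the significance matrix
letter_display <- function(groups, sig_pairs) {
  sets <- list(groups)
  for (r in seq_len(nrow(sig_pairs))) {
    i <- sig_pairs$g1[r]; j <- sig_pairs$g2[r]
    hit <- vapply(sets, function(s) i %in% s && j %in% s, logical(1))
    if (!any(hit)) next
    kept <- sets[!hit]
    for (s in sets[hit]) kept <- c(kept, list(setdiff(s, i)), list(setdiff(s, j)))
    kept <- unique(lapply(kept[lengths(kept) > 0], sort))
    # absorb: drop sets strictly contained in another
    strict_sub <- vapply(seq_along(kept), function(a)
      any(vapply(seq_along(kept), function(b)
        b != a && length(kept[[a]]) < length(kept[[b]]) &&
          all(kept[[a]] %in% kept[[b]]), logical(1))), logical(1))
    sets <- kept[!strict_sub]
  }
  sets <- sets[order(vapply(sets, function(s) min(match(s, groups)), numeric(1)))]
  vapply(groups, function(g)
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
          collapse = ""), character(1))
}

#' Pairwise Mann-Whitney tests across bins with a compact letter display
#'
#' All two-sided rank-sum tests between bins, adjusted for multiple
#' comparisons (Holm by default), and letters assigned so that bins sharing a
#' letter are not significantly different at `alpha`. A pair in which every
#' value is identical gets p = 1.
#'
#' @param data Tibble with a grouping column and a value column.
#' @param value,group Column names (strings) of the values and the bins.
#' @param alpha Significance level after adjustment (default 0.01).
#' @param adjust Adjustment method passed to [stats::p.adjust()] (default
#'   `"holm"`).
#' @return A `group_tests` object: pairwise table and per-bin letters.
#' @export
groupwise_tests <- function(data, value = "range", group = "bin",
                            alpha = 0.01, adjust = "holm") {
  vals <- split(data[[value]], data[[group]])
  vals <- vals[order(names(vals))]
  if (length(vals) < 2) abort("need at least 2 bins")
  if (any(lengths(vals) < 2)) abort("every bin needs at least 2 values")
  prs <- utils::combn(names(vals), 2)
  p <- w <- numeric(ncol(prs))
  for (k in seq_len(ncol(prs))) {
    x <- vals[[prs[1, k]]]; y <- vals[[prs[2, k]]]
    if (length(unique(c(x, y))) == 1) {
      p[k] <- 1; w[k] <- length(x) * length(y) / 2
    } else {
      wt <- suppressWarnings(wilcox.test(x, y))
      p[k] <- wt$p.value; w[k] <- unname(wt$statistic)
    }
  }
  p_adj <- p.adjust(p, method = adjust)
  pairs <- tibble(g1 = prs[1, ], g2 = prs[2, ], statistic = w, p = p,
                  p_adj = p_adj, significant = p_adj < alpha)
  letters <- letter_display(names(vals), filter(pairs, .data$significant))
  structure(list(pairs = pairs,
                 letters = tibble(group = names(vals),
                                  n = lengths(vals),
                                  letters = unname(letters)),
                 alpha = alpha, adjust = adjust),
            class = "group_tests")
}

#' @export
print.group_tests <- function(x, ...) {
  cat(sprintf("<group_tests> %d pairwise Mann-Whitney tests (%s-adjusted, alpha = %g)\n",
              nrow(x$pairs), x$adjust, x$alpha))
  print(x$letters)
  invisible(x)
}

#' @rdname groupwise_tests
#' @param x A `group_tests` object.
#' @param ... Unused.
#' @method tidy group_tests
#' @export
tidy.group_tests <- function(x, ...) x$pairs

#' @rdname groupwise_tests
#' @method glance group_tests
#' @export
glance.group_tests <- function(x, ...) {
  tibble(n_groups = nrow(x$letters), n_pairs = nrow(x$pairs),
         n_significant = sum(x$pairs$significant),
         n_distinct_letters = length(unique(x$letters$letters)),
         alpha = x$alpha, adjust = x$adjust)
}

#' Association between gbM bins and expression average / range
#'
#' Per-bin medians and quartiles of the seasonal average and range, plus a
#' monotone-trend summary: the Spearman rank correlation between gbM and
#' range across genes.
#'
#' @param bins Output of [quintile_bins()].
#' @return A `gbm_association`: `bin_summary` tibble and `spearman` list
#'   (`estimate`, `p_value`, `n`; `NA` with a note when the trend is
#'   undefined).
#' @export
association_analysis <- function(bins) {
  qs <- function(x, p) unname(quantile(x, p))
  bin_summary <- bins |>
    group_by(.data$bin) |>
    summarise(n = dplyr::n(),
              average_q1 = qs(.data$average, 0.25),
              average_median = median(.data$average),
              average_q3 = qs(.data$average, 0.75),
              range_q1 = qs(.data$range, 0.25),
              range_median = median(.data$range),
              range_q3 = qs(.data$range, 0.75),
              .groups = "drop")
  spearman <- list(estimate = NA_real_, p_value = NA_real_, n = nrow(bins),
                   note = NULL)
  if (nrow(bin_summary) < 2 || stats::sd(bins$gbm) == 0 ||
      stats::sd(bins$range) == 0) {
    spearman$note <- "trend undefined (single bin or zero variance)"
  } else {
    ct <- suppressWarnings(cor.test(bins$gbm, bins$range,
                                    method = "spearman"))
    spearman$estimate <- unname(ct$estimate)
    spearman$p_value <- ct$p.value
  }
  structure(list(bin_summary = bin_summary, spearman = spearman),
            class = "gbm_association")
}

#' @export
print.gbm_association <- function(x, ...) {
  cat("<gbm_association>\n")
  print(x$bin_summary)
  if (!is.null(x$spearman$note)) {
    cat("trend:", x$spearman$note, "\n")
  } else {
    cat(sprintf("Spearman rho(gbM, range) = %.3f (p = %.3g, n = %d)\n",
                x$spearman$estimate, x$spearman$p_value, x$spearman$n))
  }
  invisible(x)
}

#' @rdname association_analysis
#' @param x A `gbm_association` object.
#' @param ... Unused.
#' @method tidy gbm_association
#' @export
tidy.gbm_association <- function(x, ...) x$bin_summary

#' @rdname association_analysis
#' @method glance gbm_association
#' @export
glance.gbm_association <- function(x, ...) {
  tibble(spearman_rho = x$spearman$estimate,
         spearman_p = x$spearman$p_value, n_genes = x$spearman$n)
}

#' Pair one feature's methylation series with one gene's expression
#'
#' Joins the per-date methylation level of a single feature (e.g. an intronic
#' repeat) with the per-date expression of a gene and reports their Pearson
#' correlation. Constant methylation (or expression) leaves the correlation
#' undefined and flagged.
#'
#' @param feature Tibble `date`, `level` for one feature.
#' @param expression Tibble `date`, `expr` for one gene.
#' @return List with `table` (paired per-date values), `r`, and
#'   `flag_constant`.
#' @export
feature_association <- function(feature, expression) {
  f <- arrange(feature, .data$date)
  e <- arrange(expression, .data$date)
  if (nrow(f) != nrow(e) || !all(f$date == e$date)) {
    abort("feature and expression series must share the same dates")
  }
  if (nrow(f) < 3) abort("need at least 3 dates")
  tab <- tibble(date = f$date, level = f$level, expr = e$expr)
  constant <- stats::sd(tab$level) == 0 || stats::sd(tab$expr) == 0
  r <- if (constant) NA_real_ else cor(tab$level, tab$expr)
  list(table = tab, r = r, flag_constant = constant)
}
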