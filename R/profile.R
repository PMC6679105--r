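# Bulk, windowed and per-feature methylation summaries.
#
# All levels are pooled ratios: sum(methylated calls) / sum(total calls) over
# the chosen set of site-date observations — never a mean of per-site ratios.

#' Pooled methylation level
#'
#' @param n_meth,n_unmeth Vectors of methylated / unmethylated call counts.
#' @return `sum(n_meth) / sum(n_meth + n_unmeth)`, or `NA` when no calls were
#'   made (never 0).
#' @export
#' @examples
#' methylation_level(c(3, 2), c(7, 8)) # 0.25
methylation_level <- function(n_meth, n_unmeth) {
  if (any(n_meth < 0 | n_unmeth < 0)) abort("counts must be non-negative")
  tot <- sum(n_meth) + sum(n_unmeth)
  if (tot == 0) return(NA_real_)
  sum(n_meth) / tot
}

#' Bulk methylation levels per context and date
#'
#' @param series A `methylome_series`.
#' @param exclude_seq Sequences to leave out (e.g. the spike-in contig).
#' @return Tibble `context`, `date`, `level`, `n_sites`. Contexts absent from
#'   the series yield no rows.
#' @export
bulk_levels <- function(series, exclude_seq = NULL) {
  if (!is.null(exclude_seq)) {
    series <- subset_series(series, exclude_seq = exclude_seq)
  }
  if (nrow(series$sites) == 0) abort("empty series")
  ctx <- series$sites$context
  m <- rowsum(series$meth, ctx)
  t <- rowsum(series$total, ctx)
  ns <- as.vector(table(ctx)[rownames(m)])
  tibble(
    context = rep(rownames(m), ncol(m)),
    date = rep(series$dates, each = nrow(m)),
    level = as.vector(m / t),
    n_sites = rep(ns, ncol(m))
  ) |> arrange(.data$context, .data$date)
}

#' Bisulfite conversion rate from an unmethylated spike-in
#'
#' The conversion rate at each date is one minus the pooled methylation level
#' over all cytosines of the (fully unmethylated) spike-in contig; efficient
#' conversion shows rates above 0.99.
#'
#' @param series A `methylome_series`.
#' @param spike_seq_id Name of the spike-in contig.
#' @return Tibble `date`, `rate`, `n_calls`.
#' @export
conversion_rate <- function(series, spike_seq_id = SPIKE_NAME) {
  sp <- subset_series(series, seq_ids = spike_seq_id)
  if (nrow(sp$sites) == 0) {
    abort(sprintf("no spike-in sites on sequence '%s'", spike_seq_id))
  }
  m <- colSums(sp$meth)
  t <- colSums(sp$total)
  tibble(date = sp$dates, rate = 1 - m / t, n_calls = as.integer(t))
}

merged_repeat_ranges <- function(annotation) {
  r <- annotation$repeats
  if (nrow(r) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::reduce(grange_of(r))
}

#' Windowed methylation levels and repeat density
#'
#' Tiles every sequence with fixed-width windows (the last window of a
#' sequence is truncated), pools methylation per window, context and date, and
#' annotates each window with its repeat density (fraction of window bases
#' covered by repeats, overlapping repeats merged first). A site belongs to
#' the window containing its 0-based position.
#'
#' @param series A `methylome_series`.
#' @param annotation A [genome_annotation()] (supplies repeats and sequence
#'   lengths).
#' @param window_size Window width in bp (default 100,000).
#' @param exclude_seq Sequences to leave out.
#' @return Tibble `seq_id`, `start`, `end` (0-based half-open),
#'   `repeat_density`, `context`, `date`, `level` (`NA` where the window has
#'   no sites of that context), `n_sites`.
#' @export
window_profiles <- function(series, annotation, window_size = 100000,
                            exclude_seq = NULL) {
  if (window_size <= 0) abort("window_size must be positive")
  sl <- annotation$seqlengths
  if (!is.null(exclude_seq)) sl <- sl[!names(sl) %in% exclude_seq]
  wins <- bind_rows(lapply(names(sl), function(sid) {
    starts <- seq(0L, sl[[sid]] - 1L, by = window_size)
    tibble(seq_id = sid, start = as.integer(starts),
           end = as.integer(pmin(starts + window_size, sl[[sid]])))
  }))
  # repeat coverage per window, merged before counting
  merged <- merged_repeat_ranges(annotation)
  wgr <- grange_of(wins)
  cov_bp <- rep(0L, nrow(wins))
  if (length(merged) > 0) {
    hits <- GenomicRanges::findOverlaps(wgr, merged)
    if (length(hits) > 0) {
      qh <- S4Vectors::queryHits(hits)
      ov <- IRanges::pintersect(wgr[qh], merged[S4Vectors::subjectHits(hits)])
      rs <- rowsum(GenomicRanges::width(ov), qh)
      cov_bp[as.integer(rownames(rs))] <- as.integer(rs[, 1])
    }
  }
  wins$repeat_density <- cov_bp / (wins$end - wins$start)

  ser <- if (!is.null(exclude_seq))
    subset_series(series, exclude_seq = exclude_seq) else series
  widx <- paste(ser$sites$seq_id,
                (ser$sites$pos - 1L) %/% as.integer(window_size),
                ser$sites$context, sep = "\r")
  m <- rowsum(ser$meth, widx)
  t <- rowsum(ser$total, widx)
  ns <- as.vector(table(widx)[rownames(m)])
  parts <- strsplit(rownames(m), "\r", fixed = TRUE)
  lvl <- tibble(
    seq_id = rep(vapply(parts, `[`, "", 1), ncol(m)),
    win = rep(as.integer(vapply(parts, `[`, "", 2)), ncol(m)),
    context = rep(vapply(parts, `[`, "", 3), ncol(m)),
    date = rep(ser$dates, each = nrow(m)),
    level = as.vector(m / t),
    n_sites = rep(ns, ncol(m))
  )
  grid <- tidyr::expand_grid(
    wins |> mutate(win = .data$start %/% as.integer(window_size)),
    context = sort(unique(ser$sites$context)),
    date = ser$dates)
  left_join(grid, lvl, by = c("seq_id", "win", "context", "date")) |>
    mutate(n_sites = ifelse(is.na(.data$n_sites), 0L, .data$n_sites)) |>
    select("seq_id", "start", "end", "repeat_density", "context", "date",
           "level", "n_sites") |>
    arrange(.data$seq_id, .data$start, .data$context, .data$date)
}

#' Correlation between window methylation and repeat density
#'
#' Pearson correlation across windows between repeat density and the pooled
#' methylation level of one context at one date. Windows without a defined
#' level are excluded.
#'
#' @param profiles Output of [window_profiles()].
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @param date The sampling date to use.
#' @return The correlation coefficient.
#' @export
window_correlation <- function(profiles, context, date) {
  d <- profiles |>
    filter(.data$context == !!context, .data$date == as.Date(!!date),
           !is.na(.data$level))
  if (nrow(d) < 3) abort("need at least 3 windows with a defined level")
  if (stats::sd(d$level) == 0 || stats::sd(d$repeat_density) == 0) {
    abort("zero variance: correlation undefined")
  }
  cor(d$repeat_density, d$level)
}

#' Per-feature seasonal methylation series
#'
#' Pools the per-date methylation level over all sites of one context inside
#' each gene or repeat. Features without any site of the requested context are
#' dropped with a message.
#'
#' @param series A `methylome_series`.
#' @param annotation A [genome_annotation()].
#' @param type `"repeat"` or `"gene"`.
#' @param context Context to pool.
#' @param family Optional repeat family filter (exact `Class/Family` string).
#' @return Tibble `feature_id`, `family` (`NA` for genes), `date`, `level`,
#'   `n_sites`.
#' @export
feature_series <- function(series, annotation, type = c("repeat", "gene"),
                           context = "CHH", family = NULL) {
  type <- match.arg(type)
  feats <- if (type == "repeat") {
    f <- annotation$repeats
    if (!is.null(family)) f <- filter(f, .data$family %in% !!family)
    f |> rename(feature_id = "repeat_id")
  } else {
    annotation$genes |> mutate(family = NA_character_) |>
      rename(feature_id = "gene_id")
  }
  if (nrow(feats) == 0) abort("no matching features")
  ser <- subset_series(series, contexts = context)
  hit <- overlap_hit(ser$sites$pos - 1L, ser$sites$seq_id, feats)
  keep <- !is.na(hit)
  if (!any(keep)) {
    inform("no sites of the requested context fall in any feature")
    return(tibble(feature_id = character(), family = character(),
                  date = as.Date(character()), level = numeric(),
                  n_sites = integer()))
  }
  fid <- feats$feature_id[hit[keep]]
  m <- rowsum(ser$meth[keep, , drop = FALSE], fid)
  t <- rowsum(ser$total[keep, , drop = FALSE], fid)
  ns <- as.vector(table(fid)[rownames(m)])
  dropped <- setdiff(feats$feature_id, rownames(m))
  if (length(dropped) > 0) {
    inform(sprintf("%d feature(s) without %s sites excluded",
                   length(dropped), context))
  }
  tibble(
    feature_id = rep(rownames(m), ncol(m)),
    family = feats$family[match(rep(rownames(m), ncol(m)),
                                feats$feature_id)],
    date = rep(ser$dates, each = nrow(m)),
    level = as.vector(m / t),
    n_sites = rep(ns, ncol(m))
  ) |> arrange(.data$feature_id, .data$date)
}

#' Median seasonal series per repeat family
#'
#' Summarises a [feature_series()] table to the median level across features
#' of each family at each date.
#'
#' @param fs Output of [feature_series()].
#' @return Tibble `family`, `date`, `median_level`, `n_features`.
#' @export
family_medians <- function(fs) {
  fs |>
    filter(!is.na(.data$level)) |>
    group_by(.data$family, .data$date) |>
    summarise(median_level = median(.data$level),
              n_features = dplyr::n(), .groups = "drop")
}
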