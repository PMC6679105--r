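# Seasonally methylated cytosine (SeMC) detection.
#
# A SeMC is a cytosine whose methylation ratio differs between at least two
# sampling dates. The site statistic is the minimum over all C(T,2) date
# pairs of the two-sided Fisher exact p-value on the 2x2 methylated /
# unmethylated table; false discovery is controlled per context with Storey
# q-values on those per-site minima. Under the null the pairwise minimum is
# stochastically smaller than uniform; an optional Sidak correction
# p' = 1 - (1 - p_min)^n_pairs restores calibration and is used wherever
# calibrated error rates matter.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p computed by summing hypergeometric probabilities no larger than
#' the observed table's probability (with relative tolerance 1e-7 for ties),
#' i.e. the same tail definition as [stats::fisher.test()]. Vectorised over
#' tables.
#'
#' @param a,b,c,d Non-negative integer entries of `[[a, b], [c, d]]`
#'   (methylated/unmethylated at date i over date j). Vectors are recycled.
#' @return Two-sided p-values in `[0, 1]`; degenerate margins give 1.
#' @export
#' @examples
#' fisher_exact_2x2(10, 0, 0, 10) # 2 / choose(20, 10)
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  fisher2x2_cpp(rep_len(as.integer(a), n), rep_len(as.integer(b), n),
                rep_len(as.integer(c), n), rep_len(as.integer(d), n))
}

#' Per-site minimum pairwise Fisher statistic
#'
#' For each site, tests every pair of dates whose total coverage passes
#' `min_cov` and returns the minimum two-sided Fisher p. Sites with no
#' testable pair get `NA` (they are excluded from detection, not given
#' p = 1).
#'
#' @param meth,total Integer matrices (sites x dates) of methylated and total
#'   call counts; a single site may be given as vectors.
#' @param min_cov Minimum total calls for a date to enter a pair (default 5).
#' @return Tibble `p_min`, `n_pairs`.
#' @export
site_statistic <- function(meth, total, min_cov = 5) {
  if (is.null(dim(meth))) meth <- matrix(as.integer(meth), nrow = 1)
  if (is.null(dim(total))) total <- matrix(as.integer(total), nrow = 1)
  res <- pmin_fisher_cpp(meth, total, as.integer(min_cov))
  tibble(p_min = res[, 1], n_pairs = as.integer(res[, 2]))
}

# Omnibus alternative: G-test (likelihood ratio) on the 2 x T' table of
# dates passing the coverage filter.
gtest_omnibus <- function(meth, total, min_cov = 5) {
  apply_row <- function(m, t) {
    keep <- t >= min_cov
    if (sum(keep) < 2) return(c(NA_real_, 0))
    m <- m[keep]; t <- t[keep]
    o <- rbind(m, t - m)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    nz <- o > 0
    g <- 2 * sum(o[nz] * log(o[nz] / e[nz]))
    c(stats::pchisq(g, df = sum(keep) - 1, lower.tail = FALSE),
      choose(sum(keep), 2))
  }
  out <- vapply(seq_len(nrow(meth)), function(i)
    apply_row(meth[i, ], total[i, ]), numeric(2))
  tibble(p_min = out[1, ], n_pairs = as.integer(out[2, ]))
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on a lambda grid (default 0.05..0.95,
#' step 0.05) with a cubic smoothing spline evaluated at the largest lambda,
#' clipped to (0, 1], and converts sorted p-values with
#' `q_(i) = pi0 * m * p_(i) / i` enforcing monotonicity by cumulative minima
#' from the largest p downward.
#'
#' @param p P-values in `[0, 1]`.
#' @param lambda Grid for the pi0 estimate.
#' @param pi0 Optional fixed pi0 overriding the estimate.
#' @return List with `q` (same order as `p`) and `pi0`.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                           pi0 = NULL) {
  if (length(p) == 0) abort("need at least one p-value")
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (is.null(pi0)) {
    pl <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pl, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
  }
  ord <- order(p)
  raw <- pi0 * m * p[ord] / seq_len(m)
  qs <- pmin(rev(cummin(rev(raw))), 1)
  q <- numeric(m)
  q[ord] <- qs
  list(q = q, pi0 = pi0)
}

#' Peak date of a seasonal methylation profile
#'
#' The date of the maximum ratio; exact ties are broken toward the earliest
#' date and flagged.
#'
#' @param ratios Numeric vector (one site) or matrix (sites x dates) of
#'   per-date methylation ratios; `NA` allowed for uncovered dates.
#' @param dates The sampling dates (matching columns).
#' @return Tibble `peak_date`, `peak_month`, `peak_tie`.
#' @export
classify_peak <- function(ratios, dates) {
  if (is.null(dim(ratios))) ratios <- matrix(ratios, nrow = 1)
  if (ncol(ratios) != length(dates)) abort("ratios/dates length mismatch")
  if (nrow(ratios) == 1 && all(is.na(ratios))) {
    abort("all ratios undefined: no peak")
  }
  r <- ratios
  r[is.na(r)] <- -Inf
  idx <- max.col(r, ties.method = "first")
  mx <- r[cbind(seq_len(nrow(r)), idx)]
  tie <- rowSums(r == mx) > 1
  idx[!is.finite(mx)] <- NA
  tibble(peak_date = dates[idx],
         peak_month = ifelse(is.na(idx), NA_character_,
                             month_label(dates[pmax(idx, 1)])),
         peak_tie = ifelse(is.na(idx), NA, tie))
}

#' Classify genomic location of sites
#'
#' Precedence exon > intron > intergenic: a site inside any exon is exonic, a
#' site inside a gene span but no exon is intronic, anything else intergenic.
#'
#' @param annotation A [genome_annotation()].
#' @param seq_id,pos Site coordinates (1-based).
#' @return Character vector of `"exon"`, `"intron"`, `"intergenic"`.
#' @export
classify_location <- function(annotation, seq_id, pos) {
  pos0 <- pos - 1L
  exon <- !is.na(overlap_hit(pos0, seq_id, annotation$exons))
  gene <- !is.na(overlap_hit(pos0, seq_id, annotation$genes))
  ifelse(exon, "exon", ifelse(gene, "intron", "intergenic"))
}

#' Detect seasonally methylated cytosines
#'
#' Computes the per-site minimum pairwise Fisher p (or an omnibus G-test),
#' Storey q-values per context, and flags SeMCs as sites with
#' `p < alpha` and `q < fdr_max`. Ratios, peak dates and genomic locations
#' are attached to every eligible site.
#'
#' @param series A `methylome_series`.
#' @param annotation Optional [genome_annotation()] for location classes.
#' @param alpha Per-site p threshold (default 0.001).
#' @param fdr_max Storey q threshold (default 0.2).
#' @param min_cov Coverage filter for [site_statistic()] (default 5).
#' @param correction `"none"` (the literal minimum-p pipeline) or `"sidak"`
#'   (`p' = 1 - (1 - p_min)^n_pairs` before FDR; calibrated under the null).
#' @param method `"pairwise"` minimum Fisher p (default) or `"omnibus"`
#'   G-test on the full 2 x T table.
#' @param contexts Contexts to test (FDR is controlled within each context
#'   separately).
#' @param exclude_seq Sequences to leave out (e.g. the spike-in contig).
#' @return A `semc_result`: `calls` tibble (one row per eligible site with
#'   `p_min`, `q`, `peak_date`, `location`, `is_semc`, ...), the per-date
#'   `ratios` matrix aligned with `calls`, per-context `pi0`, and the
#'   parameters used.
#' @export
detect_semcs <- function(series, annotation = NULL, alpha = 0.001,
                         fdr_max = 0.2, min_cov = 5,
                         correction = c("none", "sidak"),
                         method = c("pairwise", "omnibus"),
                         contexts = the_contexts, exclude_seq = NULL) {
  correction <- match.arg(correction)
  method <- match.arg(method)
  ser <- subset_series(series, contexts = contexts, exclude_seq = exclude_seq)
  if (nrow(ser$sites) == 0) abort("no sites to test")
  stat <- if (method == "pairwise") {
    site_statistic(ser$meth, ser$total, min_cov)
  } else {
    gtest_omnibus(ser$meth, ser$total, min_cov)
  }
  eligible <- !is.na(stat$p_min)
  ser <- subset_series(ser, index = which(eligible))
  stat <- stat[eligible, ]
  p <- stat$p_min
  if (correction == "sidak") {
    p <- 1 - (1 - p)^stat$n_pairs
  }
  q <- rep(NA_real_, length(p))
  pi0 <- c()
  for (ctx in unique(ser$sites$context)) {
    i <- ser$sites$context == ctx
    st <- storey_qvalues(p[i])
    q[i] <- st$q
    pi0[ctx] <- st$pi0
  }
  ratios <- ser$meth / ifelse(ser$total > 0, ser$total, NA)
  peaks <- classify_peak(ratios, ser$dates)
  location <- if (!is.null(annotation)) {
    classify_location(annotation, ser$sites$seq_id, ser$sites$pos)
  } else NA_character_
  calls <- tibble(
    ser$sites[, c("seq_id", "pos", "strand", "context")],
    n_pairs = stat$n_pairs,
    p_min = stat$p_min,
    p_corrected = p,
    q = q,
    peaks,
    location = location,
    is_semc = stat$p_min < alpha & q < fdr_max
  )
  structure(list(calls = calls, ratios = ratios, dates = ser$dates,
                 pi0 = pi0,
                 params = list(alpha = alpha, fdr_max = fdr_max,
                               min_cov = min_cov, correction = correction,
                               method = method)),
            class = "semc_result")
}

#' @export
print.semc_result <- function(x, ...) {
  cat(sprintf("<semc_result> %d sites tested, %d SeMCs (p < %g & q < %g, %s)\n",
              nrow(x$calls), sum(x$calls$is_semc), x$params$alpha,
              x$params$fdr_max, x$params$correction))
  print(semc_counts(x))
  invisible(x)
}

#' Per-context SeMC counts
#'
#' @param x A `semc_result`.
#' @return Tibble `context`, `n_tested`, `n_semc`, `pi0`.
#' @export
semc_counts <- function(x) {
  x$calls |>
    group_by(.data$context) |>
    summarise(n_tested = dplyr::n(), n_semc = sum(.data$is_semc),
              .groups = "drop") |>
    mutate(pi0 = unname(x$pi0[.data$context]))
}

#' @rdname detect_semcs
#' @param x A `semc_result`.
#' @param ... Unused.
#' @method tidy semc_result
#' @export
tidy.semc_result <- function(x, ...) x$calls

#' @rdname detect_semcs
#' @method glance semc_result
#' @export
glance.semc_result <- function(x, ...) {
  tibble(n_tested = nrow(x$calls), n_semc = sum(x$calls$is_semc),
         alpha = x$params$alpha, fdr_max = x$params$fdr_max,
         min_cov = x$params$min_cov, correction = x$params$correction,
         method = x$params$method)
}

#' Per-date methylation ratios of detected SeMCs
#'
#' @param x A `semc_result`.
#' @param semc_only Keep only flagged SeMCs (default `TRUE`).
#' @return Long tibble `seq_id`, `pos`, `strand`, `context`, `date`, `ratio`.
#' @export
semc_ratios <- function(x, semc_only = TRUE) {
  keep <- if (semc_only) x$calls$is_semc else rep(TRUE, nrow(x$calls))
  r <- x$ratios[keep, , drop = FALSE]
  calls <- x$calls[keep, c("seq_id", "pos", "strand", "context")]
  tibble(calls[rep(seq_len(nrow(calls)), length(x$dates)), ],
         date = rep(x$dates, each = nrow(calls)),
         ratio = as.vector(r))
}

#' Hierarchically cluster SeMC seasonal profiles
#'
#' Average-linkage agglomerative clustering with correlation distance
#' `d = 1 - Pearson r` between per-date ratio profiles; rows with zero
#' variance (or undefined correlations) get distance 1 to all others. The
#' dendrogram is also returned as Newick text.
#'
#' @param x A `semc_result` (its flagged SeMCs are clustered) or a numeric
#'   matrix of profiles (rows = sites).
#' @param k Optional number of clusters to cut into.
#' @param max_leaves Random (seeded) subsample cap on the number of profiles;
#'   `NULL` clusters everything.
#' @param seed Seed for the subsample.
#' @return A `semc_clustering`: the `hclust` object, leaf `order`, `labels`,
#'   `newick` text and (if `k` given) cluster memberships.
#' @export
cluster_semcs <- function(x, k = NULL, max_leaves = NULL, seed = 1L) {
  if (inherits(x, "semc_result")) {
    keep <- which(x$calls$is_semc)
    mat <- x$ratios[keep, , drop = FALSE]
    labels <- paste(x$calls$seq_id[keep], x$calls$pos[keep],
                    x$calls$strand[keep], sep = ":")
  } else {
    mat <- as.matrix(x)
    labels <- rownames(mat)
    if (is.null(labels)) labels <- paste0("s", seq_len(nrow(mat)))
  }
  if (nrow(mat) < 2) abort("need at least 2 profiles to cluster")
  if (!is.null(max_leaves) && nrow(mat) > max_leaves) {
    set.seed(seed)
    keep2 <- sort(sample(nrow(mat), max_leaves))
    mat <- mat[keep2, , drop = FALSE]
    labels <- labels[keep2]
  }
  cc <- suppressWarnings(cor(t(mat), use = "pairwise.complete.obs"))
  cc[!is.finite(cc)] <- 0
  d <- 1 - cc
  diag(d) <- 0
  rownames(d) <- colnames(d) <- labels
  hc <- hclust(as.dist(d), method = "average")
  newick <- ape::write.tree(ape::as.phylo(hc))
  out <- list(hclust = hc, order = hc$order, labels = labels,
              newick = newick)
  if (!is.null(k)) out$clusters <- stats::cutree(hc, k = k)
  structure(out, class = "semc_clustering")
}

#' @export
print.semc_clustering <- function(x, ...) {
  cat(sprintf("<semc_clustering> %d leaves, average linkage on 1 - r\n",
              length(x$labels)))
  invisible(x)
}

#' Genomic location breakdown of SeMCs
#'
#' @param x A `semc_result` (detection must have been run with an
#'   annotation) or a calls tibble with `context` and `location`.
#' @return Tibble `context`, `location`, `n`, `prop` (proportions sum to 1
#'   within each context).
#' @export
location_breakdown <- function(x) {
  calls <- if (inherits(x, "semc_result")) x$calls else x
  calls <- filter(calls, .data$is_semc)
  if (nrow(calls) == 0) abort("no SeMC calls")
  if (all(is.na(calls$location))) abort("calls carry no location classes")
  calls |>
    count(.data$context, .data$location) |>
    group_by(.data$context) |>
    mutate(prop = .data$n / sum(.data$n)) |>
    ungroup()
}
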