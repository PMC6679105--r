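# Synthetic multi-timepoint methylome generator with planted ground truth.
#
# The generator emulates the statistical structure of a year-round
# single-clone bisulfite study: a mostly stable methylome with
# context-specific baselines, repeat-dense heterochromatic blocks with
# elevated methylation, a small fraction of seasonally methylated cytosines
# with a unique peak date, an unmethylated spike-in contig for
# conversion-rate estimation, and gene expression whose seasonal range
# shrinks with gene-body CG methylation.

SPIKE_NAME <- "spike_lambda"

repeat_families <- c("LTR/Copia", "LTR/Gypsy", "LINE/L1", "DNA/MULE-MuDR",
                     "DNA/hAT", "RC/Helitron")

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic dataset. Defaults encode
#' the reference study conditions: 8 sampling dates at ~1.5-month intervals,
#' context baselines 0.45/0.20/0.06 (CG/CHG/CHH), mean read depth 20, and a
#' small SeMC fraction (< 0.5% of cytosines).
#'
#' @param seed Integer seed; every random draw of the generator derives from
#'   it (the three stages use `seed`, `seed + 1`, `seed + 2`).
#' @param n_sequences,seq_length Number and length (bp) of genomic contigs.
#' @param block_length Length (bp) of alternating heterochromatic/genic
#'   blocks.
#' @param repeat_fraction_per_block Length-2 vector: target fraction of block
#'   bases covered by repeats in heterochromatic and genic blocks.
#' @param gc_content Genome GC fraction.
#' @param baseline_level Named per-context baseline methylation probability.
#' @param repeat_boost Named per-context additive probability increase inside
#'   repeats.
#' @param dates T strictly increasing sampling dates (default 8).
#' @param coverage_mean Mean (Poisson) read depth per site and date.
#' @param semc_fraction Fraction of (non-spike-in) sites per context planted
#'   as true SeMCs.
#' @param semc_amplitude Peak-minus-trough methylation-probability difference
#'   of a planted SeMC.
#' @param semc_width Full width (days) of the raised-cosine seasonal bump.
#' @param semc_peak_bias Probability that a planted SeMC takes its context's
#'   modal peak date (CG July, CHG March, CHH September) instead of a
#'   uniformly drawn sampling date.
#' @param semc_chh_repeats_only Plant CHH SeMCs only in intergenic repeats
#'   (emulating their concentration at repetitive sequences).
#' @param n_genes Number of genes to place in genic blocks.
#' @param gbm_coupling Strength in `[0, ~1]` of the decrease of seasonal
#'   expression amplitude with gene-body CG methylation.
#' @param expr_base,expr_slope Baseline of mean log2(RPM+1) and its weak
#'   increase with gbM.
#' @param expr_amp Maximal seasonal expression amplitude (log2 units).
#' @param expr_noise_sd Per-date Gaussian noise on expression.
#' @param spike_in_length Length (bp) of the fully unmethylated spike-in
#'   contig.
#' @param conversion_failure_rate Probability that an unmethylated cytosine
#'   reads as methylated (incomplete bisulfite conversion).
#' @param flc_like Plant one gene with a seasonally methylated intronic
#'   repeat whose expression runs in anti-phase to the repeat's CHH
#'   methylation.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_sequences = 4L,
                              seq_length = 150000L,
                              block_length = 25000L,
                              repeat_fraction_per_block = c(het = 0.6, genic = 0.05),
                              gc_content = 0.36,
                              baseline_level = c(CG = 0.45, CHG = 0.20, CHH = 0.06),
                              repeat_boost = c(CG = 0.40, CHG = 0.40, CHH = 0.15),
                              dates = default_dates(),
                              coverage_mean = 20,
                              semc_fraction = 0.005,
                              semc_amplitude = 0.4,
                              semc_width = 135,
                              semc_peak_bias = 0.5,
                              semc_chh_repeats_only = TRUE,
                              n_genes = 120L,
                              gbm_coupling = 0.7,
                              expr_base = 2.5,
                              expr_slope = 1.0,
                              expr_amp = 1.5,
                              expr_noise_sd = 0.2,
                              spike_in_length = 20000L,
                              conversion_failure_rate = 0.005,
                              flc_like = TRUE) {
  cfg <- as.list(environment())
  cfg$dates <- as.Date(cfg$dates)
  probs <- c(cfg$baseline_level, cfg$repeat_fraction_per_block, gc_content,
             semc_fraction, semc_peak_bias, conversion_failure_rate)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1]")
  if (!all(the_contexts %in% names(cfg$baseline_level)))
    abort("baseline_level needs named CG, CHG and CHH entries")
  if (!all(the_contexts %in% names(cfg$repeat_boost)))
    abort("repeat_boost needs named CG, CHG and CHH entries")
  if (coverage_mean <= 0) abort("coverage_mean must be positive")
  if (semc_amplitude < 0 || semc_amplitude > 1)
    abort("semc_amplitude must lie in [0, 1]")
  if (length(cfg$dates) < 2 || any(diff(cfg$dates) <= 0))
    abort("dates must be >= 2 and strictly increasing")
  if (n_genes < 0 || n_sequences < 1 || seq_length < 1000)
    abort("invalid genome shape")
  structure(cfg, class = "simulation_config")
}

sample_sequence <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

place_repeats_in_block <- function(block_start, block_end, frac) {
  L <- block_end - block_start
  target <- frac * L
  if (target < 50) return(NULL)
  lens <- integer()
  while (sum(lens) < target) lens <- c(lens, round(runif(1, 100, 600)))
  while (length(lens) > 0 && sum(lens) > 0.9 * L) lens <- lens[-length(lens)]
  k <- length(lens)
  if (k == 0) return(NULL)
  u <- runif(k + 1)
  gaps <- floor((L - sum(lens)) * u / sum(u))
  pos <- block_start
  starts <- integer(k)
  for (i in seq_len(k)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + lens[i]
  }
  tibble(start = starts, end = starts + lens,
         family = sample(repeat_families, k, replace = TRUE))
}

#' Simulate a toy annotated genome
#'
#' Draws random contigs partitioned into alternating repeat-dense
#' ("heterochromatic") and gene-bearing ("genic") blocks, places repeats to
#' the per-block target density and genes (with exon/intron structure) in the
#' repeat-free parts of genic blocks, and appends an unannotated spike-in
#' contig. Fully deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list with `genome` (named character vector), `annotation`
#'   ([genome_annotation()]) and `flc_like` (gene/repeat ids of the planted
#'   intronic-repeat gene, or `NULL`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  seq_ids <- paste0("scf_", seq_len(config$n_sequences))
  genome <- stats::setNames(
    vapply(seq_ids, function(i)
      sample_sequence(config$seq_length, config$gc_content), character(1)),
    seq_ids)
  genome[[SPIKE_NAME]] <- sample_sequence(config$spike_in_length,
                                          config$gc_content)
  seqlengths <- vapply(genome, nchar, integer(1))

  frac <- config$repeat_fraction_per_block
  repeats <- list()
  genic_blocks <- list()
  for (sid in seq_ids) {
    len <- config$seq_length
    starts <- seq(0L, len - 1L, by = config$block_length)
    for (b in seq_along(starts)) {
      bs <- starts[b]
      be <- min(bs + config$block_length, len)
      het <- (b %% 2L) == 1L
      rp <- place_repeats_in_block(bs, be, if (het) frac[[1]] else frac[[2]])
      if (!is.null(rp)) repeats[[length(repeats) + 1L]] <- mutate(rp, seq_id = sid)
      if (!het) genic_blocks[[length(genic_blocks) + 1L]] <-
          tibble(seq_id = sid, start = bs, end = be)
    }
  }
  repeats <- bind_rows(repeats)
  genic_blocks <- bind_rows(genic_blocks)

  genes <- NULL
  exons <- NULL
  if (config$n_genes > 0) {
    if (nrow(genic_blocks) == 0) abort("no genic blocks to place genes in")
    free <- GenomicRanges::GRanges(
      genic_blocks$seq_id,
      IRanges::IRanges(genic_blocks$start + 1L, genic_blocks$end))
    if (nrow(repeats) > 0) {
      free <- GenomicRanges::setdiff(
        free, GenomicRanges::GRanges(
          repeats$seq_id, IRanges::IRanges(repeats$start + 1L, repeats$end)))
    }
    free_tb <- tibble(seq_id = as.character(GenomicRanges::seqnames(free)),
                      start = GenomicRanges::start(free) - 1L,
                      end = GenomicRanges::end(free))
    gene_rows <- list()
    exon_rows <- list()
    placed <- 0L
    for (i in seq_len(nrow(free_tb))) {
      pos <- free_tb$start[i]
      while (placed < config$n_genes) {
        glen <- round(runif(1, 900, 2500))
        if (pos + glen + 100 > free_tb$end[i]) break
        placed <- placed + 1L
        gid <- sprintf("g%04d", placed)
        n_ex <- sample(2:4, 1)
        parts <- 2L * n_ex - 1L
        w <- runif(parts, 0.5, 1.5)
        w <- floor(glen * w / sum(w))
        w[parts] <- glen - sum(w[-parts])
        edges <- pos + c(0L, cumsum(w))
        gene_rows[[placed]] <- tibble(
          gene_id = gid, seq_id = free_tb$seq_id[i],
          start = pos, end = pos + glen,
          strand = sample(c("+", "-"), 1), n_exons = n_ex)
        ex_idx <- seq(1L, parts, by = 2L)
        exon_rows[[placed]] <- tibble(
          gene_id = gid, seq_id = free_tb$seq_id[i],
          start = edges[ex_idx], end = edges[ex_idx + 1L])
        pos <- pos + glen + round(runif(1, 120, 300))
      }
      if (placed >= config$n_genes) break
    }
    if (placed < config$n_genes) {
      abort(sprintf("genome too small: placed %d of %d requested genes",
                    placed, config$n_genes))
    }
    genes <- bind_rows(gene_rows)
    exons <- bind_rows(exon_rows)
  }

  flc <- NULL
  if (config$flc_like && !is.null(genes)) {
    cand <- genes |> filter(.data$n_exons >= 2)
    for (gid in cand$gene_id) {
      ex <- exons |> filter(.data$gene_id == gid) |> arrange(.data$start)
      intron_start <- ex$end[1]
      intron_end <- ex$start[2]
      if (intron_end - intron_start >= 220) {
        rs <- intron_start + 30L
        rl <- min(150L, intron_end - intron_start - 60L)
        repeats <- bind_rows(repeats, tibble(
          start = rs, end = rs + rl, family = "SINE/tRNA",
          seq_id = ex$seq_id[1]))
        flc <- list(gene_id = gid, repeat_start = rs, repeat_end = rs + rl,
                    seq_id = ex$seq_id[1])
        break
      }
    }
  }
  if (!is.null(genes)) genes <- select(genes, -"n_exons")
  if (nrow(repeats) > 0) {
    repeats <- repeats |>
      arrange(.data$seq_id, .data$start) |>
      mutate(repeat_id = sprintf("rep_%05d", dplyr::row_number())) |>
      select("repeat_id", "seq_id", "start", "end", "family")
  } else {
    repeats <- NULL
  }
  if (!is.null(flc)) {
    flc$repeat_id <- repeats$repeat_id[
      repeats$seq_id == flc$seq_id & repeats$start == flc$repeat_start]
  }
  ann <- genome_annotation(seqlengths, genes, exons, repeats)
  list(genome = genome, annotation = ann, flc_like = flc)
}

circ_day_dist <- function(d1, d2) {
  d <- abs(as.numeric(d1) - as.numeric(d2)) %% 365
  pmin(d, 365 - d)
}

overlap_hit <- function(pos0, seq_id, intervals) {
  # first matching interval index per site (0-based point vs half-open interval)
  if (is.null(intervals) || nrow(intervals) == 0)
    return(rep(NA_integer_, length(pos0)))
  q <- GenomicRanges::GRanges(seq_id, IRanges::IRanges(pos0 + 1L, width = 1L))
  s <- GenomicRanges::GRanges(intervals$seq_id,
                              IRanges::IRanges(intervals$start + 1L,
                                               intervals$end))
  hits <- GenomicRanges::findOverlaps(q, s, select = "first")
  hits
}

#' Simulate per-cytosine methylation counts across time points
#'
#' For every cytosine the true methylation probability at date t is
#' `clip(baseline[context] + repeat_boost[context] * in_repeat + seasonal(t))`,
#' where the seasonal term is zero for stable sites and a raised-cosine bump
#' of height `semc_amplitude` centred on the site's planted peak date for SeMC
#' sites. CG sites inside gene bodies instead take the gene's planted gbM
#' level as their base probability (gene-body methylation is seasonally
#' stable). Sequenced depth is Poisson, methylated counts Binomial, and
#' incomplete bisulfite conversion flips unmethylated calls to methylated at
#' `conversion_failure_rate`; the spike-in contig is fully unmethylated.
#'
#' @param config A [simulation_config()].
#' @param genome Named character vector of sequences (from
#'   [simulate_genome()]).
#' @param annotation The matching [genome_annotation()].
#' @param flc_like Optional planted intronic-repeat descriptor from
#'   [simulate_genome()].
#' @return List with `series` (a `methylome_series`) and `truth`
#'   (`simulation_truth`: per-site flags and true probability matrix, per-gene
#'   planted gbM).
#' @export
simulate_methylome <- function(config, genome, annotation, flc_like = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  sites <- cytosine_sites(genome)
  n <- nrow(sites)
  T <- length(config$dates)
  pos0 <- sites$pos - 1L

  rep_hit <- overlap_hit(pos0, sites$seq_id, annotation$repeats)
  in_repeat <- !is.na(rep_hit)
  gene_hit <- overlap_hit(pos0, sites$seq_id, annotation$genes)
  gene_id <- annotation$genes$gene_id[gene_hit]
  spike <- sites$seq_id == SPIKE_NAME

  # per-gene planted gbM, centred on the CG baseline
  genes <- annotation$genes
  gbm <- numeric(0)
  if (nrow(genes) > 0) {
    gbm <- stats::setNames(rbeta(nrow(genes), 2.25, 2.75), genes$gene_id)
  }

  p0 <- unname(config$baseline_level[sites$context])
  genic_cg <- !is.na(gene_id) & sites$context == "CG"
  if (any(genic_cg)) p0[genic_cg] <- unname(gbm[gene_id[genic_cg]])
  p0 <- p0 + unname(config$repeat_boost[sites$context]) * in_repeat
  p0[spike] <- 0

  # plant SeMCs per context among eligible sites
  is_semc <- rep(FALSE, n)
  peak_date <- as.Date(rep(NA, n))
  modal_peak <- c(CG = 7L, CHG = 3L, CHH = 9L) # month numbers
  for (ctx in the_contexts) {
    in_ctx <- sites$context == ctx & !spike
    eligible <- in_ctx & !genic_cg
    if (ctx == "CHH" && config$semc_chh_repeats_only) {
      elig2 <- eligible & in_repeat & is.na(gene_id)
      if (any(elig2)) eligible <- elig2
    }
    n_want <- round(config$semc_fraction * sum(in_ctx))
    idx <- which(eligible)
    if (n_want > 0 && length(idx) > 0) {
      pick <- sample(idx, min(n_want, length(idx)))
      is_semc[pick] <- TRUE
      months <- as.integer(format(config$dates, "%m"))
      modal <- which(months == modal_peak[[ctx]])[1]
      if (is.na(modal)) modal <- which.max(months)
      take_modal <- runif(length(pick)) < config$semc_peak_bias
      pk <- sample(seq_len(T), length(pick), replace = TRUE)
      pk[take_modal] <- modal
      peak_date[pick] <- config$dates[pk]
    }
  }

  # planted seasonal intronic repeat: CHH bump peaking in March
  if (!is.null(flc_like)) {
    months <- as.integer(format(config$dates, "%m"))
    flc_peak <- config$dates[which(months == 3L)[1]]
    if (is.na(flc_peak)) flc_peak <- config$dates[ceiling(T / 2)]
    sel <- sites$seq_id == flc_like$seq_id &
      pos0 >= flc_like$repeat_start & pos0 < flc_like$repeat_end &
      sites$context == "CHH"
    is_semc[sel] <- TRUE
    peak_date[sel] <- flc_peak
  }

  prob <- matrix(rep(p0, T), n, T, dimnames = list(NULL, as.character(config$dates)))
  semc_idx <- which(is_semc)
  if (length(semc_idx) > 0) {
    amp <- rep(config$semc_amplitude, length(semc_idx))
    if (!is.null(flc_like)) {
      flc_sel <- sites$seq_id[semc_idx] == flc_like$seq_id &
        pos0[semc_idx] >= flc_like$repeat_start &
        pos0[semc_idx] < flc_like$repeat_end
      amp[flc_sel] <- max(config$semc_amplitude, 0.5)
    }
    # keep the amplitude inside the [0, 1] headroom so the peak date stays the
    # unique maximum (a hard clip would flatten the bump into a plateau)
    amp <- pmin(amp, 1 - p0[semc_idx])
    for (t in seq_len(T)) {
      d <- circ_day_dist(config$dates[t], peak_date[semc_idx])
      bump <- ifelse(d < config$semc_width / 2,
                     amp * cos(pi * d / config$semc_width)^2, 0)
      prob[semc_idx, t] <- prob[semc_idx, t] + bump
    }
  }
  prob <- pmin(pmax(prob, 0), 1)

  cfr <- config$conversion_failure_rate
  p_obs <- prob + (1 - prob) * cfr
  depth <- matrix(rpois(n * T, config$coverage_mean), n, T)
  meth <- matrix(rbinom(n * T, as.vector(depth), as.vector(p_obs)), n, T,
                 dimnames = list(NULL, as.character(config$dates)))
  dimnames(depth) <- dimnames(meth)

  series <- new_methylome_series(
    select(sites, "seq_id", "pos", "strand", "context", "trinucleotide"),
    meth, depth, config$dates)
  truth_sites <- sites |>
    select("seq_id", "pos", "strand", "context") |>
    mutate(in_repeat = in_repeat, gene_id = gene_id,
           is_semc = is_semc, peak_date = peak_date)
  truth <- structure(
    list(sites = truth_sites, prob = prob,
         genes = if (nrow(genes) > 0)
           tibble(gene_id = genes$gene_id, gbm = unname(gbm)) else
             tibble(gene_id = character(), gbm = numeric()),
         flc_like = flc_like,
         dates = config$dates),
    class = "simulation_truth")
  list(series = series, truth = truth)
}

#' Convert a series back into per-date cytosine reports
#'
#' @param series A `methylome_series`.
#' @return A list of T record tibbles in the dialect of
#'   [read_cytosine_report()].
#' @export
series_to_reports <- function(series) {
  lapply(seq_along(series$dates), function(t) {
    tibble(
      series$sites[, c("seq_id", "pos", "strand")],
      n_meth = as.integer(series$meth[, t]),
      n_unmeth = as.integer(series$total[, t] - series$meth[, t]),
      context = series$sites$context,
      trinucleotide = if ("trinucleotide" %in% names(series$sites))
        series$sites$trinucleotide else NA_character_
    )
  })
}

#' Simulate seasonal gene expression coupled to gene-body methylation
#'
#' Per gene g with planted gbM level m: expression at date t is
#' `mean(m) + A(m) * cos(2*pi*(doy(t) - phase)/365) + noise`, with seasonal
#' amplitude `A(m) = expr_amp * max(0, 1 - gbm_coupling * m)` decreasing in
#' gbM and the mean increasing weakly in gbM. The planted intronic-repeat gene
#' (if present) is given a large amplitude in anti-phase to its repeat's CHH
#' methylation peak. Values are log2(RPM + 1), floored at 0.
#'
#' @param config A [simulation_config()].
#' @param annotation The [genome_annotation()] supplying gene ids.
#' @param truth Optional `simulation_truth` carrying planted gbM; genes
#'   without a planted value get a fresh Beta draw.
#' @return List with `expression` (long tibble `gene_id`, `date`, `expr`) and
#'   the updated `truth` whose `genes` table gains the deterministic seasonal
#'   `expr_average` and `expr_range` plus amplitude and phase.
#' @export
simulate_expression <- function(config, annotation, truth = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  genes <- annotation$genes
  if (nrow(genes) == 0) abort("no genes in annotation")
  g <- rep(NA_real_, nrow(genes))
  if (!is.null(truth) && nrow(truth$genes) > 0) {
    g <- truth$genes$gbm[match(genes$gene_id, truth$genes$gene_id)]
  }
  g[is.na(g)] <- rbeta(sum(is.na(g)), 2.25, 2.75)
  amp <- config$expr_amp * pmax(0, 1 - config$gbm_coupling * g)
  mean_g <- config$expr_base + config$expr_slope * g
  phase <- runif(nrow(genes), 0, 365)

  flc <- if (!is.null(truth)) truth$flc_like else NULL
  if (!is.null(flc)) {
    i <- match(flc$gene_id, genes$gene_id)
    months <- as.integer(format(config$dates, "%m"))
    flc_peak <- config$dates[which(months == 3L)[1]]
    if (is.na(flc_peak)) flc_peak <- config$dates[ceiling(length(config$dates) / 2)]
    amp[i] <- 2.5
    mean_g[i] <- 3
    phase[i] <- (as.numeric(strftime(flc_peak, "%j")) + 365 / 2) %% 365
  }

  doy <- as.numeric(strftime(config$dates, "%j"))
  det <- outer(seq_len(nrow(genes)), seq_along(doy), function(i, t)
    mean_g[i] + amp[i] * cos(2 * pi * (doy[t] - phase[i]) / 365))
  noise <- matrix(rnorm(length(det), 0, config$expr_noise_sd), nrow(det))
  vals <- pmax(det + noise, 0)
  expression <- tibble(
    gene_id = rep(genes$gene_id, length(doy)),
    date = rep(config$dates, each = nrow(genes)),
    expr = as.vector(vals)
  ) |> arrange(.data$gene_id, .data$date)

  gt <- tibble(gene_id = genes$gene_id, gbm = g,
               expr_amplitude = amp, expr_phase = phase,
               expr_average = rowMeans(det),
               expr_range = apply(det, 1, max) - apply(det, 1, min))
  if (is.null(truth)) {
    truth <- structure(list(sites = NULL, prob = NULL, genes = gt,
                            flc_like = NULL, dates = config$dates),
                       class = "simulation_truth")
  } else {
    truth$genes <- left_join(select(gt, -"gbm"), gt[, c("gene_id", "gbm")],
                             by = "gene_id") |>
      select("gene_id", "gbm", dplyr::everything())
  }
  list(expression = expression, truth = truth)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper chaining [simulate_genome()], [simulate_methylome()]
#' and [simulate_expression()].
#'
#' @param config A [simulation_config()].
#' @return List with `genome`, `annotation`, `flc_like`, `series`, `truth`,
#'   `expression`.
#' @export
simulate_dataset <- function(config) {
  geno <- simulate_genome(config)
  meth <- simulate_methylome(config, geno$genome, geno$annotation,
                             geno$flc_like)
  truth <- meth$truth
  expression <- NULL
  if (nrow(geno$annotation$genes) > 0) {
    ex <- simulate_expression(config, geno$annotation, truth)
    expression <- ex$expression
    truth <- ex$truth
  }
  list(genome = geno$genome, annotation = geno$annotation,
       flc_like = geno$flc_like, series = meth$series, truth = truth,
       expression = expression)
}
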