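# End-to-end orchestration: simulate -> profile -> semc -> gbm, with every
# inter-stage artifact on disk so stages can be rerun in isolation and a
# fixed-seed run is byte-identical.

#' Pipeline configuration
#'
#' Either a [simulation_config()] (synthetic run) or paths to real inputs
#' (genome FASTA, GFF3 + repeat BED, per-date cytosine reports, expression
#' table) — exactly one of the two — plus the analysis parameters.
#'
#' @param simulation A [simulation_config()], or `NULL` for real inputs.
#' @param genome_path,gff3_path,repeat_bed_path Real input paths.
#' @param report_paths Character vector of per-date cytosine report paths.
#' @param dates Sampling dates matching `report_paths`.
#' @param expression_path Wide gene-by-date expression TSV.
#' @param spike_seq_id Name of the unmethylated spike-in contig (`NULL` if
#'   none).
#' @param window_size,min_repeat_len,alpha,fdr_max,min_cov,correction,method
#'   Analysis parameters (see [window_profiles()], [read_annotation()],
#'   [detect_semcs()]).
#' @param expressed_min,smooth_window,adjust gbM-stage parameters (see
#'   [quintile_bins()], [seasonal_summary()], [groupwise_tests()]).
#' @param cluster_max Cap on the number of SeMC profiles clustered for the
#'   dendrogram (seeded subsample above that).
#' @param seed Seed for the seeded analysis steps (subsampling).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL, genome_path = NULL,
                            gff3_path = NULL, repeat_bed_path = NULL,
                            report_paths = NULL, dates = NULL,
                            expression_path = NULL,
                            spike_seq_id = SPIKE_NAME,
                            window_size = 100000, min_repeat_len = 50,
                            alpha = 0.001, fdr_max = 0.2, min_cov = 5,
                            correction = "none", method = "pairwise",
                            expressed_min = 1.0, smooth_window = 3,
                            adjust = "holm", cluster_max = 2000,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Violations are returned as data, one row per broken constraint, never
#' raised.
#'
#' @param config A [pipeline_config()].
#' @return Tibble `field`, `constraint`; zero rows means the configuration is
#'   valid.
#' @export
validate_config <- function(config) {
  v <- list()
  bad <- function(field, constraint) {
    v[[length(v) + 1L]] <<- tibble(field = field, constraint = constraint)
  }
  has_sim <- !is.null(config$simulation)
  has_real <- !is.null(config$genome_path) || !is.null(config$report_paths)
  if (has_sim && has_real) {
    bad("simulation", "exactly one of simulation config and real input paths")
  }
  if (!has_sim && !has_real) {
    bad("simulation", "either a simulation config or real input paths required")
  }
  if (has_sim && !inherits(config$simulation, "simulation_config")) {
    bad("simulation", "must be a simulation_config object")
  }
  if (has_real && !has_sim) {
    if (is.null(config$genome_path)) bad("genome_path", "required for real inputs")
    if (is.null(config$report_paths)) bad("report_paths", "required for real inputs")
    if (is.null(config$dates)) {
      bad("dates", "required for real inputs")
    } else if (!is.null(config$report_paths) &&
               length(config$dates) != length(config$report_paths)) {
      bad("dates", "one date per report required")
    }
  }
  chk_range <- function(field, lo, hi, lo_open = TRUE) {
    x <- config[[field]]
    ok <- is.numeric(x) && length(x) == 1 &&
      (if (lo_open) x > lo else x >= lo) && x <= hi
    if (!ok) bad(field, sprintf("must lie in %s%g, %g]",
                                if (lo_open) "(" else "[", lo, hi))
  }
  chk_range("alpha", 0, 1)
  chk_range("fdr_max", 0, 1)
  chk_range("window_size", 0, Inf)
  chk_range("min_cov", 0, Inf, lo_open = FALSE)
  chk_range("min_repeat_len", 0, Inf, lo_open = FALSE)
  chk_range("expressed_min", 0, Inf, lo_open = FALSE)
  if (!is.numeric(config$smooth_window) || config$smooth_window < 1 ||
      config$smooth_window %% 2 == 0) {
    bad("smooth_window", "must be a positive odd integer")
  }
  if (!config$correction %in% c("none", "sidak")) {
    bad("correction", "must be 'none' or 'sidak'")
  }
  if (!config$method %in% c("pairwise", "omnibus")) {
    bad("method", "must be 'pairwise' or 'omnibus'")
  }
  if (!config$adjust %in% stats::p.adjust.methods) {
    bad("adjust", "must be a stats::p.adjust method")
  }
  if (length(v) == 0) {
    tibble(field = character(), constraint = character())
  } else {
    bind_rows(v)
  }
}

pipeline_paths <- function(out_dir, config) {
  dates <- if (!is.null(config$simulation)) config$simulation$dates
           else as.Date(config$dates)
  list(
    genome = file.path(out_dir, "genome.fa"),
    gff3 = file.path(out_dir, "annotation.gff3"),
    bed = file.path(out_dir, "repeats.bed"),
    reports = file.path(out_dir, paste0("report_", dates, ".tsv")),
    expression = file.path(out_dir, "expression.tsv"),
    truth_sites = file.path(out_dir, "truth_sites.tsv"),
    truth_genes = file.path(out_dir, "truth_genes.tsv"),
    dates = dates
  )
}

stage_inputs <- function(config, out_dir) {
  p <- pipeline_paths(out_dir, config)
  if (is.null(config$simulation)) {
    p$genome <- config$genome_path
    p$gff3 <- config$gff3_path
    p$bed <- config$repeat_bed_path
    p$reports <- config$report_paths
    p$expression <- config$expression_path
  }
  p
}

load_stage_series <- function(p) {
  reports <- lapply(p$reports, read_cytosine_report)
  build_series(reports, p$dates)
}

load_stage_annotation <- function(p, config) {
  genome <- Biostrings::readDNAStringSet(p$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  ann <- if (!is.null(p$gff3) && file.exists(p$gff3)) {
    read_annotation(p$gff3, p$bed, min_repeat_len = config$min_repeat_len,
                    seqlengths = vapply(as.character(genome), nchar, integer(1)))
  } else {
    genome_annotation(stats::setNames(Biostrings::width(genome), names(genome)))
  }
  list(genome = genome, annotation = ann)
}

write_stage_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  nrow(x)
}

#' Run the full pipeline
#'
#' Executes the requested stages in order, writing every stage artifact as
#' TSV into `out_dir` together with a JSON manifest (package version, config
#' hash, seed, per-stage row counts). Stages read their inputs from disk, so
#' deleting downstream outputs and rerunning reproduces them from the
#' upstream artifacts; a rerun with an identical config is byte-identical.
#'
#' @param config A valid [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param stages Subset of `c("simulate", "profile", "semc", "gbm")` to run.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "profile", "semc", "gbm")) {
  viol <- validate_config(config)
  if (nrow(viol) > 0) {
    abort(paste0("invalid pipeline config:\n", paste(
      sprintf("- %s: %s", viol$field, viol$constraint), collapse = "\n")))
  }
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else list()
  manifest$package <- as.character(utils::packageVersion("semseason"))
  manifest$config_hash <- rlang::hash(unclass(config))
  manifest$seed <- if (!is.null(config$simulation)) config$simulation$seed
                   else config$seed
  counts <- manifest$stage_counts
  if (is.null(counts)) counts <- list()

  run_stage <- function(name, fn) {
    if (!name %in% stages) return(invisible())
    res <- tryCatch(fn(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    counts[[name]] <<- res
    inform(sprintf("stage %s: %s", name,
                   paste(names(res), unlist(res), sep = "=", collapse = " ")))
  }
  p <- stage_inputs(config, out_dir)

  run_stage("simulate", function() {
    if (is.null(config$simulation)) return(list(skipped = 1L))
    sim <- simulate_dataset(config$simulation)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(sim$genome), p$genome)
    write_annotation(sim$annotation, p$gff3, p$bed)
    reports <- series_to_reports(sim$series)
    for (t in seq_along(reports)) write_cytosine_report(reports[[t]], p$reports[t])
    if (!is.null(sim$expression)) write_expression(sim$expression, p$expression)
    ts <- sim$truth$sites |> mutate(peak_date = as.character(.data$peak_date))
    n1 <- write_stage_tsv(ts, p$truth_sites)
    n2 <- write_stage_tsv(sim$truth$genes, p$truth_genes)
    list(sites = n1, genes = n2, dates = length(p$reports))
  })

  run_stage("profile", function() {
    ga <- load_stage_annotation(p, config)
    series <- load_stage_series(p)
    spike <- config$spike_seq_id
    has_spike <- !is.null(spike) && spike %in% series$sites$seq_id
    excl <- if (has_spike) spike else NULL
    bulk <- bulk_levels(series, exclude_seq = excl)
    n1 <- write_stage_tsv(bulk, file.path(out_dir, "bulk.tsv"))
    wp <- window_profiles(series, ga$annotation, config$window_size,
                          exclude_seq = excl)
    n2 <- write_stage_tsv(wp, file.path(out_dir, "windows.tsv"))
    n3 <- 0L
    if (has_spike) {
      cr <- conversion_rate(series, spike)
      n3 <- write_stage_tsv(cr, file.path(out_dir, "conversion.tsv"))
    }
    n4 <- 0L
    if (nrow(ga$annotation$repeats) > 0) {
      fs <- suppressMessages(
        feature_series(series, ga$annotation, "repeat", context = "CHH"))
      n4 <- write_stage_tsv(fs, file.path(out_dir, "features.tsv"))
      write_stage_tsv(family_medians(fs),
                      file.path(out_dir, "family_medians.tsv"))
    }
    list(bulk = n1, windows = n2, conversion = n3, features = n4)
  })

  run_stage("semc", function() {
    ga <- load_stage_annotation(p, config)
    series <- load_stage_series(p)
    excl <- if (!is.null(config$spike_seq_id) &&
                config$spike_seq_id %in% series$sites$seq_id)
      config$spike_seq_id else NULL
    res <- detect_semcs(series, ga$annotation, alpha = config$alpha,
                        fdr_max = config$fdr_max, min_cov = config$min_cov,
                        correction = config$correction,
                        method = config$method, exclude_seq = excl)
    calls <- res$calls |> mutate(peak_date = as.character(.data$peak_date))
    n1 <- write_stage_tsv(calls, file.path(out_dir, "semcs.tsv"))
    summ <- semc_counts(res) |>
      left_join(
        res$calls |> filter(.data$is_semc) |>
          count(.data$context, .data$peak_month) |>
          pivot_wider(names_from = "peak_month", values_from = "n",
                      values_fill = 0L),
        by = "context")
    write_stage_tsv(summ, file.path(out_dir, "semc_summary.tsv"))
    n_semc <- sum(res$calls$is_semc)
    if (n_semc >= 2) {
      cl <- cluster_semcs(res, max_leaves = config$cluster_max,
                          seed = config$seed)
      writeLines(cl$newick, file.path(out_dir, "dendrogram.nwk"))
    }
    list(tested = n1, semcs = n_semc)
  })

  run_stage("gbm", function() {
    if (is.null(p$expression) || !file.exists(p$expression)) {
      return(list(skipped = 1L))
    }
    ga <- load_stage_annotation(p, config)
    series <- load_stage_series(p)
    gbm <- suppressMessages(gene_body_methylation(series, ga$annotation))
    n1 <- write_stage_tsv(gbm, file.path(out_dir, "gbm.tsv"))
    expr <- read_expression(p$expression)
    ss <- seasonal_summary(expr, smooth_window = config$smooth_window)
    write_stage_tsv(ss, file.path(out_dir, "seasonal_summary.tsv"))
    bins <- quintile_bins(gbm, ss, expressed_min = config$expressed_min)
    n2 <- write_stage_tsv(bins, file.path(out_dir, "bins.tsv"))
    sizes <- table(bins$bin)
    if (length(sizes) >= 2 && all(sizes >= 2)) {
      gt <- groupwise_tests(bins, value = "range", group = "bin",
                            alpha = 0.01, adjust = config$adjust)
      write_stage_tsv(tidy(gt), file.path(out_dir, "tests.tsv"))
      write_stage_tsv(gt$letters, file.path(out_dir, "letters.tsv"))
    } else {
      inform("too few genes per bin for pairwise tests; tests.tsv skipped")
      write_stage_tsv(tibble(), file.path(out_dir, "tests.tsv"))
    }
    assoc <- association_analysis(bins)
    write_stage_tsv(tidy(assoc), file.path(out_dir, "association.tsv"))
    list(genes = n1, binned = n2,
         spearman = round(assoc$spearman$estimate, 6))
  })

  manifest$stage_counts <- counts
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Build a pipeline config from a flat key=value file
#'
#' Lines `key = value` (or `key=value`; `#` comments allowed). Keys that match
#' [simulation_config()] arguments go to the simulation block; the rest to
#' [pipeline_config()]. `overrides` (a named list) wins over the file.
#'
#' @param path Config file path, or `NULL` for defaults only.
#' @param overrides Named list of overriding values.
#' @return A [pipeline_config()].
#' @export
pipeline_config_from_file <- function(path = NULL, overrides = list()) {
  kv <- list()
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[grepl("=", lines)])
    for (ln in lines) {
      parts <- strsplit(ln, "\\s*=\\s*", perl = TRUE)[[1]]
      key <- parts[1]
      val <- paste(parts[-1], collapse = "=")
      num <- suppressWarnings(as.numeric(val))
      kv[[key]] <- if (!is.na(num)) num else val
    }
  }
  kv[names(overrides)] <- overrides
  sim_args <- kv[names(kv) %in% names(formals(simulation_config))]
  pipe_args <- kv[names(kv) %in% names(formals(pipeline_config))]
  if (length(sim_args) > 0 || length(kv) == 0) {
    pipe_args$simulation <- do.call(simulation_config, sim_args)
  }
  do.call(pipeline_config, pipe_args)
}
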