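# Readers/writers for the formats the pipeline touches, and the in-memory
# containers used downstream.
#
# Coordinate conventions: cytosine reports are 1-based (forward coordinates,
# both strands); annotation intervals are stored 0-based half-open internally
# and converted at the file boundary (GFF3 and BED are converted on import and
# export). A site at 1-based position p occupies 0-based position p - 1.

report_cols <- c("seq_id", "pos", "strand", "n_meth", "n_unmeth",
                 "context", "trinucleotide")

#' Read a per-cytosine methylation count report
#'
#' Parses the 7-column TSV dialect (sequence, 1-based position, strand,
#' methylated count, unmethylated count, context, trinucleotide; comment lines
#' start with `#`), compatible with a Bismark CX-style per-cytosine table with
#' counts in columns 4-5.
#'
#' @param path Path to the TSV file.
#' @param genome Optional genome (named character vector or `DNAStringSet`).
#'   When supplied the context of every record is re-derived from the sequence
#'   and mismatching sites are reported with a warning; the mismatch table is
#'   attached as attribute `"context_mismatches"`.
#' @return A tibble of cytosine records in file order.
#' @export
read_cytosine_report <- function(path, genome = NULL) {
  raw <- readr::read_tsv(path, comment = "#", col_names = report_cols,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) != 7L) abort("cytosine report must have 7 tab-separated columns")
  bad_line <- function(i, what) {
    abort(sprintf("malformed cytosine report '%s', data line %d: %s",
                  path, i, what))
  }
  pos <- suppressWarnings(as.integer(raw$pos))
  nm <- suppressWarnings(as.integer(raw$n_meth))
  nu <- suppressWarnings(as.integer(raw$n_unmeth))
  chk <- function(ok, what) {
    if (any(!ok)) bad_line(which(!ok)[1], what)
  }
  chk(!is.na(pos) & pos >= 1L, "position must be a positive integer")
  chk(!is.na(nm) & nm >= 0L, "n_meth must be a non-negative integer")
  chk(!is.na(nu) & nu >= 0L, "n_unmeth must be a non-negative integer")
  chk(raw$strand %in% c("+", "-"), "unknown strand token")
  chk(raw$context %in% the_contexts, "unknown context token")
  rec <- tibble(seq_id = raw$seq_id, pos = pos, strand = raw$strand,
                n_meth = nm, n_unmeth = nu, context = raw$context,
                trinucleotide = raw$trinucleotide)
  if (!is.null(genome)) {
    derived <- assign_context(genome, rec$seq_id, rec$pos, rec$strand)
    mism <- which(!is.na(derived) & derived != rec$context)
    mismatches <- rec[mism, c("seq_id", "pos", "strand", "context")] |>
      mutate(derived_context = derived[mism])
    if (nrow(mismatches) > 0) {
      warn(sprintf("%d record(s) in '%s' disagree with the genome-derived context (first: %s:%d %s)",
                   nrow(mismatches), path, mismatches$seq_id[1],
                   mismatches$pos[1], mismatches$strand[1]))
    }
    attr(rec, "context_mismatches") <- mismatches
  }
  rec
}

#' Write a per-cytosine methylation count report
#'
#' @param records Tibble with the columns of [read_cytosine_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(records, path) {
  stopifnot(all(report_cols %in% names(records)))
  writeLines(paste0("#", paste(report_cols, collapse = "\t")), path)
  readr::write_tsv(records[report_cols], path, col_names = FALSE,
                   append = TRUE, progress = FALSE)
  invisible(path)
}

site_key <- function(x) paste(x$seq_id, x$pos, x$strand, sep = "\r")

#' Assemble a multi-timepoint methylome series
#'
#' Combines per-date cytosine reports into a single container holding the
#' union of sites with per-date methylated/total count matrices. A site absent
#' from a date's report gets counts (0, 0) at that date; such dates are later
#' removed by coverage filters, never imputed.
#'
#' @param reports List of T cytosine-record tibbles (one per sampling date).
#' @param dates Vector of T strictly increasing sampling dates (`Date` or
#'   coercible); T >= 2.
#' @return A `methylome_series` object: site table (ordered by sequence,
#'   position, strand), `meth` and `total` count matrices (sites x dates), and
#'   the dates.
#' @export
build_series <- function(reports, dates) {
  dates <- as.Date(dates)
  if (length(reports) != length(dates)) {
    abort("one report per date is required")
  }
  if (length(dates) < 2L) abort("a series needs at least two dates")
  if (any(diff(dates) <= 0)) abort("dates must be strictly increasing")
  for (t in seq_along(reports)) {
    k <- site_key(reports[[t]])
    if (anyDuplicated(k)) {
      dup <- reports[[t]][duplicated(k), ]
      abort(sprintf("duplicate site %s:%d %s in report %d",
                    dup$seq_id[1], dup$pos[1], dup$strand[1], t))
    }
  }
  all_sites <- bind_rows(lapply(reports, function(r)
    r[c("seq_id", "pos", "strand", "context")])) |>
    distinct()
  conf <- all_sites |>
    count(.data$seq_id, .data$pos, .data$strand) |>
    filter(.data$n > 1)
  if (nrow(conf) > 0) {
    abort(sprintf("conflicting context across reports at %s:%d %s",
                  conf$seq_id[1], conf$pos[1], conf$strand[1]))
  }
  sites <- arrange(all_sites, .data$seq_id, .data$pos, .data$strand)
  n <- nrow(sites)
  T <- length(dates)
  meth <- matrix(0L, n, T, dimnames = list(NULL, as.character(dates)))
  total <- meth
  keys <- site_key(sites)
  for (t in seq_len(T)) {
    idx <- match(site_key(reports[[t]]), keys)
    meth[idx, t] <- reports[[t]]$n_meth
    total[idx, t] <- reports[[t]]$n_meth + reports[[t]]$n_unmeth
  }
  new_methylome_series(sites, meth, total, dates)
}

new_methylome_series <- function(sites, meth, total, dates) {
  structure(list(sites = sites, meth = meth, total = total, dates = dates),
            class = "methylome_series")
}

#' @export
print.methylome_series <- function(x, ...) {
  cat(sprintf("<methylome_series> %d sites x %d dates (%s .. %s)\n",
              nrow(x$sites), length(x$dates),
              min(x$dates), max(x$dates)))
  print(count(x$sites, .data$context))
  invisible(x)
}

#' Subset a methylome series by site
#'
#' @param series A `methylome_series`.
#' @param seq_ids Keep only these sequences (default all).
#' @param contexts Keep only these contexts (default all).
#' @param exclude_seq Drop these sequences (applied after `seq_ids`).
#' @param index Logical or integer row index into the site table.
#' @return A `methylome_series` with the matching sites.
#' @export
subset_series <- function(series, seq_ids = NULL, contexts = NULL,
                          exclude_seq = NULL, index = NULL) {
  keep <- rep(TRUE, nrow(series$sites))
  if (!is.null(seq_ids)) keep <- keep & series$sites$seq_id %in% seq_ids
  if (!is.null(exclude_seq)) keep <- keep & !series$sites$seq_id %in% exclude_seq
  if (!is.null(contexts)) keep <- keep & series$sites$context %in% contexts
  if (!is.null(index)) {
    sel <- rep(FALSE, nrow(series$sites))
    sel[index] <- TRUE
    keep <- keep & sel
  }
  new_methylome_series(series$sites[keep, , drop = FALSE],
                       series$meth[keep, , drop = FALSE],
                       series$total[keep, , drop = FALSE],
                       series$dates)
}

#' @rdname build_series
#' @param x A `methylome_series`.
#' @param ... Unused.
#' @method tidy methylome_series
#' @export
tidy.methylome_series <- function(x, ...) {
  T <- length(x$dates)
  n <- nrow(x$sites)
  tibble(
    x$sites[rep(seq_len(n), T), ],
    date = rep(x$dates, each = n),
    n_meth = as.integer(x$meth),
    n_unmeth = as.integer(x$total - x$meth)
  )
}

# ---- annotation ------------------------------------------------------------

#' Construct a genome annotation
#'
#' Container for gene, exon, and repeat intervals over named sequences. All
#' intervals use 0-based half-open coordinates. Validates that intervals stay
#' within sequence bounds and that every exon is nested in its gene's span.
#'
#' @param seqlengths Named integer vector of sequence lengths.
#' @param genes Tibble `gene_id`, `seq_id`, `start`, `end`, `strand`.
#' @param exons Tibble `gene_id`, `seq_id`, `start`, `end`.
#' @param repeats Tibble `repeat_id`, `seq_id`, `start`, `end`, `family`.
#' @return A `genome_annotation` object.
#' @export
genome_annotation <- function(seqlengths, genes = NULL, exons = NULL,
                              repeats = NULL) {
  empty <- function(cols) as_tibble(sapply(cols, function(x) {
    if (x %in% c("start", "end")) integer() else character()
  }, simplify = FALSE))
  if (is.null(genes)) genes <- empty(c("gene_id", "seq_id", "start", "end", "strand"))
  if (is.null(exons)) exons <- empty(c("gene_id", "seq_id", "start", "end"))
  if (is.null(repeats)) repeats <- empty(c("repeat_id", "seq_id", "start", "end", "family"))
  check_bounds <- function(tb, what) {
    if (nrow(tb) == 0) return(invisible())
    if (!all(tb$seq_id %in% names(seqlengths)))
      abort(paste(what, "on unknown sequence"))
    len <- seqlengths[tb$seq_id]
    if (any(tb$start < 0 | tb$end > len | tb$start >= tb$end))
      abort(paste(what, "interval outside sequence bounds or empty"))
  }
  check_bounds(genes, "gene")
  check_bounds(exons, "exon")
  check_bounds(repeats, "repeat")
  if (nrow(exons) > 0) {
    j <- left_join(exons, genes, by = c("gene_id", "seq_id"),
                   suffix = c("", ".g"))
    if (any(is.na(j$start.g)))
      abort("exon refers to an unknown gene on its sequence")
    if (any(j$start < j$start.g | j$end > j$end.g))
      abort(sprintf("exon outside its gene span (gene %s)",
                    j$gene_id[which(j$start < j$start.g | j$end > j$end.g)[1]]))
  }
  structure(list(seqlengths = seqlengths, genes = as_tibble(genes),
                 exons = as_tibble(exons), repeats = as_tibble(repeats)),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d sequence(s), %d gene(s), %d exon(s), %d repeat(s)\n",
              length(x$seqlengths), nrow(x$genes), nrow(x$exons),
              nrow(x$repeats)))
  invisible(x)
}

grange_of <- function(tb, seqlengths = NULL) {
  GenomicRanges::GRanges(
    seqnames = tb$seq_id,
    ranges = IRanges::IRanges(start = tb$start + 1L, end = tb$end),
    seqlengths = seqlengths
  )
}

#' Read gene and repeat annotation
#'
#' Imports gene/exon features from GFF3 and repeat intervals from BED6 (the
#' BED name column carries the repeat family as a `Class/Family` string).
#' Repeats shorter than `min_repeat_len` are dropped. Coordinates are
#' converted to the internal 0-based half-open convention.
#'
#' @param gff3_path GFF3 file with `gene` and `exon` features (exon `Parent`
#'   pointing at the gene).
#' @param repeat_bed_path BED file of repeats; may be empty.
#' @param min_repeat_len Minimum repeat length in bp to retain (default 50).
#' @param seqlengths Optional named lengths; when absent they are taken from
#'   `##sequence-region` pragmas, falling back to the maximum end coordinate.
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(gff3_path, repeat_bed_path = NULL,
                            min_repeat_len = 50, seqlengths = NULL) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  if (is.null(seqlengths)) {
    pragma <- grep("^##sequence-region", readLines(gff3_path), value = TRUE)
    if (length(pragma) > 0) {
      f <- strsplit(pragma, "[ \t]+")
      seqlengths <- stats::setNames(
        vapply(f, function(x) as.integer(x[4]), integer(1)),
        vapply(f, function(x) x[2], character(1)))
    } else {
      seqlengths <- tapply(GenomicRanges::end(gr),
                           as.character(GenomicRanges::seqnames(gr)), max)
      seqlengths <- stats::setNames(as.integer(seqlengths), names(seqlengths))
    }
  }
  typ <- as.character(gr$type)
  gtb <- function(sel) tibble(
    seq_id = as.character(GenomicRanges::seqnames(gr[sel])),
    start = GenomicRanges::start(gr[sel]) - 1L,
    end = GenomicRanges::end(gr[sel])
  )
  gsel <- typ == "gene"
  genes <- gtb(gsel) |>
    mutate(gene_id = as.character(gr$ID[gsel]),
           strand = as.character(GenomicRanges::strand(gr[gsel]))) |>
    select("gene_id", "seq_id", "start", "end", "strand")
  esel <- typ == "exon"
  parent <- vapply(as.list(gr$Parent[esel]), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  exons <- gtb(esel) |>
    mutate(gene_id = parent) |>
    select("gene_id", "seq_id", "start", "end")
  repeats <- NULL
  if (!is.null(repeat_bed_path)) {
    has_rows <- length(grep("\\S", readLines(repeat_bed_path))) > 0
    if (has_rows) {
      rb <- rtracklayer::import(repeat_bed_path, format = "bed")
      repeats <- tibble(
        seq_id = as.character(GenomicRanges::seqnames(rb)),
        start = GenomicRanges::start(rb) - 1L,
        end = GenomicRanges::end(rb),
        family = if (!is.null(rb$name)) as.character(rb$name) else NA_character_
      ) |>
        filter(.data$end - .data$start >= min_repeat_len) |>
        mutate(repeat_id = paste0("rep_", dplyr::row_number())) |>
        select("repeat_id", "seq_id", "start", "end", "family")
    }
  }
  genome_annotation(seqlengths, genes, exons, repeats)
}

#' Write an annotation to GFF3 and BED
#'
#' Inverse of [read_annotation()]; used by the simulator and the pipeline.
#'
#' @param annotation A [genome_annotation()].
#' @param gff3_path,bed_path Output paths (`NULL` skips that file).
#' @return Invisibly, the annotation.
#' @export
write_annotation <- function(annotation, gff3_path = NULL, bed_path = NULL) {
  sl <- annotation$seqlengths
  if (!is.null(gff3_path)) {
    g <- annotation$genes
    e <- annotation$exons
    gr_g <- grange_of(g, sl)
    S4Vectors::mcols(gr_g) <- S4Vectors::DataFrame(
      type = "gene", ID = g$gene_id)
    GenomicRanges::strand(gr_g) <- g$strand
    gr_e <- grange_of(e, sl)
    S4Vectors::mcols(gr_e) <- S4Vectors::DataFrame(
      type = "exon",
      ID = paste0(e$gene_id, ".e", stats::ave(seq_len(nrow(e)), e$gene_id,
                                              FUN = seq_along)),
      Parent = e$gene_id)
    rtracklayer::export(c(gr_g, gr_e), gff3_path, format = "gff3")
  }
  if (!is.null(bed_path)) {
    r <- annotation$repeats
    if (nrow(r) > 0) {
      gr_r <- grange_of(r, sl)
      gr_r$name <- r$family
      gr_r$score <- 0L
      rtracklayer::export(gr_r, bed_path, format = "bed")
    } else {
      writeLines(character(), bed_path)
    }
  }
  invisible(annotation)
}

# ---- expression ------------------------------------------------------------

#' Read a gene-by-date expression table
#'
#' Wide TSV: first column `gene_id`, remaining columns one per sampling date
#' (ISO date header), values log2(RPM + 1).
#'
#' @param path Path to the TSV.
#' @return Long tibble `gene_id`, `date`, `expr`.
#' @export
read_expression <- function(path) {
  wide <- readr::read_tsv(path, comment = "#", progress = FALSE,
                          col_types = readr::cols(gene_id = "c", .default = "d"))
  pivot_longer(wide, -"gene_id", names_to = "date", values_to = "expr") |>
    mutate(date = as.Date(.data$date)) |>
    arrange(.data$gene_id, .data$date)
}

#' Write a gene-by-date expression table
#'
#' @param expression Long tibble `gene_id`, `date`, `expr`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expression, path) {
  wide <- expression |>
    mutate(date = as.character(.data$date)) |>
    arrange(.data$gene_id, .data$date) |>
    pivot_wider(names_from = "date", values_from = "expr")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}
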