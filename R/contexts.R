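# Sequence-context assignment for cytosines.
#
# A cytosine's context is read from the two bases downstream of it in the
# 5'->3' direction of its own strand: CG if the next base is G, CHG if the
# next-but-one is G (and the next is not), otherwise CHH (H = A, C or T).
# CG and CHG are symmetric across strands, CHH is not.

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

context_from_trinuc <- function(tri) {
  tri <- toupper(tri)
  b1 <- substr(tri, 1, 1)
  b2 <- substr(tri, 2, 2)
  b3 <- substr(tri, 3, 3)
  ok2 <- b2 %in% c("A", "C", "G", "T")
  ok3 <- b3 %in% c("A", "C", "G", "T")
  out <- rep(NA_character_, length(tri))
  valid <- b1 == "C" & nchar(tri) == 3L & ok2 & ok3
  out[valid & b2 == "G"] <- "CG"
  out[valid & b2 != "G" & b3 == "G"] <- "CHG"
  out[valid & b2 != "G" & b3 != "G"] <- "CHH"
  out
}

genome_as_strings <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) abort("genome sequences must be named")
    toupper(genome)
  } else {
    abort("genome must be a named character vector or a DNAStringSet")
  }
}

#' Assign methylation context to cytosines
#'
#' Determines the CG / CHG / CHH context of a cytosine from the two bases
#' downstream on the cytosine's own strand. For a minus-strand cytosine
#' (a G on the forward reference) the trinucleotide ending at `pos` is
#' reverse-complemented before the rule is applied.
#'
#' @param genome Named character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param seq_id Sequence name (recycled to the length of `pos`).
#' @param pos 1-based positions on the forward coordinate system.
#' @param strand `"+"` or `"-"`, recycled to the length of `pos`.
#'
#' @return Character vector of `"CG"`, `"CHG"`, `"CHH"`, or `NA` when the
#'   trinucleotide runs off the sequence end, contains a non-ACGT base, or the
#'   base at (`pos`, `strand`) is not a cytosine.
#' @export
#' @examples
#' assign_context(c(chr = "CCGG"), "chr", 1:2, "+")
assign_context <- function(genome, seq_id, pos, strand) {
  seqs <- genome_as_strings(genome)
  n <- max(length(seq_id), length(pos), length(strand))
  seq_id <- rep_len(seq_id, n)
  pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(strand, n)
  if (!all(strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  out <- rep(NA_character_, n)
  for (sid in unique(seq_id)) {
    if (!sid %in% names(seqs)) abort(paste0("unknown sequence '", sid, "'"))
    s <- seqs[[sid]]
    len <- nchar(s)
    idx <- which(seq_id == sid)
    bad <- pos[idx] < 1L | pos[idx] > len
    if (any(bad)) {
      abort(sprintf("position %d out of bounds for sequence '%s' (length %d)",
                    pos[idx][bad][1], sid, len))
    }
    fwd <- idx[strand[idx] == "+"]
    if (length(fwd)) {
      tri <- substring(s, pos[fwd], pos[fwd] + 2L)
      out[fwd] <- context_from_trinuc(tri)
    }
    rev <- idx[strand[idx] == "-"]
    if (length(rev)) {
      p <- pos[rev]
      lo <- p - 2L
      tri <- rep(NA_character_, length(p))
      inb <- lo >= 1L
      if (any(inb)) {
        raw <- substring(s, lo[inb], p[inb])
        tri[inb] <- comp_base(vapply(strsplit(raw, NULL), function(x)
          paste(rev(x), collapse = ""), character(1)))
      }
      out[rev] <- context_from_trinuc(tri)
    }
  }
  out
}

#' Enumerate all cytosine sites of a genome
#'
#' Scans both strands of every sequence and returns one row per cytosine with
#' an assignable context (sites whose trinucleotide runs off the sequence end
#' or contains an ambiguity base are excluded from all analyses).
#'
#' @inheritParams assign_context
#' @return A tibble with columns `seq_id`, `pos` (1-based, forward
#'   coordinates), `strand`, `context`, `trinucleotide` (on the cytosine's
#'   strand), ordered by (`seq_id`, `pos`, `strand`).
#' @export
cytosine_sites <- function(genome) {
  seqs <- genome_as_strings(genome)
  res <- lapply(names(seqs), function(sid) {
    s <- seqs[[sid]]
    ch <- strsplit(s, NULL)[[1]]
    len <- length(ch)
    # forward strand: C at p, downstream bases p+1, p+2
    pf <- which(ch == "C")
    pf <- pf[pf + 2L <= len]
    trif <- if (length(pf)) paste0("C", ch[pf + 1L], ch[pf + 2L]) else character()
    ctxf <- context_from_trinuc(trif)
    # minus strand: genomic G at p, downstream bases are complements of p-1, p-2
    pr <- which(ch == "G")
    pr <- pr[pr - 2L >= 1L]
    trir <- if (length(pr))
      paste0("C", comp_base(ch[pr - 1L]), comp_base(ch[pr - 2L])) else character()
    ctxr <- context_from_trinuc(trir)
    tibble(
      seq_id = sid,
      pos = c(pf, pr),
      strand = rep(c("+", "-"), c(length(pf), length(pr))),
      context = c(ctxf, ctxr),
      trinucleotide = c(trif, trir)
    )
  })
  bind_rows(res) |>
    filter(!is.na(.data$context)) |>
    arrange(.data$seq_id, .data$pos, .data$strand)
}
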