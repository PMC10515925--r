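#' @import data.table
#' @importFrom stats rnorm runif rbinom sd quantile median setNames
#' @importFrom utils head tail packageVersion
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", "chrom", "pos", "ref", "alt", "het", "phased", "var_class",
  "var_length", "start", "end", "read_id", "hap", "mapq", "cigar", "call",
  "anchor", "depth", "base", "window_start", "window_end", "bias_score",
  "label", "score", "i.start", "i.end", "eff_start", "eff_end", "site_idx",
  "N", "mate", "foot_start", "foot_end", "keep", "group", "cohort_id",
  "disregarded", "A", "C", "G", "T", "is_snv", "is_nd", "covered", "RD",
  "VD", "ND", "z_rd", "z_vd", "z_nd", "n_ref", "n_alt", "n_both", "n_other",
  "t_cover", "t_disjoint", "t_start", "t_end", "n_mb", "n_truth", "n_aln",
  "SB", "MB", "NMB", "NAB", "NAB_naive", "AB", "AB_context", "AB_naive",
  "avg_mapq", "n_mismapped", "category", "type", "stratum", "x", "y",
  "region_idx", "frac_improved", "improved", "low_depth", "inside",
  "score_mul", "score_add", "reason", "aln_idx", "biased", "seq",
  "strand", "..cols"
))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a CIGAR string into operation lengths and codes
#'
#' @param cigar a single CIGAR string, e.g. `"50M2D100M"`.
#' @return list with integer vector `len` and character vector `op`.
#' @keywords internal
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(list(len = integer(0), op = character(0)))
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  n <- length(toks)
  list(
    len = as.integer(substr(toks, 1L, nchar(toks) - 1L)),
    op  = substr(toks, nchar(toks), nchar(toks))
  )
}

# Reference span consumed by a CIGAR (M/D/N/=/X ops)
cigar_ref_width <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$len[cg$op %in% c("M", "D", "N", "=", "X")])
}

# vectorised reference width, caching unique CIGARs (fixtures reuse e.g. "150M")
cigar_ref_width_v <- function(cigars) {
  u <- unique(cigars)
  w <- vapply(u, cigar_ref_width, integer(1))
  w[match(cigars, u)]
}

#' Map a reference position to a read offset through an alignment
#'
#' Walks the CIGAR of an alignment starting at `pos` and returns the 1-based
#' offset in the read sequence aligned to reference position `ref_pos`.
#' Positions falling inside a deletion map to the next aligned read base
#' (`side = "right"`, used for left anchors) or the previous one
#' (`side = "left"`, used for right anchors). Returns `NA` when `ref_pos`
#' lies outside the aligned reference span.
#'
#' @param pos 1-based leftmost reference position of the alignment.
#' @param cigar CIGAR string.
#' @param ref_pos reference position to map.
#' @param side which neighbouring base to return from inside a deletion.
#' @return integer read offset or `NA`.
#' @keywords internal
ref_to_read_offset <- function(pos, cigar, ref_pos, side = c("right", "left")) {
  side <- match.arg(side)
  cg <- parse_cigar(cigar)
  rpos <- pos           # next reference position
  qoff <- 1L            # next read offset
  if (ref_pos < pos) return(NA_integer_)
  for (i in seq_along(cg$op)) {
    op <- cg$op[i]; len <- cg$len[i]
    if (op %in% c("M", "=", "X")) {
      if (ref_pos < rpos + len) return(qoff + (ref_pos - rpos))
      rpos <- rpos + len; qoff <- qoff + len
    } else if (op %in% c("D", "N")) {
      if (ref_pos < rpos + len) {
        return(if (side == "right") qoff else qoff - 1L)
      }
      rpos <- rpos + len
    } else if (op %in% c("I", "S")) {
      qoff <- qoff + len
    }
  }
  NA_integer_
}

#' Read bases aligned over a reference interval
#'
#' Returns the read subsequence whose aligned reference coordinates fall in
#' `[s, e]`, honouring the aligner's gap placement: deleted reference bases
#' contribute nothing, and inserted bases anchored at `[s, max(s, e - 1)]`
#' (for an insertion-site footprint, at `s` itself) are included. `NA` when
#' the alignment does not fully span `[s, e]`.
#'
#' @keywords internal
aligned_seq_over <- function(pos, cigar, seq, s, e) {
  cg <- parse_cigar(cigar)
  ref_end <- pos + sum(cg$len[cg$op %in% c("M", "D", "N", "=", "X")]) - 1L
  if (s < pos || e > ref_end) return(NA_character_)
  ins_anchor_max <- max(s, e - 1L)
  rpos <- pos; qoff <- 1L
  out <- character(0)
  for (i in seq_along(cg$op)) {
    op <- cg$op[i]; len <- cg$len[i]
    if (op %in% c("M", "=", "X")) {
      lo <- max(rpos, s); hi <- min(rpos + len - 1L, e)
      if (lo <= hi) {
        q1 <- qoff + (lo - rpos); q2 <- qoff + (hi - rpos)
        out <- c(out, substr(seq, q1, q2))
      }
      rpos <- rpos + len; qoff <- qoff + len
    } else if (op %in% c("D", "N")) {
      rpos <- rpos + len
    } else if (op == "I") {
      anchor <- rpos - 1L
      if (anchor >= s && anchor <= ins_anchor_max) {
        out <- c(out, substr(seq, qoff, qoff + len - 1L))
      }
      qoff <- qoff + len
    } else if (op == "S") {
      qoff <- qoff + len
    }
  }
  paste0(out, collapse = "")
}

rev_comp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Deterministic TSV writer
#' @param x data.frame/data.table
#' @param path output path
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA", eol = "\n")
  invisible(path)
}

read_tsv <- function(path) data.table::fread(path, sep = "\t", na.strings = "NA")

#' Write a FASTA file
#' @param seqs named character vector of sequences
#' @param path output path
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*", "", names(x)))
}
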