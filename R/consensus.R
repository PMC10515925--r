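#' Diploid consensus haplotypes with coordinate maps
#'
#' Applies the phased alleles of each haplotype to the reference, producing the
#' two donor haplotype sequences together with exact piecewise coordinate maps.
#' A map is a `data.table` of maximal gapless aligned blocks with columns
#' `ref_start`, `ref_end`, `hap_start`, `hap_end` (1-based closed). Reference
#' bases absent from the haplotype (deletions) fall between consecutive blocks
#' on the reference axis; inserted haplotype bases fall between consecutive
#' blocks on the haplotype axis and are anchored at the reference base
#' preceding them.
#'
#' @param reference named character vector of chromosome sequences.
#' @param variants non-overlapping phased variant table.
#' @return list of two haplotypes, each `list(hap_id=, seq=, map=)` where
#'   `seq` and `map` are named by chromosome.
#' @export
build_diploid_consensus <- function(reference, variants) {
  lapply(1:2, function(h) {
    seqs <- list(); maps <- list()
    for (cn in names(reference)) {
      res <- apply_haplotype(reference[[cn]], variants[chrom == cn], h, cn)
      seqs[[cn]] <- res$seq; maps[[cn]] <- res$map
    }
    list(hap_id = h, seq = unlist(seqs), map = maps)
  })
}

apply_haplotype <- function(refseq, vars, hap, chrom_name) {
  ref_len <- nchar(refseq)
  gt_col <- if (hap == 1L) "gt1" else "gt2"
  v <- vars[order(pos)]
  pieces <- character(0)
  blocks <- list()
  cursor <- 1L; hcursor <- 1L
  blk_rs <- 1L; blk_hs <- 1L
  bi <- 0L
  for (j in seq_len(nrow(v))) {
    vr <- v$ref[j]; p <- v$pos[j]
    if (substr(refseq, p, p + nchar(vr) - 1L) != vr)
      stop("variant at ", chrom_name, ":", p, " REF allele '", vr,
           "' does not match the reference")
    if (v[[gt_col]][j] == 0L) next
    al <- v$alt[j]
    lr <- nchar(vr); la <- nchar(al)
    pre <- substr(refseq, cursor, p - 1L)
    pieces <- c(pieces, pre, al)
    if (lr == la) {            # SNV/MNV: alignment blocks uninterrupted
      cursor <- p + lr; hcursor <- hcursor + nchar(pre) + la
      next
    }
    m0 <- min(lr, la)          # shared (left-anchored) aligned prefix
    blk_re <- p + m0 - 1L
    blk_he <- hcursor + nchar(pre) + m0 - 1L
    if (blk_re >= blk_rs) {
      bi <- bi + 1L
      blocks[[bi]] <- c(blk_rs, blk_re, blk_hs, blk_he)
    }
    cursor <- p + lr
    hcursor <- hcursor + nchar(pre) + la
    blk_rs <- cursor; blk_hs <- hcursor
  }
  tailpiece <- substr(refseq, cursor, ref_len)
  pieces <- c(pieces, tailpiece)
  hap_len <- hcursor + nchar(tailpiece) - 1L
  if (ref_len >= blk_rs) {
    bi <- bi + 1L
    blocks[[bi]] <- c(blk_rs, ref_len, blk_hs, hap_len)
  }
  map <- if (bi == 0L) {
    data.table(ref_start = integer(), ref_end = integer(),
               hap_start = integer(), hap_end = integer())
  } else {
    as.data.table(do.call(rbind, blocks))
  }
  setnames(map, c("ref_start", "ref_end", "hap_start", "hap_end"))
  list(seq = paste0(pieces, collapse = ""), map = map)
}

#' Lift haplotype intervals to reference coordinates
#'
#' Vectorised over intervals. Positions inside an insertion are clamped to the
#' flanking aligned blocks; intervals entirely inside an insertion lift to
#' `NA`.
#'
#' @param map coordinate map for one chromosome.
#' @param s,e 1-based closed haplotype intervals.
#' @return data.table with `ref_start`, `ref_end` (NA when unmappable).
#' @export
lift_hap_to_ref <- function(map, s, e) {
  i1 <- findInterval(s, map$hap_start)
  i2 <- findInterval(e, map$hap_start)
  n <- nrow(map)
  rs <- ifelse(i1 == 0L, map$ref_start[1],
        ifelse(s <= map$hap_end[pmax(i1, 1L)],
               map$ref_start[pmax(i1, 1L)] + (s - map$hap_start[pmax(i1, 1L)]),
               map$ref_start[pmin(i1 + 1L, n)]))
  # when s is in the insertion gap after the last block, there is no block right
  rs[i1 >= 1L & s > map$hap_end[pmax(i1, 1L)] & i1 >= n] <- NA_integer_
  re <- ifelse(i2 == 0L, NA_integer_,
        ifelse(e <= map$hap_end[pmax(i2, 1L)],
               map$ref_start[pmax(i2, 1L)] + (e - map$hap_start[pmax(i2, 1L)]),
               map$ref_end[pmax(i2, 1L)]))
  bad <- is.na(rs) | is.na(re) | rs > re
  rs[bad] <- NA_integer_; re[bad] <- NA_integer_
  data.table(ref_start = as.integer(rs), ref_end = as.integer(re))
}

#' Lift reference intervals to haplotype coordinates
#'
#' The lifted interval covers all haplotype bases aligned inside `[s, e]` plus
#' any inserted bases anchored at a reference position in `[s, e]` (so the
#' footprint of a VCF-style insertion lifts to the full inserted allele).
#' Positions inside a deletion are clamped to the surviving flanks.
#'
#' @inheritParams lift_hap_to_ref
#' @param s,e 1-based closed reference intervals.
#' @return data.table with `hap_start`, `hap_end`.
#' @export
lift_ref_to_hap <- function(map, s, e) {
  i1 <- findInterval(s, map$ref_start)
  i2 <- findInterval(e, map$ref_start)
  n <- nrow(map)
  hs <- ifelse(i1 == 0L, map$hap_start[1],
        ifelse(s <= map$ref_end[pmax(i1, 1L)],
               map$hap_start[pmax(i1, 1L)] + (s - map$ref_start[pmax(i1, 1L)]),
               map$hap_start[pmin(i1 + 1L, n)]))
  hs[i1 >= 1L & s > map$ref_end[pmax(i1, 1L)] & i1 >= n] <- NA_integer_
  he <- ifelse(i2 == 0L, NA_integer_,
        ifelse(e <= map$ref_end[pmax(i2, 1L)],
               map$hap_start[pmax(i2, 1L)] + (e - map$ref_start[pmax(i2, 1L)]),
               map$hap_end[pmax(i2, 1L)]))
  # include insertions anchored at ref positions in [s, e]: an insertion after
  # block i is anchored at map$ref_end[i]; extend the end when applicable
  if (n > 1L) {
    anch <- map$ref_end[-n]
    gap_after <- map$hap_start[-1L] - map$hap_end[-n] - 1L
    for (k in which(gap_after > 0L)) {
      idx <- which(!is.na(he) & anch[k] >= s & anch[k] <= e & he == map$hap_end[k])
      he[idx] <- map$hap_end[k] + gap_after[k]
    }
  }
  bad <- is.na(hs) | is.na(he) | hs > he
  hs[bad] <- NA_integer_; he[bad] <- NA_integer_
  data.table(hap_start = as.integer(hs), hap_end = as.integer(he))
}
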