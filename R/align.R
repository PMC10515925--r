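#' Place truth-tagged reads at their true origin ("perfect aligner")
#'
#' Every read is placed at its lifted reference origin with the CIGAR implied
#' by the variants it spans and maximum mapping quality. This is the zero-bias
#' baseline used in property tests: mapping balance equals simulation balance
#' at every site by construction. Reads starting or ending inside an inserted
#' segment get soft-clipped ends; reads entirely inside an insertion are
#' unalignable and are dropped (counted in attribute `n_unmapped`).
#'
#' @param reads `reads` table from [simulate_reads()].
#' @param haps diploid consensus from [build_diploid_consensus()].
#' @param max_mapq MAPQ assigned to every alignment (default 42).
#' @return alignment `data.table`: `read_id`, `chrom`, `pos`, `mapq`, `cigar`,
#'   `seq` (forward reference strand), `strand`, `mate`.
#' @export
perfect_align <- function(reads, haps, max_mapq = 42L) {
  out <- vector("list", 0L)
  n_unmapped <- 0L
  for (h in 1:2) {
    hap <- haps[[h]]
    for (cn in names(hap$seq)) {
      sub <- reads[hap == h & chrom == cn]
      if (nrow(sub) == 0L) next
      map <- hap$map[[cn]]
      i1 <- findInterval(sub$start, map$hap_start)
      simple <- i1 >= 1L & sub$end <= map$hap_end[pmax(i1, 1L)] &
        sub$start >= map$hap_start[pmax(i1, 1L)]
      res <- copy(sub)
      res[, `:=`(pos = NA_integer_, cigar = NA_character_)]
      if (any(simple)) {
        ii <- i1[simple]
        res[simple, pos := map$ref_start[ii] + (sub$start[simple] - map$hap_start[ii])]
        res[simple, cigar := paste0(nchar(seq), "M")]
      }
      hard <- which(!simple)
      for (k in hard) {
        w <- walk_map_cigar(map, sub$start[k], sub$end[k])
        if (is.null(w)) { n_unmapped <- n_unmapped + 1L; next }
        res[k, `:=`(pos = w$pos, cigar = w$cigar)]
      }
      out[[length(out) + 1L]] <- res[!is.na(pos)]
    }
  }
  aln <- rbindlist(out)
  aln[, mapq := as.integer(max_mapq)]
  aln <- aln[, .(read_id, chrom, pos, mapq, cigar, seq, strand, mate)]
  setkey(aln, chrom, pos)
  setattr(aln, "n_unmapped", n_unmapped)
  aln[]
}

# CIGAR of a haplotype interval [s, e] projected through a coordinate map
walk_map_cigar <- function(map, s, e) {
  i1 <- max(findInterval(s, map$hap_start), 1L)
  ops <- character(0); lens <- integer(0)
  push <- function(op, len) {
    if (len > 0L) { ops <<- c(ops, op); lens <<- c(lens, len) }
  }
  cur <- s; pos <- NA_integer_; prev_re <- NA_integer_
  for (i in seq(i1, nrow(map))) {
    hs <- map$hap_start[i]; he <- map$hap_end[i]
    rs <- map$ref_start[i]; re <- map$ref_end[i]
    if (hs > e) break
    if (cur < hs) {                       # inserted bases before this block
      push(if (is.na(pos)) "S" else "I", hs - cur)
      cur <- hs
    }
    lo <- max(cur, hs); hi <- min(e, he)
    if (lo > hi) next
    if (is.na(pos)) {
      pos <- rs + (lo - hs)
    } else {
      push("D", rs - prev_re - 1L)        # deleted reference bases in between
    }
    push("M", hi - lo + 1L)
    prev_re <- rs + (hi - hs)
    cur <- hi + 1L
  }
  if (is.na(pos)) return(NULL)            # read lies entirely in an insertion
  if (cur <= e) push("S", e - cur + 1L)   # trailing inserted bases
  list(pos = pos, cigar = paste0(paste0(lens, ops), collapse = ""))
}

#' Write an alignment table as SAM text
#' @param aln alignment table.
#' @param contigs named integer vector of contig lengths.
#' @param path output path.
#' @export
write_sam <- function(aln, contigs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  x <- aln[order(chrom, pos)]
  # paired + proper pair (mpileup skips "orphan" pairs by default) + mate bits
  flag <- 3L + ifelse(x$mate == 1L, 64L, 128L) +
    ifelse(x$strand == "-", 16L, 32L)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  x$read_id, flag, x$chrom, x$pos, x$mapq, x$cigar,
                  x$seq, strrep("I", nchar(x$seq)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read SAM text into an alignment table
#' @param path SAM path.
#' @return alignment table as produced by [perfect_align()].
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L)
    return(data.table(read_id = character(), chrom = character(),
                      pos = integer(), mapq = integer(), cigar = character(),
                      seq = character(), strand = character(), mate = integer()))
  f <- tstrsplit(lines, "\t", fixed = TRUE, keep = 1:10)
  flag <- as.integer(f[[2]])
  dt <- data.table(
    read_id = f[[1]], chrom = f[[3]], pos = as.integer(f[[4]]),
    mapq = as.integer(f[[5]]), cigar = f[[6]], seq = toupper(f[[10]]),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mate = ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L)
  )
  setkey(dt, chrom, pos)
  dt[]
}

#' Inject a bias scenario into an alignment set
#'
#' Four modes construct the canonical bias signatures on top of a perfect
#' alignment, for classifier and scan testing:
#' \describe{
#'   \item{`drop_alt`}{loss: removes a fraction of the reads that truly carry
#'     the ALT allele at `site` (they "failed to align").}
#'   \item{`add_mismapped`}{flux/local: relocates `n` distant reads onto the
#'     site with low MAPQ and REF-haplotype sequence (paralog-like gain), and
#'     scrambles the variant window of `corrupt_alt` ALT reads so they tally
#'     as OTHER. The net effect is NMB ~ 0 with NAB pushed toward REF, the
#'     geometry of flux (mismapped > 5) or local (otherwise).}
#'   \item{`shift_gap`}{local: moves the indel gap of reads overlapping a
#'     tandem-repeat variant `shift` bp deeper into the tract without
#'     changing the mapped span - an equally scoring alignment the naive
#'     tally misreads.}
#'   \item{`collapse_duplication`}{scan: relocates all reads starting in
#'     `src = c(start, end)` onto the homologous segment at `dest_start`,
#'     emulating a duplication collapsed onto one reference copy.}
#' }
#'
#' @param aln alignment table (is not modified; a perturbed copy is returned).
#' @param truth truth table from [simulate_reads()].
#' @param mode one of `drop_alt`, `add_mismapped`, `shift_gap`,
#'   `collapse_duplication`.
#' @param site one-row variant table (modes acting at a site).
#' @param haps diploid consensus (needed by `add_mismapped`).
#' @param fraction fraction of ALT reads to drop (`drop_alt`).
#' @param n number of relocated foreign reads (`add_mismapped`).
#' @param foreign_mapq MAPQ given to relocated reads.
#' @param corrupt_alt number of ALT reads to scramble (`add_mismapped`).
#' @param shift left shift in bp (`shift_gap`).
#' @param src,dest_start collapsed segment coordinates
#'   (`collapse_duplication`).
#' @param seed integer seed.
#' @return perturbed alignment table.
#' @export
inject_bias <- function(aln, truth, mode, site = NULL, haps = NULL,
                        fraction = 1.0, n = 6L, foreign_mapq = 0L,
                        corrupt_alt = 0L, shift = NULL,
                        src = NULL, dest_start = NULL, seed = 1L) {
  mode <- match.arg(mode, c("drop_alt", "add_mismapped", "shift_gap",
                            "collapse_duplication"))
  x <- copy(aln)
  switch(mode,
    drop_alt = {
      alt_hap <- if (site$gt1 == 1L) 1L else 2L
      cand <- truth[hap == alt_hap & chrom == site$chrom &
                      !is.na(ref_start) &
                      ref_start <= site$foot_end & ref_end >= site$foot_start,
                    read_id]
      cand <- intersect(cand, x$read_id)
      if (length(cand) == 0L)
        stop("drop_alt: no ALT-haplotype reads overlap ", site$chrom, ":", site$pos)
      withr::with_seed(seed, {
        drop <- sample(cand, max(1L, round(fraction * length(cand))))
      })
      x <- x[!read_id %in% drop]
    },
    add_mismapped = {
      stopifnot(!is.null(haps))
      ref_hap_id <- if (site$gt1 == 0L) 1L else 2L
      rh <- haps[[ref_hap_id]]
      map <- rh$map[[site$chrom]]
      withr::with_seed(seed, {
        # synthesize n REF-haplotype-sequence reads covering the site, but
        # steal identities of reads that truly originate far away
        far <- truth[chrom != site$chrom |
                       abs((ref_start + ref_end) / 2 - site$pos) > 10000]
        far <- far[read_id %in% x$read_id]
        if (nrow(far) < n) stop("add_mismapped: not enough distant reads")
        donor_ids <- sample(far$read_id, n)
        hloc <- lift_ref_to_hap(map, site$foot_start, site$foot_end)
        rl <- nchar(x$seq[1])
        center <- (hloc$hap_start + hloc$hap_end) %/% 2L
        hs <- pmax(1L, center - rl %/% 2L + sample.int(20L, n) - 10L)
        he <- hs + rl - 1L
        newrows <- rbindlist(lapply(seq_len(n), function(k) {
          w <- walk_map_cigar(map, hs[k], he[k])
          data.table(read_id = donor_ids[k], chrom = site$chrom, pos = w$pos,
                     mapq = as.integer(foreign_mapq), cigar = w$cigar,
                     seq = substr(rh$seq[[site$chrom]], hs[k], he[k]),
                     strand = "+", mate = 1L)
        }))
        # the relocated reads replace those reads' original alignments
        x <- x[!read_id %in% donor_ids]
        x <- rbind(x, newrows)
        if (corrupt_alt > 0L) {
          alt_hap <- if (site$gt1 == 1L) 1L else 2L
          vics <- truth[hap == alt_hap & chrom == site$chrom & !is.na(ref_start) &
                          ref_start <= site$foot_start & ref_end >= site$foot_end,
                        read_id]
          vics <- sample(intersect(vics, x$read_id),
                         min(corrupt_alt, length(vics)))
          for (id in vics) {
            i <- which(x$read_id == id & x$chrom == site$chrom)[1]
            o1 <- ref_to_read_offset(x$pos[i], x$cigar[i], site$foot_start - 7L)
            o2 <- ref_to_read_offset(x$pos[i], x$cigar[i], site$foot_end + 7L,
                                     side = "left")
            if (is.na(o1)) o1 <- 1L
            if (is.na(o2)) o2 <- nchar(x$seq[i])
            sq <- x$seq[i]
            win <- substr(sq, o1, o2)
            substr(sq, o1, o2) <- chartr("ACGT", "TGCA", win)  # mismatch everywhere
            x[i, seq := sq]
          }
        }
      })
    },
    shift_gap = {
      stopifnot(!is.null(site), !is.null(shift))
      w <- cigar_ref_width_v(x$cigar)
      hit <- which(x$chrom == site$chrom & x$pos <= site$foot_start &
                     x$pos + w - 1L >= site$foot_end &
                     grepl("[ID]", x$cigar))
      for (i in hit) {
        x[i, cigar := shift_gap_cigar(cigar, shift)]
      }
    },
    collapse_duplication = {
      stopifnot(!is.null(src), !is.null(dest_start))
      off <- src[1] - dest_start
      x[pos >= src[1] & pos <= src[2], pos := pos - as.integer(off)]
      setkey(x, chrom, pos)
    }
  )
  setkey(x, chrom, pos)
  x[]
}

# move the first indel op of a CIGAR `shift` bases deeper into the repeat
# (the VCF - and hence the perfect aligner - left-anchors gaps, so an
# ambiguous aligner's alternative placements lie to the right; inside a
# periodic tract the shifted alignment scores identically)
shift_gap_cigar <- function(cigar, shift) {
  cg <- parse_cigar(cigar)
  gi <- which(cg$op %in% c("I", "D"))[1]
  if (is.na(gi) || gi == 1L || gi == length(cg$op)) return(cigar)
  if (cg$op[gi - 1L] != "M" || cg$op[gi + 1L] != "M") return(cigar)
  if (cg$len[gi + 1L] <= shift) return(cigar)
  cg$len[gi - 1L] <- cg$len[gi - 1L] + shift
  cg$len[gi + 1L] <- cg$len[gi + 1L] - shift
  paste0(paste0(cg$len, cg$op), collapse = "")
}
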