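#' Naive (pileup-trusting) assignment of one read at one site
#'
#' Trusts the aligner's base-level placement. For an SNV the read base aligned
#' at the variant's exact reference coordinate decides REF/ALT; for an indel
#' the read sequence over the variant's reference footprint (with gaps exactly
#' as the aligner reported them) must equal the REF or ALT allele. Anything
#' else - sequencing error, shifted gap placement, a deletion covering the
#' position - is `OTHER`. Never returns `BOTH`.
#'
#' @param pos,cigar,seq alignment fields of the read.
#' @param variant one-row variant table.
#' @return one of `"REF"`, `"ALT"`, `"OTHER"`.
#' @export
naive_assign <- function(pos, cigar, seq, variant) {
  span_end <- pos + cigar_ref_width(cigar) - 1L
  if (pos > variant$foot_end || span_end < variant$foot_start)
    stop("read does not overlap the variant footprint")
  if (variant$var_class == "SNV") {
    b <- aligned_base_at(pos, cigar, seq, variant$pos)
    if (is.na(b)) return("OTHER")
    if (b == variant$ref) return("REF")
    if (b == variant$alt) return("ALT")
    return("OTHER")
  }
  sq <- aligned_seq_over(pos, cigar, seq, variant$foot_start, variant$foot_end)
  if (is.na(sq)) return("OTHER")
  if (sq == variant$ref) return("REF")
  if (sq == variant$alt) return("ALT")
  "OTHER"
}

# the read base aligned exactly at reference position p (NA inside a deletion
# or outside the alignment)
aligned_base_at <- function(pos, cigar, seq, p) {
  cg <- parse_cigar(cigar)
  rpos <- pos; qoff <- 1L
  for (i in seq_along(cg$op)) {
    op <- cg$op[i]; len <- cg$len[i]
    if (op %in% c("M", "=", "X")) {
      if (p < rpos + len && p >= rpos) return(substr(seq, qoff + (p - rpos),
                                                     qoff + (p - rpos)))
      rpos <- rpos + len; qoff <- qoff + len
    } else if (op %in% c("D", "N")) {
      if (p < rpos + len && p >= rpos) return(NA_character_)
      rpos <- rpos + len
    } else if (op %in% c("I", "S")) {
      qoff <- qoff + len
    }
  }
  NA_character_
}

#' Assign all reads at all HET sites with both algorithms
#'
#' Orchestrates the full assignment stage: removes overlapping variants,
#' chains the survivors into cohorts, builds per-site (and per-cohort)
#' allelic contexts, and produces one call per read per site for the
#' requested assigners. Context calls follow the cohort-first strategy for
#' multi-member cohorts.
#'
#' @param aln alignment table.
#' @param variants phased variant table (HETs are assigned; HOM-ALT variants
#'   contribute to flanking sequence via `haps` but are never measured).
#' @param haps diploid consensus from [build_diploid_consensus()].
#' @param flank flank length (default 5).
#' @param distance cohort chaining distance (default 25).
#' @param max_effective effective-variant cap (default 70).
#' @param methods subset of `c("context", "naive")`.
#' @return list with `calls` (data.table: chrom, pos, read_id, call, anchor,
#'   method), `contexts` (named by `chrom:pos`), and `sites` (the measured
#'   HET variant table, with `eff_start`, `eff_end`, `disregarded` columns).
#' @export
assign_reads <- function(aln, variants, haps, flank = 5L, distance = 25L,
                         max_effective = 70L,
                         methods = c("context", "naive")) {
  kept <- remove_overlapping_variants(variants)$kept
  hets <- kept[het == TRUE & phased == TRUE]
  if (nrow(hets) == 0L) {
    hets[, `:=`(cohort_id = integer(0), eff_start = integer(0),
                eff_end = integer(0), disregarded = logical(0))]
    return(list(calls = data.table(chrom = character(), pos = integer(),
                                   read_id = character(), call = character(),
                                   anchor = character(), method = character()),
                contexts = list(), sites = hets[]))
  }
  hets <- build_cohorts(hets, distance = distance)
  ctxs <- vector("list", nrow(hets))
  for (i in seq_len(nrow(hets)))
    ctxs[[i]] <- build_context(hets[i], haps, flank = flank,
                               max_effective = max_effective)
  names(ctxs) <- paste0(hets$chrom, ":", hets$pos)
  hets[, eff_start := vapply(ctxs, function(c) as.integer(c$eff_start), integer(1))]
  hets[, eff_end := vapply(ctxs, function(c) as.integer(c$eff_end), integer(1))]
  hets[, disregarded := vapply(ctxs, function(c) c$disregarded, logical(1))]

  a <- copy(aln)
  a[, end := pos + cigar_ref_width_v(cigar) - 1L]
  setkey(a, chrom, pos, end)
  site_iv <- hets[, .(chrom, start = eff_start, end = eff_end,
                      site_idx = seq_len(.N))]
  setkey(site_iv, chrom, start, end)
  ov <- foverlaps(a[, .(chrom, start = pos, end, aln_idx = seq_len(.N))],
                  site_iv, type = "any", nomatch = NULL)

  calls <- vector("list", 0L)
  for (cid in unique(hets$cohort_id)) {
    midx <- which(hets$cohort_id == cid)
    members <- hets[midx]
    mctx <- ctxs[midx]
    ridx <- sort(unique(ov[site_idx %in% midx, aln_idx]))
    if (length(ridx) == 0L) next
    cctx <- if (length(midx) > 1L) build_cohort_context(members, haps, flank)
            else NULL
    cchrom <- members$chrom[1]
    loc <- vector("list", 4L * length(ridx) * length(midx))
    li <- 0L
    for (ri in ridx) {
      rpos <- a$pos[ri]; rcig <- a$cigar[ri]; rseq <- a$seq[ri]
      rid <- a$read_id[ri]; rend <- a$end[ri]
      if ("context" %in% methods) {
        if (length(midx) > 1L) {
          res <- cohort_assign(rpos, rcig, rseq, cctx, members, mctx)
          for (j in seq_len(nrow(res))) {
            li <- li + 1L
            loc[[li]] <- list(chrom = cchrom, pos = res$pos[j], read_id = rid,
                              call = res$call[j], anchor = res$anchor[j],
                              method = "context")
          }
        } else {
          ctx <- mctx[[1]]
          if (!ctx$disregarded && rpos <= ctx$eff_end && rend >= ctx$eff_start) {
            r <- context_assign(rpos, rcig, rseq, ctx)
            li <- li + 1L
            loc[[li]] <- list(chrom = cchrom, pos = members$pos, read_id = rid,
                              call = r$call, anchor = r$anchor,
                              method = "context")
          }
        }
      }
      if ("naive" %in% methods) {
        for (j in seq_len(nrow(members))) {
          if (rpos > members$foot_end[j] || rend < members$foot_start[j]) next
          nc <- naive_assign(rpos, rcig, rseq, members[j])
          li <- li + 1L
          loc[[li]] <- list(chrom = cchrom, pos = members$pos[j], read_id = rid,
                            call = nc, anchor = "naive", method = "naive")
        }
      }
    }
    if (li > 0L) calls[[length(calls) + 1L]] <- rbindlist(loc[seq_len(li)])
  }
  calls <- if (length(calls)) rbindlist(calls) else
    data.table(chrom = character(), pos = integer(), read_id = character(),
               call = character(), anchor = character(), method = character())
  list(calls = calls, contexts = ctxs, sites = hets)
}
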