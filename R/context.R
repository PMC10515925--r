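#' Build the allelic context of a HET variant
#'
#' The context of an allele is the allele string plus phased flanking sequence
#' (default 5 bp each side) drawn from the donor haplotype that carries the
#' allele, so phased neighbours (including HOM-ALT ones) appear in the flanks.
#' When one allele-with-context is a prefix/suffix/substring of the other -
#' the signature of a tandem repeat - the variant is extended into an
#' "effective variant": rightward while one core string is a prefix of the
#' other, leftward while a suffix, and on the side needing the shorter
#' extension when an interior substring. Variants whose effective core exceeds
#' `max_effective` bp (or that hit a contig end unresolved) are disregarded.
#'
#' @param variant one-row HET phased variant table.
#' @param haps diploid consensus from [build_diploid_consensus()].
#' @param flank flank length in bp (default 5).
#' @param max_effective cap on the effective core length in bp (default 70).
#' @return a context object (list): `chrom`, `pos`, `eff_start`/`eff_end`
#'   (reference coordinates of the effective variant), `extended`,
#'   `disregarded`, `reason`, and per-allele entries `ref`/`alt`, each with
#'   the context string `str`, its left flank length `L_left` and core length
#'   `core_len`.
#' @export
build_context <- function(variant, haps, flank = 5L, max_effective = 70L) {
  stopifnot(nrow(variant) == 1L, variant$het)
  cn <- variant$chrom
  ref_hap <- if (variant$gt1 == 0L) 1L else 2L
  alt_hap <- 3L - ref_hap
  hR <- haps[[ref_hap]]; hA <- haps[[alt_hap]]
  seqR <- hR$seq[[cn]]; seqA <- hA$seq[[cn]]
  mapR <- hR$map[[cn]]; mapA <- hA$map[[cn]]
  fs <- variant$foot_start; fe <- variant$foot_end
  ivR <- lift_ref_to_hap(mapR, fs, fe)
  ivA <- lift_ref_to_hap(mapA, fs, fe)
  rs_R <- ivR$hap_start; re_R <- ivR$hap_end
  rs_A <- ivA$hap_start; re_A <- ivA$hap_end
  lenR <- nchar(seqR); lenA <- nchar(seqA)
  disregarded <- FALSE; reason <- NA_character_
  repeat {
    sR <- substr(seqR, rs_R, re_R)
    sA <- substr(seqA, rs_A, re_A)
    rel_pre <- startsWith(sR, sA) || startsWith(sA, sR)
    rel_suf <- endsWith(sR, sA) || endsWith(sA, sR)
    rel_sub <- rel_pre || rel_suf ||
      (nchar(sR) < nchar(sA) && grepl(sR, sA, fixed = TRUE)) ||
      (nchar(sA) < nchar(sR) && grepl(sA, sR, fixed = TRUE))
    if (!rel_sub) break
    if (max(re_R - rs_R, re_A - rs_A) + 1L > max_effective) {
      disregarded <- TRUE; reason <- "effective_span_exceeds_cap"; break
    }
    dir <- if (rel_pre) "right"
      else if (rel_suf) "left"
      else {
        # interior substring: pick the side with the shorter extension
        nr <- ext_steps_needed(seqR, seqA, rs_R, re_R, rs_A, re_A, "right",
                               max_effective)
        nl <- ext_steps_needed(seqR, seqA, rs_R, re_R, rs_A, re_A, "left",
                               max_effective)
        if (nr <= nl) "right" else "left"
      }
    if (dir == "right") {
      if (re_R >= lenR || re_A >= lenA) {
        disregarded <- TRUE; reason <- "contig_end"; break
      }
      re_R <- re_R + 1L; re_A <- re_A + 1L
    } else {
      if (rs_R <= 1L || rs_A <= 1L) {
        disregarded <- TRUE; reason <- "contig_end"; break
      }
      rs_R <- rs_R - 1L; rs_A <- rs_A - 1L
    }
  }
  eff <- lift_hap_to_ref(mapR, rs_R, re_R)
  mk <- function(hseq, hlen, s, e) {
    lf <- min(flank, s - 1L)
    rf <- min(flank, hlen - e)
    list(str = substr(hseq, s - lf, e + rf),
         L_left = lf, core_len = e - s + 1L,
         truncated = lf < flank || rf < flank)
  }
  list(
    chrom = cn, pos = variant$pos,
    foot_start = fs, foot_end = fe,
    eff_start = eff$ref_start, eff_end = eff$ref_end,
    extended = !(eff$ref_start == fs && eff$ref_end == fe),
    disregarded = disregarded, reason = reason,
    ref = mk(seqR, lenR, rs_R, re_R),
    alt = mk(seqA, lenA, rs_A, re_A),
    ref_hap = ref_hap, alt_hap = alt_hap
  )
}

# steps of one-sided extension until the two core strings stop being
# substring-related (capped); used for the two-sided-ambiguity tie-break
ext_steps_needed <- function(seqR, seqA, rs_R, re_R, rs_A, re_A, dir, cap) {
  lenR <- nchar(seqR); lenA <- nchar(seqA)
  for (k in seq_len(cap + 1L)) {
    if (dir == "right") {
      if (re_R + k > lenR || re_A + k > lenA) return(cap + 1L)
      sR <- substr(seqR, rs_R, re_R + k); sA <- substr(seqA, rs_A, re_A + k)
    } else {
      if (rs_R - k < 1L || rs_A - k < 1L) return(cap + 1L)
      sR <- substr(seqR, rs_R - k, re_R); sA <- substr(seqA, rs_A - k, re_A)
    }
    rel <- startsWith(sR, sA) || startsWith(sA, sR) ||
      endsWith(sR, sA) || endsWith(sA, sR) ||
      (nchar(sR) < nchar(sA) && grepl(sR, sA, fixed = TRUE)) ||
      (nchar(sA) < nchar(sR) && grepl(sA, sR, fixed = TRUE))
    if (!rel) return(k)
  }
  cap + 1L
}

#' Build the joint context of a variant cohort
#'
#' Concatenated per-haplotype strings over the cohort span plus flanks; used
#' to assign reads that span a whole cluster of nearby variants in one
#' comparison.
#'
#' @param members variant table of the cohort's members (one cohort).
#' @param haps diploid consensus.
#' @param flank flank length in bp.
#' @return list with the cohort reference span and per-haplotype context
#'   entries shaped like those of [build_context()].
#' @export
build_cohort_context <- function(members, haps, flank = 5L) {
  cn <- members$chrom[1]
  span_s <- min(members$foot_start); span_e <- max(members$foot_end)
  ctxs <- lapply(1:2, function(h) {
    hseq <- haps[[h]]$seq[[cn]]
    iv <- lift_ref_to_hap(haps[[h]]$map[[cn]], span_s, span_e)
    lf <- min(flank, iv$hap_start - 1L)
    rf <- min(flank, nchar(hseq) - iv$hap_end)
    list(str = substr(hseq, iv$hap_start - lf, iv$hap_end + rf),
         L_left = lf, core_len = iv$hap_end - iv$hap_start + 1L)
  })
  list(chrom = cn, span_start = span_s, span_end = span_e,
       hap1 = ctxs[[1]], hap2 = ctxs[[2]])
}

# compare the read window implied by anchoring a context at read offset `off`
# (offset of the context's first character); returns TRUE/FALSE/NA (no overlap)
ctx_window_match <- function(seq, off, ctx_str) {
  r1 <- max(1L, off)
  c1 <- r1 - off + 1L
  ov <- min(nchar(seq) - r1 + 1L, nchar(ctx_str) - c1 + 1L)
  if (ov <= 0L) return(NA)
  substr(seq, r1, r1 + ov - 1L) == substr(ctx_str, c1, c1 + ov - 1L)
}

# one anchored comparison of both alleles; p_anchor = read offset of the
# context boundary; offs = per-allele offset of the context's first character
anchored_call <- function(seq, off_ref, off_alt, ctx_ref, ctx_alt) {
  mr <- ctx_window_match(seq, off_ref, ctx_ref)
  ma <- ctx_window_match(seq, off_alt, ctx_alt)
  if (is.na(mr) && is.na(ma)) return("NONE")
  mr <- isTRUE(mr); ma <- isTRUE(ma)
  if (mr && ma) "BOTH" else if (mr) "REF" else if (ma) "ALT" else "OTHER"
}

#' Context-aware assignment of one read at one HET site
#'
#' Anchors the read at the left boundary of the effective variant and compares
#' the read window against the REF and ALT allelic context sequences (a prefix
#' or suffix of a context suffices when the read ends inside it); if the left
#' anchor is unavailable or inconclusive the right boundary is tried. Exactly
#' one matching context gives that call; both matching (or conflicting anchors,
#' or a read that does not fully cover a repeat-extended effective variant)
#' give `BOTH`; neither gives `OTHER`. Reads with `N` in the window are
#' `OTHER`.
#'
#' @param pos,cigar,seq alignment fields of the read.
#' @param ctx context object from [build_context()].
#' @return `list(call=, anchor=)` with call in `REF`, `ALT`, `BOTH`, `OTHER`.
#' @export
context_assign <- function(pos, cigar, seq, ctx) {
  if (ctx$disregarded) return(list(call = NA_character_, anchor = "none"))
  span_end <- pos + cigar_ref_width(cigar) - 1L
  if (ctx$extended && !(pos <= ctx$eff_start && span_end >= ctx$eff_end))
    return(list(call = "BOTH", anchor = "none"))
  # N in the searched window -> no exact match possible
  o1 <- ref_to_read_offset(pos, cigar, ctx$eff_start - 7L)
  o2 <- ref_to_read_offset(pos, cigar, ctx$eff_end + 7L, side = "left")
  win <- substr(seq, if (is.na(o1)) 1L else o1,
                if (is.na(o2)) nchar(seq) else o2)
  if (grepl("N", win, fixed = TRUE))
    return(list(call = "OTHER", anchor = "none"))
  p0 <- ref_to_read_offset(pos, cigar, ctx$eff_start)
  call_L <- if (is.na(p0)) "NONE" else
    anchored_call(seq,
                  p0 - ctx$ref$L_left, p0 - ctx$alt$L_left,
                  ctx$ref$str, ctx$alt$str)
  p1 <- ref_to_read_offset(pos, cigar, ctx$eff_end + 1L)
  call_R <- if (is.na(p1)) "NONE" else
    anchored_call(seq,
                  p1 - ctx$ref$L_left - ctx$ref$core_len,
                  p1 - ctx$alt$L_left - ctx$alt$core_len,
                  ctx$ref$str, ctx$alt$str)
  single <- c("REF", "ALT")
  if (call_L %in% single && call_R %in% single && call_L != call_R)
    return(list(call = "BOTH", anchor = "none"))
  if (call_L %in% single) return(list(call = call_L, anchor = "left"))
  if (call_R %in% single) return(list(call = call_R, anchor = "right"))
  if (call_L == "BOTH" || call_R == "BOTH")
    return(list(call = "BOTH", anchor = if (call_L == "BOTH") "left" else "right"))
  list(call = "OTHER", anchor = "none")
}

#' Whole-cohort assignment of one read
#'
#' Tries to match the read against the entire per-haplotype cohort strings,
#' anchored at either cohort end; a unique haplotype match tallies every
#' member variant the read covers with that haplotype's allele. Reads that do
#' not span the cohort, or that match neither/both strings, fall back to
#' per-variant [context_assign()].
#'
#' @param pos,cigar,seq alignment fields of the read.
#' @param cctx cohort context from [build_cohort_context()].
#' @param members the cohort's variant table rows.
#' @param ctxs list of per-member context objects (fallback path).
#' @return data.table with one row per member site the read overlaps:
#'   `pos`, `call`, `anchor`.
#' @export
cohort_assign <- function(pos, cigar, seq, cctx, members, ctxs) {
  span_end <- pos + cigar_ref_width(cigar) - 1L
  covers <- pos <= cctx$span_start && span_end >= cctx$span_end
  if (covers) {
    p0 <- ref_to_read_offset(pos, cigar, cctx$span_start)
    p1 <- ref_to_read_offset(pos, cigar, cctx$span_end + 1L)
    hap_call <- "NONE"
    for (anchor in c("left", "right")) {
      m1 <- m2 <- NA
      if (anchor == "left" && !is.na(p0)) {
        m1 <- ctx_window_match(seq, p0 - cctx$hap1$L_left, cctx$hap1$str)
        m2 <- ctx_window_match(seq, p0 - cctx$hap2$L_left, cctx$hap2$str)
      } else if (anchor == "right" && !is.na(p1)) {
        m1 <- ctx_window_match(seq, p1 - cctx$hap1$L_left - cctx$hap1$core_len,
                               cctx$hap1$str)
        m2 <- ctx_window_match(seq, p1 - cctx$hap2$L_left - cctx$hap2$core_len,
                               cctx$hap2$str)
      }
      if (isTRUE(m1) && !isTRUE(m2)) { hap_call <- "h1"; break }
      if (isTRUE(m2) && !isTRUE(m1)) { hap_call <- "h2"; break }
    }
    if (hap_call != "NONE") {
      h <- if (hap_call == "h1") 1L else 2L
      ov <- members[foot_start <= span_end & foot_end >= pos]
      gt <- if (h == 1L) ov$gt1 else ov$gt2
      return(data.table(pos = ov$pos,
                        call = ifelse(gt == 0L, "REF", "ALT"),
                        anchor = "cohort"))
    }
  }
  # fallback: variant-by-variant
  out <- lapply(seq_along(ctxs), function(i) {
    ctx <- ctxs[[i]]
    if (is.null(ctx) || ctx$disregarded) return(NULL)
    if (pos > ctx$eff_end || span_end < ctx$eff_start) return(NULL)
    r <- context_assign(pos, cigar, seq, ctx)
    data.table(pos = members$pos[i], call = r$call, anchor = r$anchor)
  })
  rbindlist(out[!vapply(out, is.null, logical(1))])
}
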