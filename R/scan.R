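#' Reference-free windowed bias scan
#'
#' Scan mode needs no foreknowledge of the donor's variants: it slides a
#' window (default 400 bp) over a pileup and scores each window on three
#' measures - read depth (RD), SNV density (VD) and non-diploid-position
#' density (ND) - each transformed to a Z-score against a sampled baseline,
#' truncated (Z(RD) < 1 and negative Z(VD)/Z(ND) become 0) and summed into a
#' bias score. Windows with score >= 5 seed "biased" regions, scores in
#' [3, 5) "suspicious" regions; nearby regions of the same label chain
#' together.
#'
#' @name scan-mode
NULL

#' Per-position base counts from an alignment table
#'
#' Tallies the aligned (M) bases of every read per reference position.
#' Deleted positions receive no base; inserted bases are not anchored to any
#' position and are skipped, matching the nucleotide-frequency view of a
#' pileup.
#'
#' @param aln alignment table.
#' @return data.table: `chrom`, `pos`, `depth`, `A`, `C`, `G`, `T`.
#' @export
pileup_from_alignments <- function(aln) {
  if (nrow(aln) == 0L)
    return(data.table(chrom = character(), pos = integer(), depth = integer(),
                      A = integer(), C = integer(), G = integer(),
                      T = integer()))
  u <- unique(aln$cigar)
  blocks_u <- lapply(u, function(cg) {
    p <- parse_cigar(cg)
    rofs <- integer(0); qofs <- integer(0)
    rpos <- 0L; qoff <- 0L
    for (i in seq_along(p$op)) {
      op <- p$op[i]; len <- p$len[i]
      if (op %in% c("M", "=", "X")) {
        rofs <- c(rofs, rpos + seq_len(len) - 1L)
        qofs <- c(qofs, qoff + seq_len(len) - 1L)
        rpos <- rpos + len; qoff <- qoff + len
      } else if (op %in% c("D", "N")) {
        rpos <- rpos + len
      } else if (op %in% c("I", "S")) {
        qoff <- qoff + len
      }
    }
    list(rofs = rofs, qofs = qofs)
  })
  bi <- match(aln$cigar, u)
  nb <- vapply(blocks_u, function(b) length(b$rofs), integer(1))[bi]
  ridx <- rep(seq_len(nrow(aln)), nb)
  rofs <- unlist(lapply(bi, function(i) blocks_u[[i]]$rofs), use.names = FALSE)
  qofs <- unlist(lapply(bi, function(i) blocks_u[[i]]$qofs), use.names = FALSE)
  pos <- aln$pos[ridx] + rofs
  ch <- aln$chrom[ridx]
  base <- substring(aln$seq[ridx], qofs + 1L, qofs + 1L)
  dt <- data.table(chrom = ch, pos = pos, base = base)
  dt <- dt[base %in% c("A", "C", "G", "T")]
  tab <- dcast(dt[, .N, by = .(chrom, pos, base)], chrom + pos ~ base,
               value.var = "N", fill = 0L)
  for (b in c("A", "C", "G", "T"))
    if (!b %in% names(tab)) tab[, (b) := 0L]
  tab[, depth := A + C + G + T]
  setkey(tab, chrom, pos)
  tab[, .(chrom, pos, depth, A, C, G, T)]
}

#' Parse samtools mpileup text (6-column) into base counts
#'
#' Handles `^X` (read start + MAPQ), `$` (read end), `+n`/`-n` indel
#' annotations (skipped: allele calling uses nucleotide frequencies only),
#' `*` placeholders, and `.`/`,` reference matches.
#'
#' @param path path to an mpileup text file.
#' @return data.table like [pileup_from_alignments()].
#' @export
read_mpileup <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.table(chrom = character(), pos = integer(), depth = integer(),
                      A = integer(), C = integer(), G = integer(),
                      T = integer()))
  f <- tstrsplit(lines, "\t", fixed = TRUE)
  chrom <- f[[1]]; pos <- as.integer(f[[2]]); refb <- toupper(f[[3]])
  bases <- f[[5]]
  counts <- t(vapply(seq_along(bases), function(i) {
    count_mpileup_bases(bases[i], refb[i])
  }, integer(4)))
  dt <- data.table(chrom = chrom, pos = pos,
                   A = counts[, 1], C = counts[, 2],
                   G = counts[, 3], T = counts[, 4])
  dt[, depth := A + C + G + T]
  setkey(dt, chrom, pos)
  dt[, .(chrom, pos, depth, A, C, G, T)]
}

count_mpileup_bases <- function(s, refb) {
  out <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  n <- nchar(s); i <- 1L
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "^") { i <- i + 2L; next }           # caret + mapq char
    if (ch == "$" || ch == "*" || ch == ">" || ch == "<") { i <- i + 1L; next }
    if (ch == "+" || ch == "-") {                  # indel: [+-](\d+)(seq)
      j <- i + 1L
      while (j <= n && substr(s, j, j) %in% as.character(0:9)) j <- j + 1L
      k <- as.integer(substr(s, i + 1L, j - 1L))
      i <- j + k; next
    }
    b <- toupper(ch)
    if (b %in% c(".", ",")) b <- refb
    if (b %in% names(out)) out[b] <- out[b] + 1L
    i <- i + 1L
  }
  out
}

#' Call alleles at one pileup column and flag SNV / non-diploid status
#'
#' Bases with frequency strictly greater than `allele_freq` (of the counted
#' A/C/G/T depth) are alleles. A position with two or more alleles is an SNV;
#' an SNV position is non-diploid if three or more alleles pass the
#' threshold, or if the most frequent allele is more than twice as frequent
#' as the second.
#'
#' @param counts integer vector or matrix with columns A, C, G, T.
#' @param allele_freq allele frequency threshold (default 0.15).
#' @return data.table: `alleles` (comma-joined), `is_snv`, `is_nd`.
#' @export
call_position_alleles <- function(counts, allele_freq = 0.15) {
  m <- if (is.matrix(counts)) counts else matrix(counts, nrow = 1L,
         dimnames = list(NULL, names(counts) %||% c("A", "C", "G", "T")))
  depth <- rowSums(m)
  freq <- m / pmax(depth, 1L)
  is_al <- freq > allele_freq & depth > 0L
  n_al <- rowSums(is_al)
  i1 <- max.col(m, ties.method = "first")
  v1 <- m[cbind(seq_len(nrow(m)), i1)]
  m2 <- m; m2[cbind(seq_len(nrow(m)), i1)] <- -1L
  v2 <- m2[cbind(seq_len(nrow(m2)), max.col(m2, ties.method = "first"))]
  is_snv <- n_al >= 2L
  is_nd <- is_snv & (n_al >= 3L | v1 > 2L * v2)
  bases <- colnames(m) %||% c("A", "C", "G", "T")
  alleles <- vapply(seq_len(nrow(m)), function(i) {
    paste0(bases[is_al[i, ]], collapse = ",")
  }, character(1))
  data.table(alleles = alleles, is_snv = is_snv, is_nd = is_nd)
}

#' Raw windowed measures over a pileup
#'
#' Slides windows of `window` bp every `step` bp and computes, per window,
#' the mean depth over covered positions (RD), the SNV-position density (VD)
#' and the non-diploid-position density (ND), both densities per covered
#' base. Windows containing no covered position are skipped.
#'
#' @param pileup base-count table ([pileup_from_alignments()] or
#'   [read_mpileup()]).
#' @param window window width in bp (default 400).
#' @param step window step in bp (default 100).
#' @param allele_freq allele threshold passed to [call_position_alleles()].
#' @return data.table: `chrom`, `window_start`, `window_end`, `covered`,
#'   `RD`, `VD`, `ND`.
#' @export
window_measures <- function(pileup, window = 400L, step = 100L,
                            allele_freq = 0.15) {
  if (nrow(pileup) == 0L)
    return(data.table(chrom = character(), window_start = integer(),
                      window_end = integer(), covered = integer(),
                      RD = numeric(), VD = numeric(), ND = numeric()))
  p <- copy(pileup)
  if (is.unsorted(p$pos) && any(p[, is.unsorted(pos), by = chrom]$V1))
    stop("pileup must be position-sorted within chromosome")
  calls <- call_position_alleles(as.matrix(p[, .(A, C, G, T)]),
                                 allele_freq = allele_freq)
  p[, `:=`(is_snv = calls$is_snv, is_nd = calls$is_nd)]
  out <- p[, window_measures_chrom(.SD, window, step), by = chrom]
  out[]
}

window_measures_chrom <- function(p, window, step) {
  lo <- min(p$pos); hi <- max(p$pos)
  # windows live on the fixed grid 1, 1+step, 1+2*step, ...
  starts <- seq(1L, hi, by = step)
  starts <- starts[starts + window - 1L >= lo & starts <= hi]
  # cumulative sums over a dense position axis
  L <- hi - lo + 1L
  dep <- integer(L); snv <- integer(L); nd <- integer(L); cov <- integer(L)
  idx <- p$pos - lo + 1L
  dep[idx] <- p$depth
  snv[idx] <- as.integer(p$is_snv)
  nd[idx] <- as.integer(p$is_nd)
  cov[idx] <- 1L
  cdep <- cumsum(as.numeric(dep)); csnv <- cumsum(snv)
  cnd <- cumsum(nd); ccov <- cumsum(cov)
  ws <- starts; we <- starts + window - 1L
  a <- pmax(ws - lo + 1L, 1L); b <- pmin(we - lo + 1L, L)
  keep <- a <= b
  ws <- ws[keep]; we <- we[keep]; a <- a[keep]; b <- b[keep]
  sum_rng <- function(cs, a, b) {
    lower <- numeric(length(a))
    lower[a > 1L] <- cs[a[a > 1L] - 1L]
    cs[b] - lower
  }
  ncov <- sum_rng(ccov, a, b)
  keep2 <- ncov > 0L
  data.table(
    window_start = as.integer(ws[keep2]),
    window_end = as.integer(we[keep2]),
    covered = as.integer(ncov[keep2]),
    RD = sum_rng(cdep, a, b)[keep2] / ncov[keep2],
    VD = sum_rng(csnv, a, b)[keep2] / ncov[keep2],
    ND = sum_rng(cnd, a, b)[keep2] / ncov[keep2]
  )
}

#' Estimate baseline mean and standard deviation of the window measures
#'
#' Samples a fraction of the windows (whole windows, so the spread is over
#' the same statistic being scored) and returns the per-measure mean and
#' standard deviation. With two pileup sources the sample is drawn half from
#' each, giving the joint baseline required for workflow comparison.
#'
#' @param pileups one pileup, or a list of one or two pileups.
#' @param fraction fraction of windows to sample (default 1/1000; 1 = all).
#' @param seed integer seed for the window sample.
#' @param window,step,allele_freq window parameters.
#' @return `list(mean=, sd=, n=)` with named numeric vectors over RD/VD/ND.
#' @export
sample_baseline <- function(pileups, fraction = 1 / 1000, seed = 1L,
                            window = 400L, step = 100L, allele_freq = 0.15) {
  stopifnot(fraction > 0, fraction <= 1)
  if (is.data.frame(pileups)) pileups <- list(pileups)
  stopifnot(length(pileups) %in% 1:2)
  wm <- lapply(pileups, window_measures, window = window, step = step,
               allele_freq = allele_freq)
  withr::with_seed(seed, {
    picked <- lapply(seq_along(wm), function(i) {
      n <- nrow(wm[[i]])
      k <- max(2L, min(n, ceiling(fraction * n)))
      wm[[i]][sample.int(n, k)]
    })
  })
  s <- rbindlist(picked)
  m <- c(RD = mean(s$RD), VD = mean(s$VD), ND = mean(s$ND))
  sdv <- c(RD = sd(s$RD), VD = sd(s$VD), ND = sd(s$ND))
  if (any(sdv == 0 | is.na(sdv)))
    stop("baseline standard deviation is zero for ",
         paste(names(sdv)[sdv == 0 | is.na(sdv)], collapse = ", "),
         "; sample more windows or supply explicit parameters")
  list(mean = m, sd = sdv, n = nrow(s))
}

#' Z-score and combine window measures into a bias score
#'
#' `Z = (window - baseline mean) / baseline sd` per measure; `Z(RD)` below 1
#' is truncated to 0 (only depth well above average signals collapse),
#' negative `Z(VD)`/`Z(ND)` are truncated to 0. The bias score is the sum of
#' the three truncated Z-scores.
#'
#' @param wm output of [window_measures()].
#' @param baseline output of [sample_baseline()] (or
#'   `list(mean=, sd=)` with named RD/VD/ND entries).
#' @return `wm` with `z_rd`, `z_vd`, `z_nd`, `bias_score`; the baseline is
#'   attached as attribute `baseline`.
#' @export
combine_scores <- function(wm, baseline) {
  stopifnot(all(baseline$sd > 0))
  x <- copy(wm)
  x[, z_rd := (RD - baseline$mean[["RD"]]) / baseline$sd[["RD"]]]
  x[, z_vd := (VD - baseline$mean[["VD"]]) / baseline$sd[["VD"]]]
  x[, z_nd := (ND - baseline$mean[["ND"]]) / baseline$sd[["ND"]]]
  x[z_rd < 1, z_rd := 0]
  x[z_vd < 0, z_vd := 0]
  x[z_nd < 0, z_nd := 0]
  x[, bias_score := z_rd + z_vd + z_nd]
  setattr(x, "baseline", baseline[c("mean", "sd")])
  x[]
}

#' Call biased and suspicious regions from window scores
#'
#' Windows with `bias_score >= biased_min` merge into "biased" regions,
#' windows in `[susp_min, biased_min)` into "suspicious" regions; regions of
#' the same label within `chain_gap` bp chain into one. Where a chained
#' suspicious interval would overlap a biased one, biased wins.
#'
#' @param scored output of [combine_scores()].
#' @param biased_min biased threshold (default 5).
#' @param susp_min suspicious threshold (default 3).
#' @param chain_gap chaining distance in bp (default 1000).
#' @return data.table: `chrom`, `start`, `end`, `label`, `peak_score`,
#'   `n_windows`; carries the `baseline` attribute of its input.
#' @export
call_regions <- function(scored, biased_min = 5, susp_min = 3,
                         chain_gap = 1000L) {
  mk <- function(sub, label) {
    if (nrow(sub) == 0L) return(NULL)
    out <- lapply(split(sub, sub$chrom), function(s) {
      ir <- IRanges::reduce(IRanges::IRanges(s$window_start, s$window_end),
                            min.gapwidth = chain_gap + 1L)
      data.table(chrom = s$chrom[1], start = IRanges::start(ir),
                 end = IRanges::end(ir), label = label)
    })
    rbindlist(out)
  }
  b <- mk(scored[bias_score >= biased_min], "biased")
  s <- mk(scored[bias_score >= susp_min & bias_score < biased_min],
          "suspicious")
  # biased-over-suspicious where chained intervals of different labels overlap
  if (!is.null(b) && !is.null(s)) {
    ss <- lapply(split(seq_len(nrow(s)), s$chrom), function(ii) {
      bi <- b[chrom == s$chrom[ii[1]]]
      if (nrow(bi) == 0L) return(s[ii])
      d <- IRanges::setdiff(IRanges::IRanges(s$start[ii], s$end[ii]),
                            IRanges::IRanges(bi$start, bi$end))
      if (length(d) == 0L) return(NULL)
      data.table(chrom = s$chrom[ii[1]], start = IRanges::start(d),
                 end = IRanges::end(d), label = "suspicious")
    })
    s <- rbindlist(ss[!vapply(ss, is.null, logical(1))])
  }
  out <- rbindlist(list(b, s))
  if (is.null(out) || nrow(out) == 0L) {
    out <- data.table(chrom = character(), start = integer(), end = integer(),
                      label = character(), peak_score = numeric(),
                      n_windows = integer())
    setattr(out, "baseline", attr(scored, "baseline"))
    return(out[])
  }
  # peak score and member window count per region
  sc <- scored[, .(chrom, start = window_start, end = window_end, bias_score)]
  setkey(sc, chrom, start, end)
  rk <- copy(out); rk[, region_idx := seq_len(.N)]
  setkey(rk, chrom, start, end)
  ov <- foverlaps(sc, rk, type = "any", nomatch = NULL)
  stats <- ov[, .(peak_score = max(bias_score), n_windows = .N),
              by = region_idx]
  out[, `:=`(peak_score = NA_real_, n_windows = 0L)]
  out[stats$region_idx, `:=`(peak_score = stats$peak_score,
                             n_windows = stats$n_windows)]
  setkey(out, chrom, start)
  setattr(out, "baseline", attr(scored, "baseline"))
  out[]
}

#' Compare biased regions between two alignment workflows
#'
#' For each region biased in one workflow, counts the bases that in the other
#' workflow are both well covered (depth over `depth_frac` of the overall
#' mean) and outside that workflow's biased regions; the region is "improved"
#' when at least `improve_frac` of its bases qualify. Both runs must have
#' been scored against the same jointly sampled baseline. Regions poorly
#' covered in both workflows are flagged `low_depth` and excluded from the
#' improvement tallies.
#'
#' @param regions_a,regions_b region tables from [call_regions()].
#' @param pileup_a,pileup_b base-count tables of the two workflows.
#' @param improve_frac base fraction required to call improvement
#'   (default 0.25).
#' @param depth_frac well-covered threshold as a fraction of the overall mean
#'   depth (default 0.2, i.e. 1/5).
#' @return `list(a_improved_by_b=, b_improved_by_a=, summary=)`; the region
#'   tables gain `frac_improved`, `improved` and `low_depth` columns.
#' @export
compare_runs <- function(regions_a, regions_b, pileup_a, pileup_b,
                         improve_frac = 0.25, depth_frac = 0.2) {
  ba <- attr(regions_a, "baseline"); bb <- attr(regions_b, "baseline")
  if (!is.null(ba) && !is.null(bb) && !identical(ba, bb))
    stop("the two runs were scored with different baselines; ",
         "use a joint baseline (sample_baseline on both pileups)")
  mean_depth <- mean(c(pileup_a$depth, pileup_b$depth))
  thr <- depth_frac * mean_depth
  eval_dir <- function(regs, other_regs, own_pile, other_pile) {
    regs <- copy(regs[label == "biased"])
    regs[, `:=`(frac_improved = rep(NA_real_, .N),
                improved = rep(NA, .N), low_depth = rep(NA, .N))]
    if (nrow(regs) == 0L) return(regs[])
    for (i in seq_len(nrow(regs))) {
      cn <- regs$chrom[i]; cs <- regs$start[i]; ce <- regs$end[i]
      len <- ce - cs + 1L
      well_other <- other_pile[chrom == cn & pos >= cs & pos <= ce &
                                 depth > thr, pos]
      n_well_own <- own_pile[chrom == cn & pos >= cs & pos <= ce &
                               depth > thr, .N]
      ob <- other_regs[label == "biased" & chrom == cn]
      for (k in seq_len(nrow(ob))) {
        well_other <- well_other[well_other < ob$start[k] |
                                   well_other > ob$end[k]]
      }
      set(regs, i, "frac_improved", length(well_other) / len)
      set(regs, i, "low_depth", n_well_own == 0L && length(well_other) == 0L)
    }
    regs[, improved := !low_depth & frac_improved >= improve_frac]
    regs[]
  }
  a_imp <- eval_dir(regions_a, regions_b, pileup_a, pileup_b)
  b_imp <- eval_dir(regions_b, regions_a, pileup_b, pileup_a)
  list(
    a_improved_by_b = a_imp,
    b_improved_by_a = b_imp,
    summary = data.table(
      direction = c("A_improved_by_B", "B_improved_by_A"),
      n_biased = c(nrow(a_imp), nrow(b_imp)),
      n_improved = c(sum(a_imp$improved), sum(b_imp$improved)),
      n_low_depth = c(sum(a_imp$low_depth), sum(b_imp$low_depth))
    )
  )
}

#' Count features inside or near biased regions
#'
#' A feature counts as "inside" when any base within `margin` bp of its
#' extent intersects a biased region.
#'
#' @param regions region table from [call_regions()].
#' @param features data.table with `chrom`, `start`, `end` (1-based closed;
#'   see [read_bed()]).
#' @param margin proximity margin in bp (default 100).
#' @return the feature table with an `inside` logical column, plus a summary
#'   attribute table `counts`.
#' @export
overlap_features <- function(regions, features, margin = 100L) {
  f <- copy(features)
  b <- regions[label == "biased"]
  f[, inside := FALSE]
  if (nrow(b) > 0L && nrow(f) > 0L) {
    for (cn in unique(f$chrom)) {
      bi <- b[chrom == cn]
      if (nrow(bi) == 0L) next
      ii <- which(f$chrom == cn)
      q <- IRanges::IRanges(pmax(1L, f$start[ii] - margin), f$end[ii] + margin)
      s <- IRanges::IRanges(bi$start, bi$end)
      f$inside[ii] <- IRanges::overlapsAny(q, s)
    }
  }
  counts <- f[, .(n = .N, inside = sum(inside), outside = sum(!inside))]
  setattr(f, "counts", counts)
  f[]
}

#' Read a BED file (0-based half-open) into 1-based closed intervals
#' @param path BED path.
#' @export
read_bed <- function(path) {
  dt <- fread(path, header = FALSE)
  setnames(dt, seq_len(min(4L, ncol(dt))),
           c("chrom", "start", "end", "name")[seq_len(min(4L, ncol(dt)))])
  dt[, start := as.integer(start) + 1L]
  dt[, end := as.integer(end)]
  dt[]
}

#' Write regions as BED (converting to 0-based half-open)
#' @param regions region table.
#' @param path output path.
#' @export
write_bed <- function(regions, path) {
  if (nrow(regions) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%.3f", regions$chrom,
                   regions$start - 1L, regions$end, regions$label,
                   ifelse(is.na(regions$peak_score), 0, regions$peak_score))
  writeLines(lines, path)
  invisible(path)
}
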