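#' Allelic balance at HET sites
#'
#' Three REF-fraction measures are taken per HET site, at three pipeline
#' stages: simulation balance (SB) from the simulator's truth tags, mapping
#' balance (MB) from truth tags plus the alignment, and assignment balance
#' (AB) from an assignment algorithm alone. Their differences NMB = MB - SB
#' and NAB = AB - SB isolate the bias added by mapping, and by mapping plus
#' assignment. All three denominators use the reads that fully span the
#' site's effective variant interval: reads that only partially cover it
#' cannot be attributed to a haplotype and are excluded from the whole
#' simulation analysis.
#'
#' @name balance-measures
NULL

# pairs (interval row, site row) where the interval fully covers the site
cover_pairs <- function(iv, sites) {
  # iv: chrom,start,end,idx ; sites: chrom,start,end,site_idx
  a <- copy(iv); setkey(a, chrom, start, end)
  s <- copy(sites); setkey(s, chrom, start, end)
  ov <- foverlaps(a, s, type = "any", nomatch = NULL)
  ov[i.start <= start & i.end >= end]
}

site_intervals <- function(sites) {
  s <- if ("eff_start" %in% names(sites)) {
    sites[, .(chrom, start = eff_start, end = eff_end, site_idx = seq_len(.N))]
  } else {
    sites[, .(chrom, start = foot_start, end = foot_end, site_idx = seq_len(.N))]
  }
  s[!is.na(start)]
}

#' Simulation balance per site
#'
#' SB = REF-haplotype reads / all reads, over simulated reads whose true
#' (lifted) reference origin spans the site. `NA` where no read spans.
#'
#' @param truth truth table from [simulate_reads()].
#' @param sites HET variant table (uses `eff_start`/`eff_end` when present,
#'   footprints otherwise).
#' @return data.table `site_idx`, `SB`, `n_truth`.
#' @export
compute_SB <- function(truth, sites) {
  iv <- truth[!is.na(ref_start),
              .(chrom, start = ref_start, end = ref_end, hap,
                idx = seq_len(.N))]
  pr <- cover_pairs(iv, site_intervals(sites))
  ref_hap <- ifelse(sites$gt1 == 0L, 1L, 2L)
  tab <- pr[, .(n_truth = .N,
                n_ref = sum(hap == ref_hap[site_idx[1]])), by = site_idx]
  out <- data.table(site_idx = seq_len(nrow(sites)))
  out <- tab[out, on = "site_idx"]
  out[, SB := ifelse(n_truth > 0L, n_ref / n_truth, NA_real_)]
  out[is.na(n_truth), `:=`(n_truth = 0L, n_ref = 0L)]
  out[]
}

#' Mapping balance and mismapped-read count per site
#'
#' Restricted to reads that both truly originated spanning the site and
#' aligned spanning it; the truth haplotype label supplies the allele.
#' `n_mismapped` counts aligned-spanning reads whose true origin does not
#' intersect the site at all. Also returns the mean MAPQ over all
#' aligned-spanning reads (the predictor's mapping signal).
#'
#' @param aln alignment table.
#' @param truth truth table; every aligned read must appear in it.
#' @param sites HET variant table.
#' @return data.table `site_idx`, `MB`, `n_mb`, `n_mismapped`, `avg_mapq`.
#' @export
compute_MB <- function(aln, truth, sites) {
  missing <- setdiff(aln$read_id, truth$read_id)
  if (length(missing))
    stop("aligned reads absent from the truth table, e.g. ", missing[1])
  a <- aln[, .(chrom, start = pos, end = pos + cigar_ref_width_v(cigar) - 1L,
               read_id, mapq, idx = seq_len(.N))]
  pr <- cover_pairs(a, site_intervals(sites))
  tt <- truth[, .(read_id, t_start = ref_start, t_end = ref_end, hap)]
  pr <- tt[pr, on = "read_id"]
  ref_hap <- ifelse(sites$gt1 == 0L, 1L, 2L)
  siv <- site_intervals(sites)
  pr <- siv[, .(site_idx, s_start = start, s_end = end)][pr, on = "site_idx"]
  pr[, t_cover := !is.na(t_start) & t_start <= s_start & t_end >= s_end]
  pr[, t_disjoint := is.na(t_start) | t_start > s_end | t_end < s_start]
  tab <- pr[, .(
    n_mb = sum(t_cover),
    n_ref = sum(t_cover & hap == ref_hap[site_idx[1]]),
    n_mismapped = sum(t_disjoint),
    avg_mapq = mean(mapq),
    n_aln = .N
  ), by = site_idx]
  out <- data.table(site_idx = seq_len(nrow(sites)))
  out <- tab[out, on = "site_idx"]
  out[, MB := ifelse(!is.na(n_mb) & n_mb > 0L, n_ref / n_mb, NA_real_)]
  out[is.na(n_mb), `:=`(n_mb = 0L, n_ref = 0L, n_mismapped = 0L, n_aln = 0L)]
  out[]
}

#' Assignment balance from per-read calls
#'
#' AB = REF / (REF + ALT); `BOTH` and `OTHER` calls are excluded from the
#' ratio. `NA` when no read received a REF or ALT call.
#'
#' @param calls call table from [assign_reads()] (one method).
#' @param sites HET variant table.
#' @param reads optional character vector restricting to a read set (e.g. the
#'   site-spanning reads).
#' @return data.table `site_idx`, `AB` and the four tallies.
#' @export
compute_AB <- function(calls, sites, reads = NULL) {
  cc <- if (is.null(reads)) calls else calls[read_id %in% reads]
  key <- sites[, .(chrom, pos, site_idx = seq_len(.N))]
  cc <- key[cc, on = c("chrom", "pos"), nomatch = NULL]
  tab <- cc[, .(n_ref = sum(call == "REF"), n_alt = sum(call == "ALT"),
                n_both = sum(call == "BOTH"), n_other = sum(call == "OTHER")),
            by = site_idx]
  out <- data.table(site_idx = seq_len(nrow(sites)))
  out <- tab[out, on = "site_idx"]
  for (cn in c("n_ref", "n_alt", "n_both", "n_other"))
    out[is.na(get(cn)), (cn) := 0L]
  out[, AB := ifelse(n_ref + n_alt > 0L, n_ref / (n_ref + n_alt), NA_real_)]
  out[]
}

#' Per-site balance table
#'
#' Runs [compute_SB()], [compute_MB()] and [compute_AB()] (for both
#' assigners) over the measured HET sites and derives NMB = MB - SB and
#' NAB = AB - SB. AB tallies are restricted to reads whose alignment spans
#' the site, the same read universe as MB.
#'
#' @param assignment result of [assign_reads()].
#' @param truth truth table.
#' @param aln alignment table.
#' @return data.table with one row per measured HET site: coordinates,
#'   alleles, `var_length`, `SB`, `MB`, `AB_naive`, `AB_context`, `NMB`,
#'   `NAB` (context), `NAB_naive`, `n_mismapped`, `avg_mapq` and the
#'   context-assigner tallies.
#' @export
site_balance <- function(assignment, truth, aln) {
  sites <- assignment$sites
  sb <- compute_SB(truth, sites)
  mb <- compute_MB(aln, truth, sites)
  # restrict AB to site-spanning reads: recompute the spanning pairs once
  a <- aln[, .(chrom, start = pos, end = pos + cigar_ref_width_v(cigar) - 1L,
               read_id, idx = seq_len(.N))]
  pr <- cover_pairs(a, site_intervals(sites))
  span_reads <- pr[, .(read_id, site_idx)]
  ab_ctx <- compute_AB_spanning(assignment$calls[method == "context"],
                                sites, span_reads)
  ab_nai <- compute_AB_spanning(assignment$calls[method == "naive"],
                                sites, span_reads)
  out <- sites[, .(chrom, pos, ref, alt, var_class, var_length,
                   eff_start, eff_end, disregarded)]
  out[, site_idx := seq_len(.N)]
  out[, SB := sb$SB[site_idx]]
  out[, MB := mb$MB[site_idx]]
  out[, n_mismapped := mb$n_mismapped[site_idx]]
  out[, avg_mapq := mb$avg_mapq[site_idx]]
  out[, AB_context := ab_ctx$AB[site_idx]]
  out[, AB_naive := ab_nai$AB[site_idx]]
  for (cn in c("n_ref", "n_alt", "n_both", "n_other"))
    out[, (cn) := ab_ctx[[cn]][site_idx]]
  out[, NMB := MB - SB]
  out[, NAB := AB_context - SB]
  out[, NAB_naive := AB_naive - SB]
  out[disregarded == TRUE, c("SB", "MB", "AB_context", "AB_naive",
                             "NMB", "NAB", "NAB_naive") := NA_real_]
  out[]
}

# AB over per-site spanning read sets (read may span one site but not another)
compute_AB_spanning <- function(calls, sites, span_reads) {
  key <- sites[, .(chrom, pos, site_idx = seq_len(.N))]
  cc <- key[calls, on = c("chrom", "pos"), nomatch = NULL]
  cc <- cc[span_reads, on = c("read_id", "site_idx"), nomatch = NULL]
  tab <- cc[, .(n_ref = sum(call == "REF"), n_alt = sum(call == "ALT"),
                n_both = sum(call == "BOTH"), n_other = sum(call == "OTHER")),
            by = site_idx]
  out <- data.table(site_idx = seq_len(nrow(sites)))
  out <- tab[out, on = "site_idx"]
  for (cn in c("n_ref", "n_alt", "n_both", "n_other"))
    out[is.na(get(cn)), (cn) := 0L]
  out[, AB := ifelse(n_ref + n_alt > 0L, n_ref / (n_ref + n_alt), NA_real_)]
  out[]
}

#' ALT-allele fraction stratified by indel length
#'
#' Groups sites by signed variant length (0 = SNV, positive = insertion,
#' negative = deletion), clamping lengths beyond `cap` into the -cap/+cap
#' strata, and summarises the ALT fraction `1 - balance` per stratum for each
#' requested balance measure (median, first and third quartile) together with
#' the stratum site counts.
#'
#' @param balances output of [site_balance()].
#' @param cap clamp for extreme lengths (default 25).
#' @param measures which balance columns to stratify.
#' @return long data.table: `stratum`, `measure`, `n`, `q1`, `median`, `q3`.
#' @export
alt_fraction_by_length <- function(balances,
                                   cap = 25L,
                                   measures = c("SB", "MB", "AB_naive",
                                                "AB_context")) {
  b <- copy(balances)
  b[, stratum := pmax(pmin(var_length, cap), -cap)]
  out <- rbindlist(lapply(measures, function(m) {
    x <- b[!is.na(get(m)),
           .(measure = m, n = .N,
             q1 = quantile(1 - get(m), 0.25, names = FALSE),
             median = median(1 - get(m)),
             q3 = quantile(1 - get(m), 0.75, names = FALSE)),
           by = stratum]
    x
  }))
  setkey(out, stratum, measure)
  out[]
}
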