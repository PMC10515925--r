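library(data.table)

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- memoised fixture cache (shared across test files in one test_dir run)
.fix_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fix_cache)) assign(key, expr, envir = .fix_cache)
  get(key, envir = .fix_cache)
}

# a complete simulated world: reference, phased variants, consensus,
# truth-tagged reads and a perfect alignment
make_world <- function(L, n_snv, n_indel = 0L, seed = 1L, error_rate = 0,
                       coverage = 15, hom_frac = 0, buffer = 60L,
                       n_repeats = 0L, repeat_unit_range = c(4L, 4L),
                       repeat_copy_range = c(6L, 8L), duplication = NULL,
                       repeat_variants = FALSE) {
  ref <- random_reference(L, seed = seed, n_repeats = n_repeats,
                          repeat_unit_range = repeat_unit_range,
                          repeat_copy_range = repeat_copy_range,
                          duplication = duplication)
  v <- if (repeat_variants) {
    repeat_deletion_variants(ref, seed = seed + 1L)
  } else {
    random_phased_variants(ref, n_snv = n_snv, n_indel = n_indel,
                           seed = seed + 1L, hom_frac = hom_frac,
                           buffer = buffer)
  }
  haps <- build_diploid_consensus(ref, v)
  sim <- simulate_reads(haps, coverage_per_hap = coverage,
                        error_rate = error_rate,
                        seed_hap1 = seed + 2L, seed_hap2 = seed + 3L)
  aln <- perfect_align(sim$reads, haps)
  list(ref = ref, variants = v, haps = haps, reads = sim$reads,
       truth = sim$truth, aln = aln)
}

# medium world shared by balance/classify unit tests (~150 kb, 300 HETs)
medium_world <- function() {
  cached("medium", make_world(150000L, n_snv = 240L, n_indel = 60L,
                              seed = 100L))
}

medium_assignment <- function() {
  cached("medium_asg", {
    w <- medium_world()
    assign_reads(w$aln, w$variants, w$haps)
  })
}

medium_balance <- function() {
  cached("medium_bal", {
    w <- medium_world()
    site_balance(medium_assignment(), w$truth, w$aln)
  })
}

# world with deliberately clustered variants (for cohort logic): a 3-SNV
# cluster, an SNV+insertion pair within cohort distance, and isolated sites
cluster_world <- function() {
  cached("cluster", {
    ref <- random_reference(20000L, seed = 300L)
    at <- function(p) substr(ref[[1]], p, p)
    other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
    pos <- c(5000L, 5010L, 5025L, 9000L, 9012L, 13000L, 16000L)
    refs <- vapply(pos, at, character(1))
    alts <- vapply(refs, other, character(1))
    alts[5] <- paste0(refs[5], "TTA")   # insertion member of the pair
    # whole cluster phased onto haplotype 2
    v <- vt("chr1", pos, refs, alts,
            gt1 = c(0L, 0L, 0L, 0L, 0L, 1L, 0L),
            gt2 = c(1L, 1L, 1L, 1L, 1L, 0L, 1L))
    haps <- build_diploid_consensus(ref, v)
    sim <- simulate_reads(haps, coverage_per_hap = 12,
                          seed_hap1 = 301L, seed_hap2 = 302L)
    aln <- perfect_align(sim$reads, haps)
    list(ref = ref, variants = v, haps = haps, truth = sim$truth, aln = aln)
  })
}

# ---- independent oracles -------------------------------------------------

# brute-force clustering of variants by pairwise footprint intersection
# (transitive closure), used against remove_overlapping_variants()
oracle_overlap_groups <- function(v) {
  n <- nrow(v)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || v$chrom[i] != v$chrom[j]) next
      if (v$foot_start[i] <= v$foot_end[j] && v$foot_end[i] >= v$foot_start[j] &&
          grp[i] != grp[j]) {
        grp[grp == grp[j]] <- grp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  grp
}

# brute-force read-to-haplotype call: does the read sequence contain the
# haplotype's sequence over the effective variant plus flanks? Error-free
# reads fully spanning the effective variant must match exactly one side.
oracle_hap_call <- function(read_seq, ctx) {
  in_ref <- grepl(ctx$ref$str, read_seq, fixed = TRUE)
  in_alt <- grepl(ctx$alt$str, read_seq, fixed = TRUE)
  if (in_ref && in_alt) "BOTH" else if (in_ref) "REF"
  else if (in_alt) "ALT" else "OTHER"
}

# independent re-derivation of the bias-category geometry, for the grid test
oracle_category <- function(nmb, nab, m, radius = 0.1) {
  inside_circle <- nmb^2 + nab^2 <= radius^2
  if (inside_circle) return("balanced")
  same_sign <- (nmb > 0 && nab > 0) || (nmb < 0 && nab < 0)
  in_wedge <- same_sign && nab <= 2 * nmb + 1e-12 && nab >= 0.5 * nmb - 1e-12
  if (nmb < 0) in_wedge <- same_sign && nab >= 2 * nmb - 1e-12 &&
      nab <= 0.5 * nmb + 1e-12
  if (in_wedge) return("loss")
  vertical <- abs(nmb) <= radius && abs(nab) > radius
  if (vertical) return(if (m > 5) "flux" else "local")
  "outlier"
}

# mean sequenced depth implied by a truth table (depth-counting oracle)
oracle_mean_depth <- function(truth, L) {
  sum(truth$end - truth$start + 1) / L
}

# small hand-writable variant table
vt <- function(chrom, pos, ref, alt, gt1, gt2, phased = TRUE) {
  biasbench:::new_variant_table(chrom, pos, ref, alt, gt1, gt2, phased)
}

# write VCF body lines with a minimal header
write_vcf_lines <- function(body, path) {
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               body), path)
  path
}
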