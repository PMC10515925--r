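# small deterministic scaffolding: a 60 bp reference around position 31
mini_ref <- function(core = "ACGTACGTAG", seed = 7L) {
  random_reference(200L, seed = seed)
}

test_that("naive_assign trusts the aligner's placement", {
  ref <- mini_ref()
  b <- substr(ref[[1]], 100, 100)
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  v <- vt("chr1", 100L, b, alt, 0L, 1L)
  seq_ref <- substr(ref[[1]], 81, 120)
  # aligned ALT base decides ALT
  seq_alt <- seq_ref
  substr(seq_alt, 20, 20) <- alt
  expect_equal(naive_assign(81L, "40M", seq_alt, v), "ALT")
  expect_equal(naive_assign(81L, "40M", seq_ref, v), "REF")
  # sequencing error producing a third base: OTHER
  third <- setdiff(c("A", "C", "G", "T"), c(b, alt))[1]
  seq_err <- seq_ref
  substr(seq_err, 20, 20) <- third
  expect_equal(naive_assign(81L, "40M", seq_err, v), "OTHER")
  expect_error(naive_assign(150L, "40M", seq_ref, v), "overlap")
})

test_that("naive_assign on indels requires the VCF gap placement", {
  # reference with a (ATTC) x 7 tandem tract starting at 101
  base <- random_reference(300L, seed = 8)
  refseq <- paste0(substr(base[[1]], 1, 100), strrep("ATTC", 7),
                   substr(base[[1]], 129, 300))
  ref <- setNames(refseq, "chr1")
  anchor <- substr(refseq, 100, 100)
  v <- vt("chr1", 100L, paste0(anchor, "ATTC"), anchor, 0L, 1L)  # 1-unit DEL
  # the same ALT read admits several equally scoring gap placements inside
  # the periodic tract; only the VCF placement tallies as ALT
  aseq <- paste0(substr(refseq, 61, 100), substr(refseq, 105, 144))
  expect_equal(naive_assign(61L, "40M4D40M", aseq, v), "ALT")
  # gap straddling the footprint boundary: sequence matches neither allele
  expect_equal(naive_assign(61L, "42M4D38M", aseq, v), "OTHER")
  # gap shifted one full unit out of the footprint: the ALT read is
  # miscounted as REF - the naive local-bias failure mode
  expect_equal(naive_assign(61L, "44M4D36M", aseq, v), "REF")
  # REF read is unaffected
  rseq <- substr(refseq, 61, 140)
  expect_equal(naive_assign(61L, "80M", rseq, v), "REF")
})

test_that("build_context extends through repeat tracts", {
  base <- random_reference(400L, seed = 9)
  refseq <- paste0(substr(base[[1]], 1, 100), strrep("ATTC", 7),
                   substr(base[[1]], 129, 400))
  ref <- setNames(refseq, "chr1")
  anchor <- substr(refseq, 100, 100)
  v <- vt("chr1", 100L, paste0(anchor, "ATTC"), anchor, 0L, 1L)
  haps <- build_diploid_consensus(ref, v)
  ctx <- build_context(v, haps)
  expect_false(ctx$disregarded)
  expect_true(ctx$extended)
  # effective span runs from the anchor through the whole tract to the
  # first differing base after it
  expect_equal(ctx$eff_start, 100L)
  expect_gte(ctx$eff_end, 128L)
  # oracle: direct string comparison of the two allele strings confirms the
  # extension was necessary right up to the tract end
  for (k in seq(4, 24, by = 4)) {
    sR <- substr(refseq, 100, 100 + k)
    sA <- paste0(anchor, substr(refseq, 105, 105 + k - 4))
    expect_true(startsWith(sR, sA))  # still prefix-ambiguous inside tract
  }
  # isolated SNV in unique sequence: 1 bp effective span
  b <- substr(refseq, 300, 300)
  vs <- vt("chr1", 300L, b, setdiff(c("A", "C", "G", "T"), b)[1], 0L, 1L)
  hs <- build_diploid_consensus(ref, vs)
  cs <- build_context(vs, hs)
  expect_false(cs$extended)
  expect_equal(c(cs$eff_start, cs$eff_end), c(300L, 300L))
  expect_equal(nchar(cs$ref$str), 11L)
  expect_equal(substr(cs$ref$str, 6, 6), b)
})

test_that("effective variants beyond the cap are disregarded", {
  base <- random_reference(500L, seed = 10)
  refseq <- paste0(substr(base[[1]], 1, 100), strrep("TTCA", 20),
                   substr(base[[1]], 181, 500))
  ref <- setNames(refseq, "chr1")
  anchor <- substr(refseq, 100, 100)
  v <- vt("chr1", 100L, paste0(anchor, "TTCA"), anchor, 0L, 1L)
  haps <- build_diploid_consensus(ref, v)
  ctx <- build_context(v, haps)  # 80 bp tract > 70 bp cap
  expect_true(ctx$disregarded)
  expect_equal(ctx$reason, "effective_span_exceeds_cap")
  expect_false(build_context(v, haps, max_effective = 120L)$disregarded)
})

test_that("context_assign matches reads by anchored exact search", {
  w <- cached("simfix", make_world(60000L, n_snv = 40L, n_indel = 10L,
                                   seed = 200L))
  kept <- remove_overlapping_variants(w$variants)$kept[het == TRUE &
                                                         var_class == "SNV"]
  site <- kept[3]
  ctx <- build_context(site, w$haps)
  # error-free read fully spanning the SNV context: call = truth allele
  tr <- w$truth[!is.na(ref_start) & ref_start <= site$pos - 10L &
                  ref_end >= site$pos + 10L][1:20]
  for (i in seq_len(nrow(tr))) {
    a <- w$aln[read_id == tr$read_id[i]][1]
    want <- if ((tr$hap[i] == 1L && site$gt1 == 0L) ||
                (tr$hap[i] == 2L && site$gt2 == 0L)) "REF" else "ALT"
    expect_equal(context_assign(a$pos, a$cigar, a$seq, ctx)$call, want)
  }
  # read ending 2 bp past the variant: decided by the left anchor from a
  # context prefix
  a <- w$aln[read_id == tr$read_id[1]][1]
  short <- substr(a$seq, 1, site$pos + 2L - a$pos + 1L)
  res <- context_assign(a$pos, paste0(nchar(short), "M"), short, ctx)
  want <- if ((tr$hap[1] == 1L && site$gt1 == 0L) ||
              (tr$hap[1] == 2L && site$gt2 == 0L)) "REF" else "ALT"
  expect_equal(res$call, want)
  expect_equal(res$anchor, "left")
  # N inside the window: OTHER
  nn <- a$seq
  substr(nn, site$pos - a$pos + 1L, site$pos - a$pos + 1L) <- "N"
  expect_equal(context_assign(a$pos, a$cigar, nn, ctx)$call, "OTHER")
})

test_that("reads not covering a repeat-extended variant are BOTH", {
  base <- random_reference(600L, seed = 11)
  refseq <- paste0(substr(base[[1]], 1, 100), strrep("ATTC", 7),
                   substr(base[[1]], 129, 600))
  ref <- setNames(refseq, "chr1")
  anchor <- substr(refseq, 100, 100)
  v <- vt("chr1", 100L, paste0(anchor, "ATTC"), anchor, 0L, 1L)
  haps <- build_diploid_consensus(ref, v)
  ctx <- build_context(v, haps)
  # REF read covering only 5 of the 7 units cannot be attributed
  partial <- substr(refseq, 80, 120)
  expect_equal(context_assign(80L, "41M", partial, ctx)$call, "BOTH")
  # REF read covering the whole tract is attributable
  full <- substr(refseq, 80, 150)
  expect_equal(context_assign(80L, "71M", full, ctx)$call, "REF")
  # ALT read (one unit fewer) covering the whole effective span
  hseq <- haps[[2]]$seq[["chr1"]]
  iv <- lift_ref_to_hap(haps[[2]]$map[["chr1"]], 80L, 150L)
  aseq <- substr(hseq, iv$hap_start, iv$hap_end)
  expect_equal(
    context_assign(80L, paste0("21M4D", nchar(aseq) - 21L, "M"), aseq,
                   ctx)$call, "ALT")
})

test_that("cohort_assign tallies spanning reads once per member", {
  w <- cluster_world()
  kept <- remove_overlapping_variants(w$variants)$kept[het == TRUE]
  ch <- build_cohorts(kept, 25L)
  members <- ch[cohort_id == ch[pos == 5000L, cohort_id]]
  expect_equal(nrow(members), 3L)
  cctx <- build_cohort_context(members, w$haps)
  ctxs <- lapply(seq_len(nrow(members)),
                 function(i) build_context(members[i], w$haps))
  # hap2 (all-ALT) read spanning the cohort: three ALT calls
  tr <- w$truth[hap == 2L & !is.na(ref_start) & ref_start <= 4970L &
                  ref_end >= 5055L][1]
  a <- w$aln[read_id == tr$read_id][1]
  res <- cohort_assign(a$pos, a$cigar, a$seq, cctx, members, ctxs)
  expect_equal(res$call, rep("ALT", 3))
  expect_equal(res$anchor, rep("cohort", 3))
  # read overlapping only the last member: per-variant fallback
  tr2 <- w$truth[!is.na(ref_start) & ref_start > 5010L &
                   ref_start <= 5025L & ref_end >= 5035L][1]
  expect_false(is.na(tr2$read_id))
  a2 <- w$aln[read_id == tr2$read_id][1]
  res2 <- cohort_assign(a2$pos, a2$cigar, a2$seq, cctx, members, ctxs)
  expect_equal(nrow(res2), 1L)
  expect_equal(res2$pos, 5025L)
  expect_equal(res2$call, if (tr2$hap == 1L) "REF" else "ALT")
  expect_true(res2$anchor %in% c("left", "right"))
  # an error inside the cohort string but outside one member's context:
  # the fallback rescues that member's call
  a3 <- w$aln[read_id == tr$read_id][1]
  sq <- a3$seq
  off <- 5010L - a3$pos + 1L
  substr(sq, off, off) <- "N"   # kill the middle member only
  res3 <- cohort_assign(a3$pos, a3$cigar, sq, cctx, members, ctxs)
  expect_equal(res3[pos == 5000L, call], "ALT")
  expect_equal(res3[pos == 5025L, call], "ALT")
  expect_equal(res3[pos == 5010L, call], "OTHER")
})

test_that("context calls equal the brute-force substring oracle", {
  w <- cached("simfix", make_world(60000L, n_snv = 40L, n_indel = 10L,
                                   seed = 200L))
  asg <- cached("simfix_asg", assign_reads(w$aln, w$variants, w$haps))
  sites <- asg$sites
  calls <- asg$calls[method == "context"]
  checked <- 0L
  for (i in which(!sites$disregarded)[1:25]) {
    ctx <- asg$contexts[[i]]
    cc <- calls[pos == sites$pos[i]]
    for (j in seq_len(min(nrow(cc), 15L))) {
      a <- w$aln[read_id == cc$read_id[j]]
      a <- a[pos <= ctx$eff_start - 5L &
               pos + cigar_ref_width_v(cigar) - 1L >= ctx$eff_end + 5L][1]
      if (nrow(a) == 0L || is.na(a$pos)) next
      expect_equal(cc$call[j], oracle_hap_call(a$seq, ctx),
                   label = paste0("site ", sites$pos[i], " read ",
                                  cc$read_id[j]))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 100L)
})

test_that("swapping the allele labels swaps REF and ALT calls exactly", {
  ref <- random_reference(20000L, seed = 12)
  v <- random_phased_variants(ref, n_snv = 15L, n_indel = 5L, seed = 13)
  haps <- build_diploid_consensus(ref, v)
  sim <- simulate_reads(haps, coverage_per_hap = 8, seed_hap1 = 1,
                        seed_hap2 = 2)
  aln <- perfect_align(sim$reads, haps)
  swap_call <- function(x) c(REF = "ALT", ALT = "REF", BOTH = "BOTH",
                             OTHER = "OTHER")[[x]]
  for (i in seq_len(nrow(v))) {
    ctx_a <- build_context(v[i], haps)
    if (ctx_a$disregarded) next
    # relabel: what was called REF is now called ALT and vice versa
    ctx_b <- ctx_a
    ctx_b$ref <- ctx_a$alt; ctx_b$alt <- ctx_a$ref
    cc <- aln[pos <= ctx_a$eff_start &
                pos + cigar_ref_width_v(cigar) - 1L >= ctx_a$eff_end]
    for (j in seq_len(min(nrow(cc), 8L))) {
      ca <- context_assign(cc$pos[j], cc$cigar[j], cc$seq[j], ctx_a)$call
      cb <- context_assign(cc$pos[j], cc$cigar[j], cc$seq[j], ctx_b)$call
      expect_equal(cb, swap_call(ca))
    }
  }
})
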