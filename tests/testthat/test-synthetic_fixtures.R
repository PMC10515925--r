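test_that("diploid consensus applies exactly the phased alleles", {
  ref <- random_reference(1000L, seed = 1)
  empty <- vt("chr1", integer(0), character(0), character(0),
              integer(0), integer(0))
  h0 <- build_diploid_consensus(ref, empty)
  expect_equal(h0[[1]]$seq[["chr1"]], ref[["chr1"]])
  expect_equal(h0[[2]]$seq[["chr1"]], ref[["chr1"]])
  expect_equal(h0[[1]]$map[["chr1"]],
               data.table(ref_start = 1L, ref_end = 1000L,
                          hap_start = 1L, hap_end = 1000L))
  # one HET SNV 0|1: hap1 identical, hap2 differs at exactly one position
  b <- substr(ref[[1]], 500, 500)
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  v <- vt("chr1", 500L, b, alt, 0L, 1L)
  h1 <- build_diploid_consensus(ref, v)
  expect_identical(h1[[1]]$seq[["chr1"]], ref[["chr1"]])
  d <- mapply(function(a, b) a != b,
              strsplit(h1[[2]]$seq[["chr1"]], "")[[1]],
              strsplit(ref[[1]], "")[[1]])
  expect_equal(sum(d), 1L)
  expect_equal(unname(which(d)), 500L)
  # 5 bp insertion on hap2: length bookkeeping
  vi <- vt("chr1", 500L, b, paste0(b, "ACGTA"), 0L, 1L)
  h2 <- build_diploid_consensus(ref, vi)
  expect_equal(nchar(h2[[2]]$seq[["chr1"]]), 1005L)
  expect_equal(nchar(h2[[1]]$seq[["chr1"]]), 1000L)
  # inconsistent REF allele names the site
  bad <- vt("chr1", 500L, ifelse(b == "A", "C", "A"), "G", 0L, 1L)
  expect_error(build_diploid_consensus(ref, bad), "chr1:500")
})

test_that("coordinate maps lift exactly through indels", {
  ref <- random_reference(2000L, seed = 2)
  b1 <- substr(ref[[1]], 400, 400); b2 <- substr(ref[[1]], 1200, 1200)
  v <- vt("chr1", c(400L, 1200L),
          ref = c(b1, substr(ref[[1]], 1200, 1207)),
          alt = c(paste0(b1, "TTTTT"), b2),
          gt1 = c(1L, 1L), gt2 = c(0L, 0L))
  haps <- build_diploid_consensus(ref, v)
  map <- haps[[1]]$map[["chr1"]]
  # forward/backward round trip over aligned blocks
  withr::with_seed(3, {
    for (k in 1:50) {
      s <- sample(2000L - 210L, 1L); e <- s + sample(10:200, 1L)
      hv <- lift_ref_to_hap(map, s, e)
      rv <- lift_hap_to_ref(map, hv$hap_start, hv$hap_end)
      # the round trip clamps only around the two indels (5 bp ins, 7 bp del)
      expect_lte(abs(rv$ref_start - s), 8L)
      expect_lte(abs(rv$ref_end - e), 8L)
    }
  })
  # insertion footprint lifts to the full inserted allele
  hv <- lift_ref_to_hap(map, 400L, 400L)
  expect_equal(hv$hap_end - hv$hap_start + 1L, 6L)
  # deletion footprint collapses to the anchor base on the deleted hap
  hv2 <- lift_ref_to_hap(map, 1200L, 1207L)
  expect_equal(hv2$hap_end - hv2$hap_start + 1L, 1L)
})

test_that("simulate_reads is faithful, well-calibrated and deterministic", {
  w <- cached("simfix", make_world(60000L, n_snv = 40L, n_indel = 10L,
                                   seed = 200L))
  # error-free reads substring-match their haplotype at their origin
  withr::with_seed(4, idx <- sample(nrow(w$truth), 200L))
  for (i in idx) {
    tr <- w$truth[i]
    hseq <- w$haps[[tr$hap]]$seq[[tr$chrom]]
    expect_identical(w$reads[read_id == tr$read_id & mate == tr$mate, seq],
                     substr(hseq, tr$start, tr$end))
  }
  # combined mean depth within 10% of 2 x 15
  expect_lt(abs(oracle_mean_depth(w$truth, 60000L) - 30) / 30, 0.1)
  # determinism: same seeds give byte-identical FASTQ
  s1 <- simulate_reads(w$haps, coverage_per_hap = 2, seed_hap1 = 9,
                       seed_hap2 = 10)
  s2 <- simulate_reads(w$haps, coverage_per_hap = 2, seed_hap1 = 9,
                       seed_hap2 = 10)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(s1$reads, f1); write_fastq(s2$reads, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_error(simulate_reads(w$haps, seed_hap1 = 1, seed_hap2 = 1))
  expect_error(simulate_reads(w$haps, read_len = 70000L), "read_len")
})

test_that("error injection hits the requested substitution rate", {
  w <- cached("simfix", make_world(60000L, n_snv = 40L, n_indel = 10L,
                                   seed = 200L))
  se <- simulate_reads(w$haps, coverage_per_hap = 5, error_rate = 0.01,
                       seed_hap1 = 21, seed_hap2 = 22)
  nmis <- 0L; ntot <- 0L
  for (i in seq_len(min(500L, nrow(se$truth)))) {
    tr <- se$truth[i]
    hseq <- w$haps[[tr$hap]]$seq[[tr$chrom]]
    a <- strsplit(se$reads[read_id == tr$read_id & mate == tr$mate, seq],
                  "")[[1]]
    b <- strsplit(substr(hseq, tr$start, tr$end), "")[[1]]
    nmis <- nmis + sum(a != b); ntot <- ntot + length(a)
  }
  expect_gt(nmis / ntot, 0.005)
  expect_lt(nmis / ntot, 0.02)
})

test_that("perfect_align reproduces origins and variant CIGARs", {
  ref <- random_reference(3000L, seed = 5)
  b <- substr(ref[[1]], 1500, 1500)
  v <- vt("chr1", 1500L, substr(ref[[1]], 1500, 1505), b, 0L, 1L)  # 5 bp DEL
  haps <- build_diploid_consensus(ref, v)
  sim <- simulate_reads(haps, coverage_per_hap = 10, seed_hap1 = 11,
                        seed_hap2 = 12)
  aln <- perfect_align(sim$reads, haps)
  # hap1 carries no variant: plain full-match CIGARs at the true position
  h1 <- aln[read_id %in% sim$truth[hap == 1L, read_id]]
  expect_true(all(h1$cigar == "150M"))
  tt1 <- sim$truth[h1, on = "read_id"]
  expect_equal(h1$pos, tt1$ref_start)
  # hap2 reads crossing the deletion carry a 5 bp D op (and no other gap)
  h2 <- aln[read_id %in% sim$truth[hap == 2L, read_id]]
  crossing <- h2[grepl("D", cigar)]
  expect_gt(nrow(crossing), 0L)
  expect_true(all(grepl("^[0-9]+M5D[0-9]+M$", crossing$cigar)))
  expect_equal(attr(aln, "n_unmapped"), 0L)
})

test_that("inject_bias constructs the canonical scenarios", {
  w <- cached("simfix", make_world(60000L, n_snv = 40L, n_indel = 10L,
                                   seed = 200L))
  kept <- remove_overlapping_variants(w$variants)$kept[het == TRUE]
  site <- kept[10]
  # drop_alt 1.0 removes every ALT-truth read over the site
  a1 <- inject_bias(w$aln, w$truth, "drop_alt", site = site, fraction = 1,
                    seed = 1)
  alt_hap <- if (site$gt1 == 1L) 1L else 2L
  alt_ids <- w$truth[hap == alt_hap & !is.na(ref_start) &
                       ref_start <= site$foot_end &
                       ref_end >= site$foot_start, read_id]
  expect_equal(sum(a1$read_id %in% alt_ids), 0L)
  # a site with no ALT reads is an error
  nocov <- copy(site)[, `:=`(pos = 1L, foot_start = 1L, foot_end = 1L)]
  expect_error(inject_bias(w$aln, w$truth, "drop_alt", site = nocov),
               "no ALT")
  # add_mismapped n = 6 produces exactly 6 mismapped reads at the site
  a2 <- inject_bias(w$aln, w$truth, "add_mismapped", site = site,
                    haps = w$haps, n = 6L, seed = 2)
  sites_dt <- copy(kept)
  mb <- compute_MB(a2, w$truth, sites_dt)
  expect_equal(mb$n_mismapped[which(sites_dt$pos == site$pos)], 6L)
  # collapse_duplication moves reads wholesale
  a3 <- inject_bias(w$aln, w$truth, "collapse_duplication",
                    src = c(40000L, 42000L), dest_start = 10000L)
  expect_equal(nrow(a3[pos >= 40000L & pos <= 42000L]), 0L)
  expect_equal(nrow(a3), nrow(w$aln))
})
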