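test_that("call_position_alleles applies the frequency rules", {
  # A:10 C:8 G:1 -> two alleles, SNV, diploid-consistent (10/8 <= 2)
  r1 <- call_position_alleles(c(A = 10L, C = 8L, G = 1L, T = 0L))
  expect_equal(r1$alleles, "A,C")
  expect_true(r1$is_snv); expect_false(r1$is_nd)
  # A:20 C:5 -> C is 20% > 15%, top 4x second -> non-diploid
  r2 <- call_position_alleles(c(A = 20L, C = 5L, G = 0L, T = 0L))
  expect_true(r2$is_snv); expect_true(r2$is_nd)
  # three alleles above threshold -> non-diploid
  r3 <- call_position_alleles(c(A = 10L, C = 6L, G = 4L, T = 0L))
  expect_equal(r3$alleles, "A,C,G")
  expect_true(r3$is_nd)
  # single allele: no SNV, no ND regardless of skew
  r4 <- call_position_alleles(c(A = 29L, C = 1L, G = 0L, T = 0L))
  expect_false(r4$is_snv); expect_false(r4$is_nd)
  # exact 2:1 is diploid-consistent ("more than twice" is strict)
  r5 <- call_position_alleles(c(A = 20L, C = 10L, G = 0L, T = 0L))
  expect_true(r5$is_snv); expect_false(r5$is_nd)
})

test_that("window_measures computes densities over covered positions", {
  pos <- 1:2000
  p <- data.table(chrom = "c", pos = pos, depth = 30L, A = 30L, C = 0L,
                  G = 0L, T = 0L)
  # plant two HET-like columns and one collapsed-like column
  p[pos == 500, `:=`(A = 15L, C = 15L)]
  p[pos == 900, `:=`(A = 15L, T = 15L)]
  p[pos == 1500, `:=`(A = 24L, G = 6L)]   # 80/20: SNV and non-diploid
  wm <- window_measures(p, window = 400L, step = 400L)
  expect_equal(wm$covered, rep(400L, 5L))
  expect_equal(wm$RD, rep(30, 5))
  expect_equal(wm$VD, c(0, 1 / 400, 1 / 400, 1 / 400, 0))
  expect_equal(wm$ND, c(0, 0, 0, 1 / 400, 0))
  # interior windows of the sliding grid are full width (regression guard
  # for the cumulative-sum offset)
  wm2 <- window_measures(p, window = 400L, step = 100L)
  expect_true(all(wm2[window_start >= 1 & window_end <= 2000, covered] == 400L))
  expect_equal(nrow(window_measures(p[0])), 0L)
  expect_error(window_measures(p[c(5, 3, 1)]), "sorted")
})

test_that("combine_scores applies the published truncation rules", {
  base <- list(mean = c(RD = 30, VD = 0.001, ND = 0.0001),
               sd = c(RD = 2, VD = 0.0005, ND = 0.0001))
  wm <- data.table(chrom = "c", window_start = 1L, window_end = 400L,
                   covered = 400L,
                   RD = c(31.6, 34, 30, 26),
                   VD = c(0.00075, 0.00175, 0.001, 0.001),
                   ND = c(0.0001, 0.00027, 0.0001, 0.0001))
  sc <- combine_scores(wm, base)
  # z_rd = 0.8 -> 0 ; z_vd = -0.5 -> 0 ; window at the mean -> 0
  expect_equal(sc$z_rd, c(0, 2, 0, 0))
  expect_equal(sc$z_vd, c(0, 1.5, 0, 0))
  expect_equal(sc$z_nd, c(0, 1.7, 0, 0))
  expect_equal(sc$bias_score, c(0, 5.2, 0, 0))
})

test_that("sample_baseline is exact at fraction 1 and deterministic", {
  w <- cached("simfix", make_world(60000L, n_snv = 40L, n_indel = 10L,
                                   seed = 200L))
  pile <- cached("simfix_pile", pileup_from_alignments(w$aln))
  b1 <- sample_baseline(pile, fraction = 1, seed = 1)
  wm <- window_measures(pile)
  expect_equal(b1$mean[["RD"]], mean(wm$RD))
  expect_equal(b1$sd[["VD"]], sd(wm$VD))
  b2 <- sample_baseline(pile, fraction = 0.3, seed = 5)
  b3 <- sample_baseline(pile, fraction = 0.3, seed = 5)
  expect_identical(b2, b3)
  # two identical sources give the single-source parameters at fraction 1
  b4 <- sample_baseline(list(pile, pile), fraction = 1, seed = 1)
  expect_equal(b4$mean, b1$mean)
  # pooling the duplicated sample only changes the n-1 denominator
  expect_equal(b4$sd, b1$sd, tolerance = 1e-3)
  # a constant measure cannot be z-scored
  flat <- data.table(chrom = "c", pos = 1:2000, depth = 30L, A = 30L,
                     C = 0L, G = 0L, T = 0L)
  expect_error(sample_baseline(flat, fraction = 1, seed = 1),
               "standard deviation is zero")
})

test_that("call_regions merges, chains and labels correctly", {
  base <- list(mean = c(RD = 0, VD = 0, ND = 0), sd = c(RD = 1, VD = 1, ND = 1))
  mkwin <- function(starts, score) {
    data.table(chrom = "c", window_start = starts,
               window_end = starts + 399L, covered = 400L,
               RD = 0, VD = 0, ND = 0, z_rd = 0, z_vd = 0, z_nd = 0,
               bias_score = score)
  }
  # two biased blocks 400 bp apart chain into one region
  sc <- rbind(mkwin(c(1000L), 6), mkwin(c(1800L), 7))
  r <- call_regions(sc)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(1000L, 2199L))
  expect_equal(r$peak_score, 7)
  # 1500 bp apart stays two regions
  sc2 <- rbind(mkwin(1000L, 6), mkwin(2900L, 6))
  expect_equal(nrow(call_regions(sc2)), 2L)
  # scores in [3, 5) are suspicious only
  sc3 <- mkwin(c(1000L, 5000L), 4)
  r3 <- call_regions(sc3)
  expect_equal(unique(r3$label), "suspicious")
  # chaining is idempotent
  r4 <- call_regions(rbind(mkwin(seq(1000L, 3000L, 200L), 6),
                           mkwin(6000L, 6)))
  again <- r4[, .(chrom, start, end, label)]
  ir <- IRanges::reduce(IRanges::IRanges(again$start, again$end),
                        min.gapwidth = 1001L)
  expect_equal(length(ir), nrow(r4))
  # suspicious chains never overlap biased regions
  sc5 <- rbind(mkwin(c(1000L, 1400L), 6), mkwin(c(1200L, 2000L), 4))
  r5 <- call_regions(sc5)
  bi <- r5[label == "biased"]; su <- r5[label == "suspicious"]
  if (nrow(su)) {
    expect_true(all(su$end < bi$start | su$start > bi$end))
  }
})

test_that("the mpileup parser agrees with samtools on a real pileup", {
  w <- cached("simfix", make_world(60000L, n_snv = 40L, n_indel = 10L,
                                   seed = 200L))
  d <- tempfile("mp"); dir.create(d)
  fa <- file.path(d, "ref.fa"); write_fasta(w$ref, fa)
  sam <- file.path(d, "a.sam")
  write_sam(w$aln, setNames(nchar(w$ref), names(w$ref)), sam)
  bam <- file.path(d, "a.bam")
  system2("samtools", c("sort", "-o", bam, sam), stdout = FALSE,
          stderr = FALSE)
  mp <- file.path(d, "a.pile")
  system2("samtools",
          c("mpileup", "-B", "-Q", "0", "-d", "10000", "-f", fa, bam),
          stdout = mp, stderr = FALSE)
  got <- read_mpileup(mp)
  want <- cached("simfix_pile", pileup_from_alignments(w$aln))
  m <- merge(got, want, by = c("chrom", "pos"))
  expect_equal(nrow(m), nrow(want))
  expect_equal(m$A.x, m$A.y)
  expect_equal(m$C.x, m$C.y)
  expect_equal(m$G.x, m$G.y)
  expect_equal(m$T.x, m$T.y)
})

test_that("compare_runs applies the 25% / one-fifth-depth rule", {
  regA <- data.table(chrom = "chr1", start = 1001L, end = 3000L,
                     label = "biased", peak_score = 6, n_windows = 5L)
  regB0 <- data.table(chrom = character(), start = integer(),
                      end = integer(), label = character(),
                      peak_score = numeric(), n_windows = integer())
  mkpile <- function(frac_good) {
    depth <- rep(2L, 2000L)
    depth[seq_len(round(frac_good * 2000L))] <- 30L
    data.table(chrom = "chr1", pos = 1001:3000, depth = depth, A = depth,
               C = 0L, G = 0L, T = 0L)
  }
  pA <- mkpile(1)
  r30 <- compare_runs(regA, regB0, pA, mkpile(0.30))
  expect_true(r30$a_improved_by_b$improved)
  r15 <- compare_runs(regA, regB0, pA, mkpile(0.15))
  expect_false(r15$a_improved_by_b$improved)
  # well-covered bases inside B's own biased regions never count
  regB <- copy(regA)
  rB <- compare_runs(regA, regB, pA, mkpile(0.30))
  expect_false(rB$a_improved_by_b$improved)
  # identical runs improve nothing in either direction
  same <- compare_runs(regA, copy(regA), pA, pA)
  expect_equal(same$summary$n_improved, c(0L, 0L))
  # mismatched baselines are rejected
  a <- copy(regA); b <- copy(regA)
  setattr(a, "baseline", list(mean = 1)); setattr(b, "baseline", list(mean = 2))
  expect_error(compare_runs(a, b, pA, pA), "baseline")
})

test_that("overlap_features honours the proximity margin", {
  reg <- data.table(chrom = "chr1", start = 5000L, end = 6000L,
                    label = "biased", peak_score = 8, n_windows = 3L)
  feats <- data.table(chrom = "chr1",
                      start = c(6050L, 6150L, 5500L, 100L),
                      end = c(6060L, 6160L, 5510L, 200L))
  r <- overlap_features(reg, feats, margin = 100L)
  expect_equal(r$inside, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(attr(r, "counts")$inside, 2L)
  r0 <- overlap_features(reg[0], feats)
  expect_false(any(r0$inside))
})

test_that("a collapsed duplication doubles window depth", {
  dup <- list(length = 2000L, src_start = 40000L, dest_start = 10000L)
  w <- cached("dupfix", make_world(60000L, n_snv = 0L, seed = 400L,
                                   duplication = dup, n_repeats = 0L,
                                   repeat_variants = FALSE))
  alnc <- inject_bias(w$aln, w$truth, "collapse_duplication",
                      src = c(40000L, 41999L), dest_start = 10000L)
  pile <- pileup_from_alignments(alnc)
  inside <- pile[pos >= 10200 & pos <= 11800, mean(depth)]
  outside <- pile[pos >= 20000 & pos <= 38000, mean(depth)]
  expect_gt(inside / outside, 1.7)
})
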