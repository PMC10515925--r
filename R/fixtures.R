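#' Generate a random reference sequence with optional planted structure
#'
#' Bases are drawn i.i.d. uniformly. Optionally plants tandem repeat tracts
#' (what the local-bias and effective-variant machinery needs) and one exact
#' segmental duplication (what the scan mode's collapsed-duplication scenario
#' needs).
#'
#' @param length total sequence length in bp.
#' @param seed integer seed; all randomness in the generator flows from it.
#' @param chrom chromosome name.
#' @param n_repeats number of tandem repeat tracts to plant.
#' @param repeat_unit_range range of repeat unit sizes (bp).
#' @param repeat_copy_range range of copy numbers.
#' @param duplication `NULL`, or `list(length=, src_start=, dest_start=)`;
#'   the segment at `src_start` is copied over the sequence at `dest_start`.
#' @return named character vector of length 1; attributes `repeats`
#'   (data.table: start, unit_len, n_copies, end) and `duplication` describe
#'   the planted structure.
#' @export
random_reference <- function(length, seed, chrom = "chr1",
                             n_repeats = 0L,
                             repeat_unit_range = c(2L, 6L),
                             repeat_copy_range = c(4L, 12L),
                             duplication = NULL) {
  withr::with_seed(seed, {
    s <- paste0(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                collapse = "")
    reps <- data.table(start = integer(), unit_len = integer(),
                       n_copies = integer(), end = integer())
    if (n_repeats > 0L) {
      # space tracts evenly with random jitter so they never collide
      slots <- floor(seq(length * 0.1, length * 0.9, length.out = n_repeats))
      for (i in seq_len(n_repeats)) {
        ul <- sample(seq(repeat_unit_range[1], repeat_unit_range[2]), 1L)
        nc <- sample(seq(repeat_copy_range[1], repeat_copy_range[2]), 1L)
        unit <- paste0(sample(c("A", "C", "G", "T"), ul, replace = TRUE),
                       collapse = "")
        tract <- strrep(unit, nc)
        st <- slots[i]
        substr(s, st, st + nchar(tract) - 1L) <- tract
        reps <- rbind(reps, data.table(start = st, unit_len = ul,
                                       n_copies = nc,
                                       end = st + nchar(tract) - 1L))
      }
    }
    if (!is.null(duplication)) {
      seg <- substr(s, duplication$src_start,
                    duplication$src_start + duplication$length - 1L)
      substr(s, duplication$dest_start,
             duplication$dest_start + duplication$length - 1L) <- seg
    }
    out <- setNames(s, chrom)
    attr(out, "repeats") <- reps
    attr(out, "duplication") <- duplication
    out
  })
}

#' Generate random phased variants over a reference
#'
#' Draws HET SNVs and indels at non-overlapping positions; genotypes are
#' phased, with the ALT allele placed on haplotype 1 or 2 with equal
#' probability. A fraction of sites can be made homozygous-ALT.
#'
#' @param reference named character vector (one chromosome).
#' @param n_snv,n_indel site counts.
#' @param seed integer seed.
#' @param indel_len_range range of absolute indel lengths (bp).
#' @param hom_frac fraction of sites made 1|1.
#' @param avoid optional data.table of closed intervals (`start`, `end`) that
#'   variants must not touch.
#' @param buffer minimum spacing between variant footprints (bp).
#' @return a phased variant table.
#' @export
random_phased_variants <- function(reference, n_snv, n_indel = 0L, seed = 1L,
                                   indel_len_range = c(1L, 10L),
                                   hom_frac = 0, avoid = NULL, buffer = 60L) {
  chrom_name <- names(reference)[1]
  refseq <- reference[[1]]
  L <- nchar(refseq)
  withr::with_seed(seed, {
    n <- n_snv + n_indel
    max_fp <- indel_len_range[2] + 2L
    # candidate anchor positions on a jittered grid, guaranteeing spacing
    pitch <- max(buffer + max_fp, floor((L - 200L) / max(n, 1L)))
    if (pitch * n > L - 200L)
      stop("reference too short for ", n, " variants at this spacing")
    anchors <- 100L + pitch * (seq_len(n) - 1L) +
      sample.int(max(pitch - max_fp - buffer, 1L), n, replace = TRUE)
    if (!is.null(avoid) && nrow(avoid)) {
      ok <- rep(TRUE, n)
      for (k in seq_len(nrow(avoid)))
        ok <- ok & (anchors + max_fp < avoid$start[k] | anchors > avoid$end[k])
      anchors <- anchors[ok]
      n <- length(anchors)
      n_snv <- min(n_snv, n); n_indel <- n - n_snv
    }
    kind <- sample(rep(c("SNV", "INDEL"), c(n_snv, n_indel)))
    ref_al <- character(n); alt_al <- character(n)
    for (i in seq_len(n)) {
      p <- anchors[i]
      b <- substr(refseq, p, p)
      if (kind[i] == "SNV") {
        ref_al[i] <- b
        alt_al[i] <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      } else {
        k <- sample(seq(indel_len_range[1], indel_len_range[2]), 1L)
        if (runif(1) < 0.5) {           # deletion
          ref_al[i] <- substr(refseq, p, p + k)
          alt_al[i] <- b
        } else {                        # insertion
          ref_al[i] <- b
          alt_al[i] <- paste0(b, paste0(
            sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""))
        }
      }
    }
    hom <- runif(n) < hom_frac
    alt_on_h1 <- runif(n) < 0.5
    gt1 <- ifelse(hom, 1L, ifelse(alt_on_h1, 1L, 0L))
    gt2 <- ifelse(hom, 1L, ifelse(alt_on_h1, 0L, 1L))
    new_variant_table(chrom_name, anchors, ref_al, alt_al, gt1, gt2,
                      phased = TRUE)
  })
}

#' One-unit HET deletions inside planted tandem repeat tracts
#'
#' For each planted tract (see [random_reference()]) emits a VCF-style
#' deletion of one repeat unit, anchored one base left of the tract. These are
#' the canonical gap-placement-ambiguous variants: the deletion can be placed
#' at any unit of the tract with an equally good alignment.
#'
#' @param reference output of [random_reference()] with planted repeats.
#' @param seed seed controlling which haplotype carries the deletion.
#' @return a phased variant table.
#' @export
repeat_deletion_variants <- function(reference, seed = 1L) {
  reps <- attr(reference, "repeats")
  stopifnot(!is.null(reps), nrow(reps) > 0L)
  refseq <- reference[[1]]
  withr::with_seed(seed, {
    pos <- reps$start - 1L
    ref_al <- vapply(seq_len(nrow(reps)),
                     function(i) substr(refseq, pos[i], pos[i] + reps$unit_len[i]),
                     character(1))
    alt_al <- vapply(pos, function(p) substr(refseq, p, p), character(1))
    alt_on_h1 <- runif(nrow(reps)) < 0.5
    new_variant_table(names(reference)[1], pos, ref_al, alt_al,
                      gt1 = as.integer(alt_on_h1),
                      gt2 = as.integer(!alt_on_h1), phased = TRUE)
  })
}

#' Write a phased variant table as a VCF 4.2 file
#' @param variants phased variant table.
#' @param path output path.
#' @param contigs optional named integer vector of contig lengths.
#' @export
write_vcf <- function(variants, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tdonor")
  gt <- paste0(variants$gt1, ifelse(variants$phased, "|", "/"), variants$gt2)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.\tGT\t%s",
                  variants$chrom, variants$pos, variants$ref, variants$alt,
                  ifelse(variants$filter %in% c("PASS", "overlapping"),
                         "PASS", variants$filter),
                  gt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate truth-tagged paired-end reads from a diploid consensus
#'
#' Fragments are sampled uniformly and independently per haplotype (different
#' seeds for the two haplotypes so the coverage profiles are uncorrelated),
#' with substitution sequencing errors injected i.i.d. per base. Truth lives
#' in the returned table, not in read names.
#'
#' @param haps output of [build_diploid_consensus()].
#' @param coverage_per_hap mean per-haplotype coverage (default 15, i.e. ~30x
#'   combined).
#' @param read_len read length (default 150).
#' @param frag_mean,frag_sd fragment length model (default 400 +/- 50).
#' @param error_rate per-base substitution error rate in `[0, 1)`.
#' @param seed_hap1,seed_hap2 distinct integer seeds.
#' @return `list(reads=, truth=)`; `reads` has the (forward-reference-strand)
#'   sequence per mate, `truth` has haplotype coordinates (`start`, `end`) and
#'   lifted reference coordinates (`ref_start`, `ref_end`) per mate.
#' @export
simulate_reads <- function(haps, coverage_per_hap = 15, read_len = 150L,
                           frag_mean = 400, frag_sd = 50, error_rate = 0,
                           seed_hap1 = 1L, seed_hap2 = 2L) {
  stopifnot(seed_hap1 != seed_hap2, error_rate >= 0, error_rate < 1)
  per_hap <- lapply(1:2, function(h) {
    seed <- if (h == 1L) seed_hap1 else seed_hap2
    hap <- haps[[h]]
    out <- vector("list", length(hap$seq))
    for (ci in seq_along(hap$seq)) {
      cn <- names(hap$seq)[ci]
      hseq <- hap$seq[[ci]]
      L <- nchar(hseq)
      if (read_len > L) stop("read_len ", read_len, " exceeds haplotype length ", L)
      withr::with_seed(seed + ci - 1L, {
        nfrag <- round(coverage_per_hap * L / (2 * read_len))
        flen <- pmax(2L * read_len,
                     pmin(L, as.integer(round(rnorm(nfrag, frag_mean, frag_sd)))))
        fstart <- 1L + floor(runif(nfrag) * (L - flen + 1L))
        s1 <- fstart; e1 <- fstart + read_len - 1L
        e2 <- fstart + flen - 1L; s2 <- e2 - read_len + 1L
        id <- sprintf("h%d_%s_f%06d", h, cn, seq_len(nfrag))
        dt <- data.table(
          read_id = rep(id, 2L),
          mate = rep(1:2, each = nfrag),
          hap = h, chrom = cn,
          start = c(s1, s2), end = c(e1, e2),
          strand = rep(c("+", "-"), each = nfrag)
        )
        dt[, seq := substring(hseq, start, end)]
        if (error_rate > 0) {
          nb <- nrow(dt) * read_len
          nerr <- stats::rbinom(1L, nb, error_rate)
          if (nerr > 0L) {
            at <- sample.int(nb, nerr)
            row <- (at - 1L) %/% read_len + 1L
            off <- (at - 1L) %% read_len + 1L
            sq <- dt$seq
            for (k in seq_len(nerr)) {
              old <- substr(sq[row[k]], off[k], off[k])
              substr(sq[row[k]], off[k], off[k]) <-
                sample(setdiff(c("A", "C", "G", "T"), old), 1L)
            }
            dt[, seq := sq]
          }
        }
        lift <- lift_hap_to_ref(hap$map[[cn]], dt$start, dt$end)
        dt[, `:=`(ref_start = lift$ref_start, ref_end = lift$ref_end)]
        out[[ci]] <- dt
      })
    }
    rbindlist(out)
  })
  all <- rbindlist(per_hap)
  all[, read_id := paste0(read_id, "/", mate)]
  reads <- all[, .(read_id, hap, chrom, start, end, mate, strand, seq)]
  truth <- all[, .(read_id, hap, chrom, start, end, mate, ref_start, ref_end)]
  list(reads = reads, truth = truth)
}

#' Write simulated reads as FASTQ (reverse-strand mates are reverse-complemented)
#' @param reads `reads` table from [simulate_reads()].
#' @param path output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  sq <- ifelse(reads$strand == "-", rev_comp(reads$seq), reads$seq)
  lines <- as.vector(rbind(paste0("@", reads$read_id), sq, "+",
                           strrep("I", nchar(sq))))
  writeLines(lines, path)
  invisible(path)
}

#' Write a read truth table as TSV
#' @param truth truth table from [simulate_reads()].
#' @param path output path.
#' @export
write_truth <- function(truth, path) write_tsv(truth, path)

#' Read a truth table written by [write_truth()]
#' @param path TSV path.
#' @export
read_truth <- function(path) read_tsv(path)
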