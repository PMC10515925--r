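#' Phased diploid variant tables
#'
#' A phased variant table is a `data.table` with one row per biallelic variant:
#' `chrom`, `pos` (1-based position of the first REF base), `ref`, `alt`,
#' `gt1`/`gt2` (0 = REF, 1 = ALT on haplotype 1/2), `phased` (logical),
#' `het` (logical), `filter`, `var_class` (`SNV`/`INS`/`DEL`/`MNV`) and
#' `var_length` (`nchar(alt) - nchar(ref)`). The reference footprint of a
#' variant is the closed interval `[pos, pos + nchar(ref) - 1]`.
#'
#' @name variant-table
NULL

classify_alleles <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr == 1L & la == 1L, "SNV",
    ifelse(la > lr, "INS", ifelse(la < lr, "DEL", "MNV")))
}

new_variant_table <- function(chrom, pos, ref, alt, gt1, gt2, phased, filter = "PASS") {
  stopifnot(all(nchar(ref) > 0L), all(nchar(alt) > 0L), all(pos >= 1L))
  dt <- data.table(
    chrom = chrom, pos = as.integer(pos), ref = toupper(ref), alt = toupper(alt),
    gt1 = as.integer(gt1), gt2 = as.integer(gt2),
    phased = phased, filter = filter
  )
  dt[, het := gt1 != gt2]
  dt[, var_class := classify_alleles(ref, alt)]
  dt[, var_length := nchar(alt) - nchar(ref)]
  dt[, foot_start := pos]
  dt[, foot_end := pos + nchar(ref) - 1L]
  setkey(dt, chrom, pos)
  dt[]
}

#' Load phased diploid variants from a VCF file
#'
#' Reads a VCF 4.x file (plain or gzip/bgzip compressed), keeping only records
#' whose FILTER is `PASS` or `.`. Multi-allelic records are split into
#' biallelic records; sites where both haplotypes carry different non-reference
#' alleles (e.g. `1|2`), half-calls and `./.` sites are returned with
#' `filter = "overlapping"` so that [remove_overlapping_variants()] removes
#' them together with anything they touch. Symbolic ALTs (`<DEL>`, breakends)
#' are skipped and counted.
#'
#' @param path path to the VCF file.
#' @param region optional `list(chrom=, start=, end=)` restriction.
#' @return a phased variant table (see [variant-table]); attributes
#'   `n_filtered`, `n_skipped`, `n_missing_gt` carry exclusion counts.
#' @export
load_phased_variants <- function(path, region = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  body_idx <- which(!startsWith(lines, "#"))
  out <- vector("list", length(body_idx))
  n_filtered <- 0L; n_skipped <- 0L; n_missing_gt <- 0L
  k <- 0L
  for (i in body_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 10L)
      stop("malformed VCF line ", i, ": expected >= 10 fields, got ", length(f))
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) stop("malformed VCF line ", i, ": POS is not an integer")
    filt <- f[7]
    if (!(filt %in% c("PASS", ".", ""))) { n_filtered <- n_filtered + 1L; next }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i)) { n_missing_gt <- n_missing_gt + 1L; next }
    gt <- strsplit(f[10], ":", fixed = TRUE)[[1]][gt_i]
    ref <- toupper(f[4])
    alts <- strsplit(toupper(f[5]), ",", fixed = TRUE)[[1]]
    if (grepl("[^ACGTN]", ref) || any(grepl("[^ACGTN,]", alts))) {
      n_skipped <- n_skipped + 1L; next   # symbolic allele / breakend
    }
    phased <- grepl("|", gt, fixed = TRUE)
    gtv <- strsplit(gt, "[|/]")[[1]]
    if (length(gtv) != 2L || any(gtv == ".")) {
      # half call / ./. : marker treated as overlapping so the footprint is purged
      k <- k + 1L
      out[[k]] <- data.table(chrom = f[1], pos = pos, ref = ref, alt = alts[1],
                             gt1 = 0L, gt2 = 0L, phased = FALSE, filter = "overlapping")
      next
    }
    a1 <- as.integer(gtv[1]); a2 <- as.integer(gtv[2])
    if (a1 > 0L && a2 > 0L && a1 != a2) {
      # 1|2-style: both haplotypes non-reference with different alleles;
      # split records would overlap each other, mark both for removal
      for (a in c(a1, a2)) {
        k <- k + 1L
        out[[k]] <- data.table(chrom = f[1], pos = pos, ref = ref, alt = alts[a],
                               gt1 = 0L, gt2 = 0L, phased = phased, filter = "overlapping")
      }
      next
    }
    used <- unique(c(a1, a2)); used <- used[used > 0L]
    if (length(used) == 0L) next  # hom-ref carries no allele of interest
    a <- used[1]
    k <- k + 1L
    out[[k]] <- data.table(chrom = f[1], pos = pos, ref = ref, alt = alts[a],
                           gt1 = as.integer(a1 == a), gt2 = as.integer(a2 == a),
                           phased = phased, filter = "PASS")
  }
  dt <- if (k == 0L) {
    data.table(chrom = character(), pos = integer(), ref = character(),
               alt = character(), gt1 = integer(), gt2 = integer(),
               phased = logical(), filter = character())
  } else rbindlist(out[seq_len(k)])
  if (!is.null(region) && nrow(dt)) {
    dt <- dt[chrom == region$chrom & pos >= region$start & pos <= region$end]
  }
  v <- new_variant_table(dt$chrom, dt$pos, dt$ref, dt$alt, dt$gt1, dt$gt2,
                         dt$phased, dt$filter)
  if (n_missing_gt > 0L)
    warning(n_missing_gt, " VCF record(s) without GT skipped")
  setattr(v, "n_filtered", n_filtered)
  setattr(v, "n_skipped", n_skipped)
  setattr(v, "n_missing_gt", n_missing_gt)
  v
}

#' Remove groups of variants with intersecting reference footprints
#'
#' Any connected group of variants whose reference footprints intersect (a
#' deletion extending over an SNV, `1|2` sites, `./.` markers) is removed in
#' its entirety, because the member sites cannot vary independently. Variants
#' flagged `filter == "overlapping"` at load time are removed along with
#' everything their footprint touches.
#'
#' @param variants a phased variant table sorted by (chrom, pos).
#' @return `list(kept=, removed=)`, both variant tables; `removed` has a
#'   `reason` column.
#' @export
remove_overlapping_variants <- function(variants) {
  if (nrow(variants) == 0L)
    return(list(kept = variants, removed = copy(variants)[, reason := character(0)]))
  v <- copy(variants)
  setkey(v, chrom, pos)
  # single pass per chromosome: cluster variants whose footprints intersect
  v[, group := {
    cummax_end <- shift(cummax(as.integer(foot_end)), fill = -1L)
    cumsum(foot_start > cummax_end)
  }, by = chrom]
  v[, keep := .N == 1L & all(filter != "overlapping"), by = .(chrom, group)]
  kept <- v[keep == TRUE][, c("group", "keep") := NULL]
  removed <- v[keep == FALSE][, c("group", "keep") := NULL]
  removed[, reason := ifelse(filter == "overlapping",
                             "unresolved_genotype", "footprint_overlap")]
  list(kept = kept[], removed = removed[])
}

#' Group nearby variants into cohorts by single-linkage chaining
#'
#' Consecutive variants whose reference footprints are within `distance` bp of
#' each other join one cohort; the cohort extends until no further variant is
#' reachable. Input variants must be pairwise non-overlapping.
#'
#' @param variants non-overlapping phased variant table.
#' @param distance chaining distance in bp (default 25).
#' @return the variant table with a `cohort_id` column, keyed by cohort.
#' @export
build_cohorts <- function(variants, distance = 25L) {
  v <- copy(variants)
  if (nrow(v) == 0L) { v[, cohort_id := integer(0)]; return(v[]) }
  setkey(v, chrom, pos)
  bad <- v[, any(foot_start <= shift(cummax(as.integer(foot_end)), fill = -1L)), by = chrom]
  if (any(bad$V1))
    stop("overlapping variants present; run remove_overlapping_variants() first")
  v[, cohort_id := {
    gap <- foot_start - shift(foot_end, fill = foot_start[1])
    cumsum(gap > distance)
  }, by = chrom]
  v[, cohort_id := rleid(chrom, cohort_id)]
  v[]
}

#' Write kept/removed site reports
#' @param x variant table (with optional `reason` column)
#' @param path output TSV path
#' @export
write_site_report <- function(x, path) {
  cols <- intersect(c("chrom", "pos", "ref", "alt", "reason"), names(x))
  write_tsv(x[, ..cols], path)
}
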