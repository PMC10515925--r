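#' Build a run configuration
#'
#' Collects every path and tunable of the three analysis modes, with the
#' published defaults. A config round-trips through JSON
#' ([write_config()] / [read_config()]) and is embedded in each run's
#' provenance record.
#'
#' @param mode one of `"simulate"`, `"predict"`, `"scan"`, `"compare"`.
#' @param reference,vcf,sam,sam_b,truth,mpileup,bed input paths (mode
#'   dependent; `sam` may be an internal alignment table in programmatic
#'   use).
#' @param out_dir output directory (created if absent).
#' @param flank context flank length (5 bp).
#' @param cohort_distance cohort chaining distance (25 bp).
#' @param max_effective effective-variant cap (70 bp).
#' @param radius balanced-circle radius (0.1).
#' @param slope_hi,slope_lo loss-wedge slopes (2, 0.5).
#' @param flux_reads mismapped-read threshold (5).
#' @param max_mapq aligner MAPQ ceiling (42).
#' @param window,step scan window geometry (400, 100 bp).
#' @param biased_min,susp_min scan score thresholds (5, 3).
#' @param chain_gap region chaining distance (1000 bp).
#' @param sample_fraction baseline window sample fraction (1/1000).
#' @param coverage_per_hap,read_len,frag_mean,frag_sd,error_rate internal
#'   simulator settings.
#' @param seed master seed; per-stage seeds derive from it.
#' @param make_plots write diagnostic plots in simulate mode.
#' @return a `bias_config` list.
#' @export
bias_config <- function(mode = c("simulate", "predict", "scan", "compare"),
                        reference = NULL, vcf = NULL, sam = NULL, sam_b = NULL,
                        truth = NULL, mpileup = NULL, bed = NULL,
                        out_dir = tempfile("biasbench_"),
                        flank = 5L, cohort_distance = 25L, max_effective = 70L,
                        radius = 0.1, slope_hi = 2, slope_lo = 0.5,
                        flux_reads = 5L, max_mapq = 42L,
                        window = 400L, step = 100L,
                        biased_min = 5, susp_min = 3, chain_gap = 1000L,
                        sample_fraction = 1 / 1000,
                        coverage_per_hap = 15, read_len = 150L,
                        frag_mean = 400, frag_sd = 50, error_rate = 0,
                        seed = 1L, make_plots = FALSE) {
  cfg <- list(mode = match.arg(mode), reference = reference, vcf = vcf,
              sam = sam, sam_b = sam_b, truth = truth, mpileup = mpileup,
              bed = bed, out_dir = out_dir, flank = flank,
              cohort_distance = cohort_distance,
              max_effective = max_effective, radius = radius,
              slope_hi = slope_hi, slope_lo = slope_lo,
              flux_reads = flux_reads, max_mapq = max_mapq, window = window,
              step = step, biased_min = biased_min, susp_min = susp_min,
              chain_gap = chain_gap, sample_fraction = sample_fraction,
              coverage_per_hap = coverage_per_hap, read_len = read_len,
              frag_mean = frag_mean, frag_sd = frag_sd,
              error_rate = error_rate, seed = seed, make_plots = make_plots)
  class(cfg) <- "bias_config"
  cfg
}

#' @rdname bias_config
#' @param cfg a `bias_config`.
#' @param path JSON path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname bias_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(bias_config, cfg[!vapply(cfg, is.null, logical(1))])
}

write_provenance <- function(cfg, extra = list()) {
  rec <- c(list(package = "biasbench",
                version = as.character(packageVersion("biasbench")),
                r_version = as.character(getRversion()),
                config = unclass(cfg)),
           extra)
  jsonlite::write_json(rec, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
}

load_alignments <- function(x) {
  if (is.character(x)) read_sam(x) else as.data.table(x)
}

#' Run simulate mode end to end
#'
#' Filters and structures the phased variants, builds the diploid consensus,
#' simulates truth-tagged reads (unless an external alignment + truth table
#' is supplied), places the reads with the perfect aligner, runs both
#' assignment algorithms, computes SB/MB/AB and NMB/NAB, classifies every
#' HET site, and writes the balance table, the category summary, the indel
#' strata table and a provenance record (plus diagnostic plots when
#' requested).
#'
#' @param cfg a `bias_config` with `mode = "simulate"`; requires `reference`
#'   and `vcf` paths. Supplying `sam` without `truth` is an error.
#' @return list with `balance` (classified site table), `summary`,
#'   `strata`, `paths` of the written files.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "bias_config"), !is.null(cfg$reference),
            !is.null(cfg$vcf))
  if (!is.null(cfg$sam) && is.null(cfg$truth))
    stop("external alignments need a truth table (TSV: read_id, hap, chrom, ",
         "start, end, mate, ref_start, ref_end); simulate mode measures SB ",
         "and MB from it")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  reference <- read_fasta(cfg$reference)
  variants <- load_phased_variants(cfg$vcf)
  if (nrow(variants[het == TRUE]) == 0L)
    warning("no HET variants in ", cfg$vcf, "; balance table will be empty")
  flt <- remove_overlapping_variants(variants)
  haps <- build_diploid_consensus(reference, flt$kept)
  if (is.null(cfg$sam)) {
    sim <- simulate_reads(haps, coverage_per_hap = cfg$coverage_per_hap,
                          read_len = cfg$read_len, frag_mean = cfg$frag_mean,
                          frag_sd = cfg$frag_sd, error_rate = cfg$error_rate,
                          seed_hap1 = cfg$seed, seed_hap2 = cfg$seed + 1L)
    truth <- sim$truth
    aln <- perfect_align(sim$reads, haps, max_mapq = cfg$max_mapq)
  } else {
    aln <- load_alignments(cfg$sam)
    truth <- if (is.character(cfg$truth)) read_truth(cfg$truth) else
      as.data.table(cfg$truth)
  }
  asg <- assign_reads(aln, flt$kept, haps, flank = cfg$flank,
                      distance = cfg$cohort_distance,
                      max_effective = cfg$max_effective)
  bal <- site_balance(asg, truth, aln)
  cls <- classify_balance(bal, "context", radius = cfg$radius,
                          slope_hi = cfg$slope_hi, slope_lo = cfg$slope_lo,
                          flux_reads = cfg$flux_reads)
  summ <- summarize_categories(cls)
  strata <- alt_fraction_by_length(bal)
  paths <- c(balance = file.path(cfg$out_dir, "balance.tsv"),
             summary = file.path(cfg$out_dir, "category_summary.tsv"),
             strata = file.path(cfg$out_dir, "indel_strata.tsv"),
             removed = file.path(cfg$out_dir, "removed_sites.tsv"),
             assignments = file.path(cfg$out_dir, "assignments.tsv"))
  write_tsv(asg$calls, paths["assignments"])
  write_tsv(cls, paths["balance"])
  write_tsv(summ, paths["summary"])
  write_tsv(strata, paths["strata"])
  write_site_report(flt$removed, paths["removed"])
  if (isTRUE(cfg$make_plots)) {
    plot_nmb_nab(cls, radius = cfg$radius, slope_hi = cfg$slope_hi,
                 slope_lo = cfg$slope_lo,
                 file = file.path(cfg$out_dir, "nmb_nab.png"))
  }
  write_provenance(cfg, list(n_sites = nrow(cls),
                             n_removed = nrow(flt$removed)))
  invisible(list(balance = cls, summary = summ, strata = strata,
                 paths = paths))
}

#' Run predict mode end to end
#'
#' Context-aware assignment on real (truth-free) alignments: per-HET AB and
#' mean MAPQ, the affected-HET phasing filter, both prediction scores, and a
#' ranked-site table. When a labelled balance table from a simulation run is
#' given, ROC/PR evaluation tables are written as well.
#'
#' @param cfg a `bias_config`; requires `reference`, `vcf` and `sam`.
#' @param labels optional classified balance table (from [run_simulate()])
#'   whose categories are transferred as ground truth.
#' @return list with `ranked` (data.table) and, when labelled, `evaluation`.
#' @export
run_predict <- function(cfg, labels = NULL) {
  stopifnot(inherits(cfg, "bias_config"), !is.null(cfg$reference),
            !is.null(cfg$vcf), !is.null(cfg$sam))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  reference <- read_fasta(cfg$reference)
  variants <- load_phased_variants(cfg$vcf)
  flt <- remove_overlapping_variants(variants)
  haps <- build_diploid_consensus(reference, flt$kept)
  aln <- load_alignments(cfg$sam)
  asg <- assign_reads(aln, flt$kept, haps, flank = cfg$flank,
                      distance = cfg$cohort_distance,
                      max_effective = cfg$max_effective,
                      methods = "context")
  sites <- asg$sites
  a <- aln[, .(chrom, start = pos, end = pos + cigar_ref_width_v(cigar) - 1L,
               read_id, mapq, idx = seq_len(.N))]
  pr <- cover_pairs(a, site_intervals(sites))
  ab <- compute_AB_spanning(asg$calls, sites, pr[, .(read_id, site_idx)])
  mq <- pr[, .(avg_mapq = mean(mapq)), by = site_idx]
  tab <- sites[, .(chrom, pos, ref, alt, var_class, var_length)]
  tab[, site_idx := seq_len(.N)]
  tab <- ab[tab, on = "site_idx"]
  tab <- mq[tab, on = "site_idx"]
  setnames(tab, "AB", "AB_context")
  ranked <- rank_sites(tab[!is.na(AB_context)], max_mapq = cfg$max_mapq)
  out <- list(ranked = ranked)
  paths <- c(ranked = file.path(cfg$out_dir, "ranked_sites.tsv"))
  cols <- intersect(c("chrom", "pos", "ref", "alt", "var_class", "var_length",
                      "avg_mapq", "AB_context", "score_mul", "score_add",
                      "rank"), names(ranked))
  write_tsv(ranked[, ..cols], paths["ranked"])
  if (!is.null(labels)) {
    lab <- labels[, .(chrom, pos, biased = !is.na(category) &
                        category != "balanced")]
    ev <- lab[ranked, on = c("chrom", "pos"), nomatch = NULL]
    ev <- ev[!is.na(biased)]
    if (length(unique(ev$biased)) < 2L) {
      warning("transferred labels contain a single class; ",
              "skipping ROC/PR evaluation")
    } else {
      eval_mul <- evaluate_predictions(ev$score_mul, ev$biased)
      eval_add <- evaluate_predictions(ev$score_add, ev$biased)
      out$evaluation <- list(mul = eval_mul, add = eval_add)
      write_tsv(data.table(score = c("mul", "add"),
                           auc = c(eval_mul$auc, eval_add$auc),
                           auprc = c(eval_mul$auprc, eval_add$auprc)),
                file.path(cfg$out_dir, "evaluation.tsv"))
    }
  }
  write_provenance(cfg, list(n_ranked = nrow(ranked)))
  out$paths <- paths
  invisible(out)
}

#' Run scan mode end to end
#'
#' Builds (or reads) the pileup, estimates the Z-score baseline by window
#' sampling (or uses supplied parameters), scores windows, calls biased and
#' suspicious regions, and writes per-window scores plus BED files.
#'
#' @param cfg a `bias_config`; requires one of `sam` or `mpileup`.
#' @param baseline optional precomputed `list(mean=, sd=)`, bypassing
#'   sampling.
#' @return list with `windows`, `regions`, `paths`.
#' @export
run_scan <- function(cfg, baseline = NULL) {
  stopifnot(inherits(cfg, "bias_config"),
            !is.null(cfg$sam) || !is.null(cfg$mpileup))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  pile <- if (!is.null(cfg$mpileup)) read_mpileup(cfg$mpileup)
          else pileup_from_alignments(load_alignments(cfg$sam))
  if (nrow(pile) == 0L) {
    regions <- data.table(chrom = character(), start = integer(),
                          end = integer(), label = character(),
                          peak_score = numeric(), n_windows = integer())
    wm <- data.table(chrom = character(), window_start = integer(),
                     window_end = integer(), covered = integer(),
                     RD = numeric(), VD = numeric(), ND = numeric(),
                     z_rd = numeric(), z_vd = numeric(), z_nd = numeric(),
                     bias_score = numeric())
  } else {
    if (is.null(baseline))
      baseline <- sample_baseline(pile, fraction = cfg$sample_fraction,
                                  seed = cfg$seed, window = cfg$window,
                                  step = cfg$step)
    wm <- combine_scores(window_measures(pile, cfg$window, cfg$step),
                         baseline)
    regions <- call_regions(wm, biased_min = cfg$biased_min,
                            susp_min = cfg$susp_min,
                            chain_gap = cfg$chain_gap)
  }
  paths <- c(windows = file.path(cfg$out_dir, "window_scores.tsv"),
             biased = file.path(cfg$out_dir, "biased_regions.bed"),
             suspicious = file.path(cfg$out_dir, "suspicious_regions.bed"))
  write_tsv(wm, paths["windows"])
  write_bed(regions[label == "biased"], paths["biased"])
  write_bed(regions[label == "suspicious"], paths["suspicious"])
  write_provenance(cfg, list(n_regions = nrow(regions)))
  invisible(list(windows = wm, regions = regions, paths = paths))
}

#' Compare two alignment workflows with scan mode
#'
#' Scores both inputs against a single jointly sampled baseline (separate
#' baselines are an error: the less biased workflow would otherwise be held
#' to a stricter standard), calls regions for each, and reports which biased
#' regions of one workflow the other improves.
#'
#' @param cfg a `bias_config`; requires `sam` and `sam_b` (or two mpileups
#'   as a length-2 character vector in `mpileup`).
#' @param baseline optional shared `list(mean=, sd=)` parameters.
#' @return list with `regions_a`, `regions_b`, `comparison`, `paths`.
#' @export
run_compare <- function(cfg, baseline = NULL) {
  stopifnot(inherits(cfg, "bias_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  piles <- if (!is.null(cfg$mpileup)) {
    stopifnot(length(cfg$mpileup) == 2L)
    lapply(cfg$mpileup, read_mpileup)
  } else {
    stopifnot(!is.null(cfg$sam), !is.null(cfg$sam_b))
    list(pileup_from_alignments(load_alignments(cfg$sam)),
         pileup_from_alignments(load_alignments(cfg$sam_b)))
  }
  if (is.null(baseline))
    baseline <- sample_baseline(piles, fraction = cfg$sample_fraction,
                                seed = cfg$seed, window = cfg$window,
                                step = cfg$step)
  score <- function(p) combine_scores(window_measures(p, cfg$window,
                                                      cfg$step), baseline)
  rga <- call_regions(score(piles[[1]]), cfg$biased_min, cfg$susp_min,
                      cfg$chain_gap)
  rgb <- call_regions(score(piles[[2]]), cfg$biased_min, cfg$susp_min,
                      cfg$chain_gap)
  cmp <- compare_runs(rga, rgb, piles[[1]], piles[[2]])
  paths <- c(a = file.path(cfg$out_dir, "regions_a.bed"),
             b = file.path(cfg$out_dir, "regions_b.bed"),
             report = file.path(cfg$out_dir, "comparison.tsv"))
  write_bed(rga, paths["a"])
  write_bed(rgb, paths["b"])
  write_tsv(cmp$summary, paths["report"])
  write_provenance(cfg, list(n_regions_a = nrow(rga), n_regions_b = nrow(rgb)))
  invisible(list(regions_a = rga, regions_b = rgb, comparison = cmp,
                 paths = paths))
}
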