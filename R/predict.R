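#' Two-feature bias prediction score for one site
#'
#' Combines the mean mapping quality of the reads over a HET site (normalised
#' by the aligner's maximum MAPQ) with the site's assignment balance, by
#' multiplication or by addition:
#' \deqn{mul: ((avgMAPQ - maxMAPQ) / maxMAPQ) \times AB}
#' \deqn{add: ((avgMAPQ - maxMAPQ) / maxMAPQ) \times 1.5 + AB}
#' Lower (more negative) scores indicate sites more likely to be affected by
#' reference bias: the MAPQ term is 0 at the MAPQ ceiling and approaches -1
#' (mul) / -1.5 (add) as the overlapping reads become ambiguous. `max_mapq`
#' must match the aligner (42 for Bowtie 2/BWA-MEM, 60 for VG Giraffe) and is
#' never autodetected.
#'
#' @param avg_mapq mean MAPQ of reads over the site, in `[0, max_mapq]`.
#' @param assigned_balance assignment balance in `[0, 1]`.
#' @param max_mapq aligner MAPQ ceiling (default 42).
#' @param method `"mul"` or `"add"`.
#' @param folded if `TRUE`, substitute the folded deviation
#'   `2 * |AB - 0.5|` for the raw AB, so that bias toward either allele moves
#'   the score the same way (off by default: the raw equations).
#' @return numeric score vector.
#' @export
score_site <- function(avg_mapq, assigned_balance, max_mapq = 42,
                       method = c("mul", "add"), folded = FALSE) {
  method <- match.arg(method)
  if (any(avg_mapq > max_mapq, na.rm = TRUE))
    stop("avg_mapq exceeds max_mapq (", max_mapq,
         "); wrong maximum for this aligner?")
  ab <- if (folded) 2 * abs(assigned_balance - 0.5) else assigned_balance
  q <- (avg_mapq - max_mapq) / max_mapq
  if (method == "mul") q * ab else q * 1.5 + ab
}

#' Filter HET sites degraded by incomplete phasing information
#'
#' Drops sites where the assignment evidence itself is untrustworthy: (1)
#' more than 90% of the covering reads carry an OTHER allele, or (2) one of
#' the two HET alleles has no read support at all and more than 40% of reads
#' are OTHER.
#'
#' @param site_stats data.table with per-site tallies `n_ref`, `n_alt`,
#'   `n_both`, `n_other`.
#' @param other_frac_hi rule-1 OTHER fraction threshold (default 0.9).
#' @param other_frac_lo rule-2 OTHER fraction threshold (default 0.4).
#' @return `list(kept=, dropped=)`; `dropped` has a `reason` column.
#' @export
filter_affected_hets <- function(site_stats, other_frac_hi = 0.9,
                                 other_frac_lo = 0.4) {
  x <- copy(site_stats)
  tot <- x$n_ref + x$n_alt + x$n_both + x$n_other
  fo <- ifelse(tot > 0L, x$n_other / tot, 0)
  rule1 <- fo > other_frac_hi
  rule2 <- (x$n_ref == 0L | x$n_alt == 0L) & fo > other_frac_lo
  x[, reason := ifelse(rule1, "other_gt_90pct",
                       ifelse(rule2, "allele_absent_other_gt_40pct",
                              NA_character_))]
  list(kept = x[is.na(reason)][, reason := NULL][],
       dropped = x[!is.na(reason)])
}

#' Rank HET sites by predicted bias
#'
#' @param balances balance table with `avg_mapq`, `AB_context` and tallies.
#' @param max_mapq aligner MAPQ ceiling.
#' @param folded see [score_site()].
#' @return the filtered table with `score_mul`, `score_add` and `rank`
#'   (1 = most biased, by the multiplicative score).
#' @export
rank_sites <- function(balances, max_mapq = 42, folded = FALSE) {
  flt <- filter_affected_hets(balances)
  x <- flt$kept[!is.na(AB_context) & !is.na(avg_mapq)]
  x[, score_mul := score_site(avg_mapq, AB_context, max_mapq, "mul",
                              folded = folded)]
  x[, score_add := score_site(avg_mapq, AB_context, max_mapq, "add",
                              folded = folded)]
  setorder(x, score_mul, pos)
  x[, rank := seq_len(.N)]
  x[]
}

#' ROC and PR curves for a bias score against labels
#'
#' Sites are ranked from most to least biased (ascending score: low scores
#' flag bias) and standard ROC and precision-recall curves are traced over
#' every threshold; areas use the trapezoid rule. Labels collapse every bias
#' category into a single positive class.
#'
#' @param scores numeric score vector.
#' @param labels logical vector, `TRUE` = biased.
#' @param direction `"low"` (default) when low scores mean biased, `"high"`
#'   otherwise.
#' @return `list(roc=, pr=, auc=, auprc=)`; `roc`/`pr` are data.tables of
#'   curve points.
#' @export
evaluate_predictions <- function(scores, labels, direction = c("low", "high")) {
  direction <- match.arg(direction)
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.logical(labels[ok])
  if (length(unique(labels)) < 2L)
    stop("labels contain a single class; ROC/PR undefined")
  s <- if (direction == "low") scores else -scores
  o <- order(s)
  lab <- labels[o]; sv <- s[o]
  # collapse threshold steps at tied scores
  n <- length(lab)
  last_of_tie <- c(sv[-n] != sv[-1], TRUE)
  tp <- cumsum(lab)[last_of_tie]
  fp <- cumsum(!lab)[last_of_tie]
  P <- sum(lab); N <- sum(!lab)
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  roc <- data.table(fpr = fpr, tpr = tpr)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  prec <- tp / (tp + fp); rec <- tp / P
  pr <- data.table(recall = c(0, rec), precision = c(prec[1], prec))
  auprc <- sum(diff(c(0, rec)) * (c(prec[1], head(prec, -1)) + prec) / 2)
  list(roc = roc, pr = pr, auc = auc, auprc = auprc)
}
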