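## Regulation calls: IP target calling, mutant abundance changes, the
## stabilized / co-regulated classification, target-set enrichment,
## cross-mutant concordance, and double-mutant additivity.

#' Call IP-enriched target transcripts
#'
#' IP log2 enrichment is the mean log2 IP expression minus the mean log2
#' control-IP expression (computed on un-quantile-normalized IP data).  A
#' transcript is a target iff its enrichment strictly exceeds
#' `log2(threshold_fold)`: "more than 3-fold enriched" excludes the
#' boundary.
#'
#' @param expr a `polystab_expr` expression matrix.
#' @param sheet sample sheet.
#' @param threshold_fold linear IP enrichment threshold (default 3).
#' @param dataset sample-sheet dataset holding the IP experiment.
#' @return data.frame: transcript_id, ip_log2_enrichment, is_target.
#' @export
call_targets <- function(expr, sheet, threshold_fold = 3, dataset = "ip") {
  stopifnot(inherits(expr, "polystab_expr"))
  sheet <- sheet[sheet$dataset == dataset, , drop = FALSE]
  ip <- sheet$sample_id[sheet$assay == "ip"]
  ctrl <- sheet$sample_id[sheet$assay == "control_ip"]
  if (!length(ip)) stop("no IP samples in the sheet", call. = FALSE)
  if (!length(ctrl)) stop("missing control IP samples", call. = FALSE)
  enr <- rowMeans(expr$values[, ip, drop = FALSE]) -
    rowMeans(expr$values[, ctrl, drop = FALSE])
  data.frame(transcript_id = rownames(expr$values),
             ip_log2_enrichment = enr,
             is_target = enr > log2(threshold_fold),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Log2 abundance change of a genotype relative to baseline
#'
#' delta = mean log2 expression in the genotype minus mean log2 expression
#' in the baseline, over the samples of one dataset (so that both sides
#' share a normalization scheme).
#'
#' @param expr a `polystab_expr`.
#' @param sheet sample sheet.
#' @param genotype genotype whose change is wanted.
#' @param baseline baseline genotype (default wild type).
#' @param dataset sample-sheet dataset to use.
#' @param assay assay of the compared samples.
#' @return named numeric vector of per-transcript log2 deltas.
#' @export
abundance_change <- function(expr, sheet, genotype, baseline = "wt",
                             dataset = "gonad", assay = "total") {
  stopifnot(inherits(expr, "polystab_expr"))
  sheet <- sheet[sheet$dataset == dataset & sheet$assay == assay, ,
                 drop = FALSE]
  g <- sheet$sample_id[sheet$genotype == genotype]
  b <- sheet$sample_id[sheet$genotype == baseline]
  if (!length(g)) stop("no samples for genotype ", genotype, call. = FALSE)
  if (!length(b)) stop("no samples for baseline ", baseline, call. = FALSE)
  rowMeans(expr$values[, g, drop = FALSE]) -
    rowMeans(expr$values[, b, drop = FALSE])
}

#' Assemble the per-transcript regulation call table
#'
#' Combines IP target calls with the mutant abundance deltas and applies the
#' stability classification of [call_co_regulated()].
#'
#' @param expr_ip expression matrix carrying the IP dataset (must be
#'   un-quantile-normalized for the IP columns).
#' @param expr_abundance expression matrix carrying the gonad (and
#'   optionally RNAi) datasets; defaults to `expr_ip` when one matrix holds
#'   everything.
#' @param sheet sample sheet.
#' @param ip_fold,gld1_cut,cgh1_cut thresholds (linear IP fold; log2 cuts).
#' @param rnai if TRUE also compute the RNAi knockdown delta.
#' @return a RegulationCallTable data.frame: transcript_id,
#'   ip_log2_enrichment, is_target, delta_gld1, delta_cgh1, delta_double,
#'   (delta_rnai), stabilized, co_regulated.
#' @export
build_regulation_calls <- function(expr_ip, sheet, expr_abundance = expr_ip,
                                   ip_fold = 3, gld1_cut = -1,
                                   cgh1_cut = -0.5, rnai = TRUE) {
  calls <- call_targets(expr_ip, sheet, threshold_fold = ip_fold)
  calls$delta_gld1 <- abundance_change(expr_abundance, sheet, "gld1")
  calls$delta_cgh1 <- abundance_change(expr_abundance, sheet, "cgh1ts")
  calls$delta_double <- abundance_change(expr_abundance, sheet, "double")
  if (rnai) {
    calls$delta_rnai <- abundance_change(expr_abundance, sheet, "rnai_cgh1",
                                         baseline = "rnai_mock",
                                         dataset = "rnai")
  }
  call_co_regulated(calls, gld1_cut = gld1_cut, cgh1_cut = cgh1_cut)
}

#' Classify stabilized and co-regulated transcripts
#'
#' A transcript is `stabilized` iff it is a target and its gld-1 mutant
#' abundance change falls strictly below the log2 cut (-1 by default, i.e.
#' more than two-fold reduced).  It is `co_regulated` iff it is additionally
#' reduced below the cgh-1ts cut (-0.5 log2).  Both cuts are strict, so
#' boundary values are excluded; non-targets are never co-regulated however
#' strongly reduced.
#'
#' @param calls data.frame with is_target, delta_gld1, delta_cgh1.
#' @param gld1_cut,cgh1_cut log2 cut-offs.
#' @return `calls` with logical columns `stabilized` and `co_regulated`.
#' @export
call_co_regulated <- function(calls, gld1_cut = -1, cgh1_cut = -0.5) {
  stopifnot(all(c("is_target", "delta_gld1", "delta_cgh1") %in% names(calls)))
  calls$stabilized <- calls$is_target & calls$delta_gld1 < gld1_cut
  calls$co_regulated <- calls$stabilized & calls$delta_cgh1 < cgh1_cut
  calls
}

#' Target-set enrichment of a gene set (hypergeometric)
#'
#' Fold enrichment is the target frequency in the set over the target
#' frequency in the universe; significance is the hypergeometric upper tail
#' P[X >= k] for X ~ Hypergeom(N, K, n).  A two-proportion z test is
#' reported alongside as a documented alternative.
#'
#' @param set_members character vector, a subset of `universe`.
#' @param target_flags named logical vector of target status covering the
#'   universe.
#' @param universe character vector of all considered transcripts.
#' @return an `enrichment_result` list: k, n, K, N, set_fraction,
#'   background_fraction, fold, p_hypergeometric, p_two_proportion.
#' @export
enrichment <- function(set_members, target_flags, universe) {
  if (!length(set_members) || !length(universe)) {
    stop("set and universe must be non-empty", call. = FALSE)
  }
  if (!all(set_members %in% universe)) {
    stop("the gene set must be a subset of the universe", call. = FALSE)
  }
  flags <- target_flags[universe]
  stopifnot(!anyNA(flags))
  k <- sum(target_flags[set_members])
  n <- length(set_members)
  K <- sum(flags)
  N <- length(universe)
  fold <- (k / n) / (K / N)
  p_hyper <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p1 <- k / n
  p0 <- K / N
  pp <- (k + K) / (n + N)
  z <- if (pp %in% c(0, 1)) 0 else {
    (p1 - p0) / sqrt(pp * (1 - pp) * (1 / n + 1 / N))
  }
  structure(list(k = k, n = n, K = K, N = N,
                 set_fraction = p1, background_fraction = p0, fold = fold,
                 p_hypergeometric = p_hyper,
                 p_two_proportion = pnorm(z, lower.tail = FALSE)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("target-set enrichment: %d/%d in set vs %d/%d in universe\n",
              x$k, x$n, x$K, x$N))
  cat(sprintf("  %.1f%% vs %.1f%% background: fold = %.2f, hypergeometric p = %.3g\n",
              100 * x$set_fraction, 100 * x$background_fraction, x$fold,
              x$p_hypergeometric))
  invisible(x)
}

#' Expressed-transcript universe
#'
#' Stand-in for "all germline mRNAs": transcripts whose mean wild-type total
#' expression lies at or above a quantile floor of that distribution.
#'
#' @param expr a `polystab_expr`.
#' @param sheet sample sheet.
#' @param floor_quantile expression floor as a quantile (default 0.4).
#' @param dataset,assay,genotype samples defining the reference expression.
#' @return character vector of transcript ids.
#' @export
define_universe <- function(expr, sheet, floor_quantile = 0.4,
                            dataset = "gonad", assay = "total",
                            genotype = "wt") {
  sheet <- sheet[sheet$dataset == dataset & sheet$assay == assay &
                   sheet$genotype == genotype, , drop = FALSE]
  m <- rowMeans(expr$values[, sheet$sample_id, drop = FALSE])
  keep <- !is.na(m) & m >= quantile(m, floor_quantile, na.rm = TRUE)
  rownames(expr$values)[keep]
}

#' Pearson concordance of two mutants' abundance changes
#'
#' @param delta_a,delta_b named numeric vectors of log2 changes.
#' @return Pearson r over the shared non-missing transcripts; NA (with a
#'   warning) if either vector is constant.
#' @export
cross_mutant_concordance <- function(delta_a, delta_b) {
  shared <- intersect(names(delta_a), names(delta_b))
  a <- delta_a[shared]
  b <- delta_b[shared]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) stop("need at least 3 shared transcripts", call. = FALSE)
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0) {
    warning("zero variance; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(a[ok], b[ok])
}

#' Double-mutant additivity of stability effects
#'
#' Per transcript, score = delta_double - (delta_gld1 + delta_cgh1); zero
#' for perfectly additive effects.  The set summary also reports the
#' fraction of transcripts whose double-mutant change is below both single
#' mutants' ("further reduced").
#'
#' @param delta_gld1,delta_cgh1,delta_double numeric vectors (aligned).
#' @return list with `score` (per-transcript), `mean_score`, and
#'   `fraction_further_reduced`.
#' @export
additivity_score <- function(delta_gld1, delta_cgh1, delta_double) {
  stopifnot(length(delta_gld1) == length(delta_cgh1),
            length(delta_gld1) == length(delta_double))
  score <- delta_double - (delta_gld1 + delta_cgh1)
  further <- delta_double < pmin(delta_gld1, delta_cgh1)
  list(score = score, mean_score = mean(score, na.rm = TRUE),
       fraction_further_reduced = mean(further, na.rm = TRUE))
}

#' Sensitivity, specificity and FDR of a call against planted truth
#'
#' @param called,truth logical vectors (aligned).
#' @return list with sensitivity, specificity, fdr, and the confusion
#'   counts.
#' @export
recovery_metrics <- function(called, truth) {
  ok <- !is.na(called) & !is.na(truth)
  called <- called[ok]
  truth <- truth[ok]
  tp <- sum(called & truth)
  fp <- sum(called & !truth)
  fn <- sum(!called & truth)
  tn <- sum(!called & !truth)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
       tp = tp, fp = fp, fn = fn, tn = tn)
}
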