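## Translation state: polysomal/total log2 ratios per genotype, depletion
## calls, genotype shift tests, and the spike-in-normalized fraction-level
## polysomal association used for qPCR validation.

#' Polysomal/total translation-state ratios per genotype
#'
#' For each genotype with matched polysomal and total samples, the ratio is
#' the mean log2 polysomal expression minus the mean log2 total expression
#' per transcript (fractions 8-12 pooled versus fractions 1-12 upstream).
#' Transcripts missing either side are flagged missing.  The wild-type ratio
#' carries the depletion call; the shift column is the mutant ratio minus
#' the wild-type ratio.
#'
#' @param expr a `polystab_expr` expression matrix.
#' @param sheet sample sheet.
#' @param genotypes genotypes to compute ratios for; the first is the
#'   baseline used for the depletion call and the shift.
#' @param dataset sample-sheet dataset holding the polysome experiment.
#' @param threshold_fold depletion threshold passed to [call_depleted()].
#' @return a TranslationTable data.frame: transcript_id, one `ratio_<g>`
#'   column per genotype, `shift`, `depleted`.
#' @export
polysome_total_ratio <- function(expr, sheet, genotypes = c("wt", "gld1"),
                                 dataset = "polysome", threshold_fold = 2) {
  stopifnot(inherits(expr, "polystab_expr"))
  values <- expr$values
  sheet <- sheet[sheet$dataset == dataset, , drop = FALSE]
  out <- data.frame(transcript_id = rownames(values),
                    stringsAsFactors = FALSE)
  for (g in genotypes) {
    pol <- sheet$sample_id[sheet$assay == "polysomal" & sheet$genotype == g]
    tot <- sheet$sample_id[sheet$assay == "total" & sheet$genotype == g]
    if (!length(pol) || !length(tot)) {
      stop("no matched polysomal/total samples for genotype ", g,
           call. = FALSE)
    }
    out[[paste0("ratio_", g)]] <-
      rowMeans(values[, pol, drop = FALSE]) -
      rowMeans(values[, tot, drop = FALSE])
  }
  base <- out[[paste0("ratio_", genotypes[1])]]
  if (length(genotypes) > 1L) {
    out$shift <- out[[paste0("ratio_", genotypes[2])]] - base
  }
  out$depleted <- call_depleted(base, threshold_fold)
  out
}

#' Call polysome-depleted transcripts
#'
#' A transcript is depleted iff its polysomal/total log2 ratio is strictly
#' below -log2(threshold_fold): "more than two-fold depleted" excludes the
#' boundary, so a ratio of exactly -1 is not called at the default 2-fold
#' threshold.
#'
#' @param ratio numeric vector of polysomal/total log2 ratios.
#' @param threshold_fold linear fold threshold (default 2).
#' @return logical vector (NA where the ratio is missing).
#' @export
call_depleted <- function(ratio, threshold_fold = 2) {
  ratio < -log2(threshold_fold)
}

#' Welch test for a gene set's translation-state shift between genotypes
#'
#' Compares the polysomal/total ratio distribution of a gene set between two
#' genotypes with a two-sample Welch t test (the box-plot comparison of the
#' figure style this reproduces), and reports the per-transcript median
#' shift.  Any gene-set partition (e.g. stabilized versus non-stabilized
#' targets) can be tested by passing the corresponding id vectors.
#'
#' @param table a TranslationTable from [polysome_total_ratio()].
#' @param gene_set character vector of transcript ids.
#' @param genotypes length-2 character vector (baseline first).
#' @return list with `t`, `p`, `n` (per-genotype counts), `median_shift`
#'   (median of per-transcript ratio differences), `mean_shift`.
#' @export
shift_test <- function(table, gene_set, genotypes = c("wt", "gld1")) {
  cols <- paste0("ratio_", genotypes)
  stopifnot(all(cols %in% names(table)))
  rows <- table[table$transcript_id %in% gene_set, cols]
  rows <- rows[complete.cases(rows), , drop = FALSE]
  x <- rows[[1]]
  y <- rows[[2]]
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 transcripts with ratios in both genotypes",
         call. = FALSE)
  }
  if (sd(x) == 0 && sd(y) == 0) {
    t_stat <- if (mean(x) == mean(y)) 0 else sign(mean(y) - mean(x)) * Inf
    p <- if (mean(x) == mean(y)) 1 else 0
  } else {
    tt <- t.test(y, x, var.equal = FALSE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  list(t = t_stat, p = p,
       n = setNames(c(length(x), length(y)), genotypes),
       median_shift = median(y - x), mean_shift = mean(y - x))
}

#' Spike-in normalization of gradient fraction quantities
#'
#' Corrects per-fraction RNA-isolation and reverse-transcription efficiency:
#' `corrected_i = q_i / s_i * mean(s)`.  Multiplying any fraction's quantity
#' and spike by a common factor leaves the corrected profile unchanged up to
#' one common rescaling (the `mean(s)` factor restores the overall scale and
#' is the only part that moves), so every scale-free downstream statistic --
#' in particular [polysomal_association()] -- is exactly invariant.
#'
#' @param profile long data.frame with transcript_id, condition, fraction,
#'   quantity, spike (as from [simulate_fraction_profiles()]).
#' @return the data.frame with a `corrected` column added.
#' @export
spike_normalize_fractions <- function(profile) {
  if (any(profile$spike <= 0)) {
    stop("spike-in quantities must be positive", call. = FALSE)
  }
  key <- interaction(profile$transcript_id, profile$condition, drop = TRUE)
  mean_s <- stats::ave(profile$spike, key)
  profile$corrected <- profile$quantity / profile$spike * mean_s
  profile
}

#' Polysomal association of spike-corrected fraction profiles
#'
#' Association = sum of corrected quantities in the polysomal fractions
#' (8-12 by default) over the total (fractions 1-12); a number in `[0, 1]`,
#' invariant to global rescaling of a profile.  Profiles with zero total are
#' flagged NA.
#'
#' @param profile long data.frame with a `corrected` column (see
#'   [spike_normalize_fractions()]).
#' @param polysomal_fractions integer fractions counted as polysomal.
#' @return data.frame: transcript_id, condition, association.
#' @export
polysomal_association <- function(profile, polysomal_fractions = 8:12) {
  stopifnot("corrected" %in% names(profile))
  key <- list(transcript_id = profile$transcript_id,
              condition = profile$condition)
  tot <- stats::aggregate(profile$corrected, key, sum)
  pol_rows <- profile$fraction %in% polysomal_fractions
  pol <- stats::aggregate(profile$corrected[pol_rows],
                          lapply(key, function(k) k[pol_rows]), sum)
  out <- merge(tot, pol, by = c("transcript_id", "condition"),
               suffixes = c("_total", "_poly"))
  out$association <- ifelse(out$x_total > 0, out$x_poly / out$x_total,
                            NA_real_)
  out[, c("transcript_id", "condition", "association")]
}
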