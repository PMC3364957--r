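## Synthetic-data generator: annotation, oligo map, planted truth, sample
## sheet, oligo-level intensities, gradient fraction profiles and qPCR
## quantities.  All randomness derives from the config seed via fixed
## per-stage offsets, so each generator is deterministic on its own.

rtruncnorm_left <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(pmax(mean, lower), n))
  qnorm(runif(n, pnorm(lower, mean, sd), 1), mean, sd)
}

#' Simulate transcript annotation, oligo map, and planted truth
#'
#' Transcripts tile a virtual chromosome without overlap; each transcript is
#' covered by at least one fully contained oligo at the configured density.
#' The paired truth table plants, per transcript: IP target status (and a
#' log2 IP enrichment, truncated above the 3-fold cut that defines targets),
#' translation state with a polysomal/total log2 ratio, per-mutant log2
#' abundance effects (additive in the double mutant), and the derived
#' stabilized / co-regulated labels.  UTR binding-motif counts (`gbm_count`)
#' are drawn higher for targets, mirroring motif-driven binding.
#'
#' @param config a [sim_config()].
#' @return a list with `annotation` (transcript_id, chrom, start, end
#'   (0-based half-open), strand, gbm_count), `oligo_map` (oligo_id, chrom,
#'   start, end, strand, mapping_status), and `truth` (planted regulatory
#'   truth per transcript).
#' @examples
#' sim <- simulate_annotation(sim_config(seed = 1, n_transcripts = 10))
#' nrow(sim$annotation)
#' @export
simulate_annotation <- function(config) {
  validate_config(config)
  set.seed(stage_seed(config, "annotation"))
  n <- config$n_transcripts

  len <- sample(seq(config$transcript_length_range[1],
                    config$transcript_length_range[2]), n, replace = TRUE)
  gap <- config$intergenic_gap
  start <- cumsum(c(gap, utils::head(len, -1) + gap))
  annotation <- data.frame(
    transcript_id = sprintf("tx%04d", seq_len(n)),
    chrom = "chrV",
    start = as.integer(start),
    end = as.integer(start + len),
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )

  truth <- simulate_truth(annotation$transcript_id, config)
  annotation$gbm_count <- ifelse(truth$is_target,
                                 1L + rpois(n, 3), rpois(n, 0.3))

  oligo_map <- simulate_oligo_map(annotation, config)
  list(annotation = annotation, oligo_map = oligo_map, truth = truth)
}

simulate_truth <- function(transcript_id, config) {
  n <- length(transcript_id)
  is_target <- runif(n) < config$target_fraction

  ip <- numeric(n)
  ip[is_target] <- rtruncnorm_left(sum(is_target), config$ip_log2_mean,
                                   config$ip_log2_sd, log2(3))
  ip[!is_target] <- rnorm(sum(!is_target), 0, config$ip_null_sd)

  repressed <- runif(n) < ifelse(is_target,
                                 config$repressed_fraction_target,
                                 config$repressed_fraction_nontarget)
  ratio_wt <- ifelse(repressed,
                     rnorm(n, config$depletion_log2_mean,
                           config$depletion_log2_sd),
                     rnorm(n, 0, config$translated_ratio_sd))
  # Loss of the RBP relieves (part of) the depletion of its repressed targets
  ratio_gld1 <- ifelse(repressed & is_target,
                       ratio_wt * (1 - config$gld1_relief), ratio_wt)

  stabilized_draw <- is_target & runif(n) < config$stabilized_fraction
  costab_draw <- stabilized_draw & runif(n) < config$cgh1_costab_prob
  offtarget_destab <- !is_target & runif(n) < config$offtarget_destab_fraction

  delta_gld1 <- rnorm(n, 0, config$null_delta_sd)
  delta_cgh1 <- rnorm(n, 0, config$null_delta_sd)
  delta_gld1[stabilized_draw] <- rnorm(sum(stabilized_draw),
                                       config$delta_gld1_mean,
                                       config$delta_gld1_sd)
  delta_cgh1[costab_draw] <- rnorm(sum(costab_draw),
                                   config$delta_cgh1_mean,
                                   config$delta_cgh1_sd)
  delta_gld1[offtarget_destab] <- rnorm(sum(offtarget_destab),
                                        config$offtarget_delta_mean,
                                        config$offtarget_delta_sd)
  delta_cgh1[offtarget_destab] <- rnorm(sum(offtarget_destab),
                                        config$offtarget_delta_mean,
                                        config$offtarget_delta_sd)

  base_log2 <- log2(rexp(n, rate = 1 / config$base_signal_mean))

  data.frame(
    transcript_id = transcript_id,
    is_target = is_target,
    translation_state = ifelse(repressed, "repressed", "translated"),
    ip_log2_enrichment = ip,
    ratio_log2_wt = ratio_wt,
    ratio_log2_gld1 = ratio_gld1,
    delta_gld1 = delta_gld1,
    delta_cgh1 = delta_cgh1,
    delta_double = delta_gld1 + delta_cgh1,
    delta_rnai = delta_cgh1 + rnorm(n, 0, config$rnai_extra_sd),
    base_log2 = base_log2,
    # emitted labels; recomputable from the planted quantities above
    stabilized = is_target & delta_gld1 < -1,
    co_regulated = is_target & delta_gld1 < -1 & delta_cgh1 < -0.5,
    stringsAsFactors = FALSE
  )
}

simulate_oligo_map <- function(annotation, config) {
  per_tx <- lapply(seq_len(nrow(annotation)), function(i) {
    tx <- annotation[i, ]
    len <- tx$end - tx$start
    n_oligo <- max(1L, floor(len / 1000 * config$oligo_density_per_kb))
    lo <- tx$start
    hi <- tx$end - config$oligo_length
    starts <- if (n_oligo == 1L) {
      as.integer((lo + hi) / 2)
    } else {
      as.integer(round(seq(lo, hi, length.out = n_oligo)))
    }
    data.frame(
      oligo_id = sprintf("%s_o%02d", tx$transcript_id, seq_len(n_oligo)),
      transcript_origin = tx$transcript_id,
      chrom = tx$chrom,
      start = starts,
      end = starts + config$oligo_length,
      strand = tx$strand,
      stringsAsFactors = FALSE
    )
  })
  oligo_map <- do.call(rbind, per_tx)
  n <- nrow(oligo_map)
  status <- sample(c("unique", "multi", "unmapped"), n, replace = TRUE,
                   prob = c(1 - config$multi_fraction - config$unmapped_fraction,
                            config$multi_fraction, config$unmapped_fraction))
  oligo_map$mapping_status <- status
  rownames(oligo_map) <- NULL
  oligo_map
}

#' Sample sheet for the four array datasets
#'
#' Emits the samples of the polysome dataset (polysomal and total mRNA from
#' wild-type and gld-1 animals), the dissected-gonad abundance dataset
#' (wild type and the gld-1, cgh-1ts and double mutants), the RNAi dataset
#' (mock and cgh-1 knockdown), and the IP dataset (IP, control IP, input).
#' Each dataset carries its own quantile-normalization scheme: polysomal and
#' total samples are normalized as two separate groups, the gonad and RNAi
#' datasets each in one step, and the IP dataset is exempt because the IP
#' and control-IP intensity distributions genuinely differ.
#'
#' @param config a [sim_config()].
#' @return a data.frame with columns sample_id, dataset, assay, genotype,
#'   replicate, normalization_group.
#' @export
simulate_sample_sheet <- function(config) {
  validate_config(config)
  reps <- seq_len(config$n_replicates)
  block <- function(dataset, assay, genotype, group) {
    expand.grid(dataset = dataset, assay = assay, genotype = genotype,
                replicate = reps, stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE)[, c("dataset", "assay", "genotype",
                                            "replicate")] |>
      transform(normalization_group = group)
  }
  sheet <- rbind(
    block("polysome", "polysomal", c("wt", "gld1"), "polysome_polysomal"),
    block("polysome", "total", c("wt", "gld1"), "polysome_total"),
    block("gonad", "total", c("wt", "gld1", "cgh1ts", "double"), "gonad"),
    block("rnai", "total", c("rnai_mock", "rnai_cgh1"), "rnai"),
    block("ip", c("ip", "control_ip", "input"), "wt", "ip")
  )
  sheet$sample_id <- sprintf("%s.%s.%s.r%d", sheet$dataset, sheet$assay,
                             sheet$genotype, sheet$replicate)
  rownames(sheet) <- NULL
  sheet[, c("sample_id", "dataset", "assay", "genotype", "replicate",
            "normalization_group")]
}

#' Noise-free planted log2 signal per transcript and sample
#'
#' The deterministic part of the intensity model: per-transcript base
#' abundance plus the planted assay and genotype effects (IP enrichment for
#' targets in IP samples, polysomal depletion of repressed transcripts with
#' partial relief for targets in the gld-1 mutant, and the mutant abundance
#' deltas in total samples).  Used by the intensity generator and, in tests,
#' as the known answer that processing must recover.
#'
#' @param truth truth table from [simulate_annotation()].
#' @param sheet sample sheet from [simulate_sample_sheet()].
#' @return a transcripts x samples numeric matrix of log2 signal.
#' @export
planted_log2_matrix <- function(truth, sheet) {
  geno_delta <- cbind(wt = 0, gld1 = truth$delta_gld1,
                      cgh1ts = truth$delta_cgh1,
                      double = truth$delta_double,
                      rnai_mock = 0, rnai_cgh1 = truth$delta_rnai)
  out <- matrix(NA_real_, nrow(truth), nrow(sheet),
                dimnames = list(truth$transcript_id, sheet$sample_id))
  for (j in seq_len(nrow(sheet))) {
    s <- sheet[j, ]
    if (!s$genotype %in% colnames(geno_delta)) {
      stop("unknown genotype: ", s$genotype, call. = FALSE)
    }
    v <- truth$base_log2 + geno_delta[, s$genotype]
    v <- v + switch(s$assay,
      total = 0,
      input = 0,
      control_ip = 0,
      polysomal = if (s$genotype == "gld1") truth$ratio_log2_gld1
                  else truth$ratio_log2_wt,
      ip = truth$ip_log2_enrichment,
      stop("unknown assay: ", s$assay, call. = FALSE)
    )
    out[, j] <- v
  }
  out
}

#' Simulate raw oligo-level tiling-array intensities
#'
#' Raw intensity = additive normal background + the transcript's linear
#' signal, the convolution model that the downstream background correction
#' assumes.  Replicate measurement noise is applied on the log2 scale per
#' transcript and sample (shared by the transcript's oligos); every oligo of
#' a transcript carries the same underlying signal.
#'
#' @param annotation,oligo_map,truth from [simulate_annotation()].
#' @param sheet sample sheet.
#' @param config a [sim_config()].
#' @return an oligos x samples matrix of positive raw intensities, rownames
#'   = oligo ids.
#' @export
simulate_oligo_intensities <- function(annotation, oligo_map, truth, sheet,
                                       config) {
  validate_config(config)
  set.seed(stage_seed(config, "intensities"))
  L <- planted_log2_matrix(truth, sheet)
  noise <- matrix(rnorm(length(L), 0, config$noise_sd), nrow(L), ncol(L))
  signal_linear <- 2^(L + noise)

  idx <- match(oligo_map$transcript_origin, truth$transcript_id)
  n_oligo <- nrow(oligo_map)
  n_sample <- ncol(L)
  bg <- matrix(rnorm(n_oligo * n_sample, config$bg_mean, config$bg_sd),
               n_oligo, n_sample)
  raw <- bg + signal_linear[idx, , drop = FALSE]
  raw[raw <= 0] <- .Machine$double.eps  # background is normal; clamp rare negatives
  dimnames(raw) <- list(oligo_map$oligo_id, colnames(L))
  raw
}

#' Redistribute ribosome-bound mass after EDTA treatment
#'
#' Chelating magnesium dissociates monosomes and polysomes, so a fraction
#' `runoff` of the mass in fractions 7-12 is released and redistributed over
#' fractions 1-6 (proportionally to their existing mass).  The transcript's
#' total across the 12 fractions is conserved exactly.
#'
#' @param q numeric vector of 12 fraction quantities.
#' @param runoff fraction of bound mass released, in (0, 1].
#' @return the transformed 12-fraction vector.
#' @export
edta_transform <- function(q, runoff = 0.9) {
  stopifnot(length(q) == 12, all(q >= 0), runoff >= 0, runoff <= 1)
  released <- runoff * q[7:12]
  out <- q
  out[7:12] <- q[7:12] - released
  light <- q[1:6]
  w <- if (sum(light) > 0) light / sum(light) else rep(1 / 6, 6)
  out[1:6] <- light + sum(released) * w
  out
}

#' Simulate 12-fraction sucrose-gradient profiles with spike-in
#'
#' Translated transcripts concentrate mass in the polysomal fractions
#' (8-12), repressed transcripts in the light fractions (1-6), with the
#' monosome peak at fraction 7 in between.  An EDTA-treated counterpart of
#' every profile is produced by [edta_transform()], so its polysomal mass is
#' strictly lower by construction.  Per-fraction recovery efficiency (one
#' draw per fraction and condition, shared by all transcripts and by the
#' spike-in) emulates RNA-isolation and RT variation; the spike-in vector is
#' the handle that removes it again.
#'
#' @param truth truth table.
#' @param config a [sim_config()].
#' @param transcripts optional character vector restricting the profiles.
#' @return long data.frame: transcript_id, condition ("untreated"/"EDTA"),
#'   fraction (1-12), quantity, spike.
#' @export
simulate_fraction_profiles <- function(truth, config, transcripts = NULL) {
  validate_config(config)
  set.seed(stage_seed(config, "fractions"))
  if (is.null(transcripts)) transcripts <- truth$transcript_id
  tr <- truth[match(transcripts, truth$transcript_id), ]
  stopifnot(!anyNA(tr$transcript_id))
  n <- nrow(tr)

  w_translated <- c(0.3, 0.3, 0.3, 0.4, 0.5, 0.6, 1.0, 1.5, 1.8, 1.8, 1.5, 1.2)
  w_repressed <- c(1.8, 1.8, 1.5, 1.2, 0.8, 0.6, 0.5, 0.3, 0.25, 0.2, 0.15, 0.1)

  eff <- matrix(exp(rnorm(24, 0, config$spike_efficiency_sd)), 12, 2,
                dimnames = list(NULL, c("untreated", "EDTA")))
  total_q <- rgamma(n, shape = 4, rate = 4 / 100)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    w <- if (tr$translation_state[i] == "repressed") w_repressed else w_translated
    w <- w * rgamma(12, shape = 25, rate = 25)  # transcript-specific wiggle
    q_unt <- total_q[i] * w / sum(w)
    q_edta <- edta_transform(q_unt, config$edta_runoff)
    qs <- cbind(untreated = q_unt, EDTA = q_edta)
    per_cond <- lapply(c("untreated", "EDTA"), function(cond) {
      meas <- qs[, cond] * eff[, cond] *
        exp(rnorm(12, 0, config$fraction_noise_sd))
      data.frame(transcript_id = tr$transcript_id[i], condition = cond,
                 fraction = 1:12, quantity = meas,
                 spike = config$spike_amount * eff[, cond],
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, per_cond)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate RT-qPCR relative quantities for abundance comparisons
#'
#' Emits efficiency-corrected relative quantities for the requested genes in
#' the requested genotypes, plus the unregulated reference gene `tbb-2`.
#' Each biological replicate sample carries a log-normal nuisance scale
#' factor (RNA amount, RT efficiency) that normalization to the reference
#' gene must cancel.
#'
#' @param truth truth table.
#' @param config a [sim_config()].
#' @param genes transcript ids to measure.
#' @param genotypes genotype labels (see [planted_log2_matrix()]).
#' @param sample_scale_sd log-scale sd of the per-sample nuisance factor.
#' @param qpcr_noise_sd log2 technical noise per well; defaults to the
#'   config replicate noise.
#' @return long data.frame: sample_id, assay, genotype, replicate, gene_id,
#'   quantity.
#' @export
simulate_qpcr_abundance <- function(truth, config, genes,
                                    genotypes = c("wt", "gld1", "cgh1ts",
                                                  "double"),
                                    sample_scale_sd = 0.2,
                                    qpcr_noise_sd = config$noise_sd) {
  validate_config(config)
  set.seed(stage_seed(config, "qpcr"))
  eff <- qpcr_gene_effects(truth, genes)
  grid <- expand.grid(genotype = genotypes,
                      replicate = seq_len(config$n_replicates),
                      stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("qpcr.%s.r%d", grid$genotype, grid$replicate)
  grid$scale <- exp(rnorm(nrow(grid), 0, sample_scale_sd))

  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(j) {
    g <- grid[j, ]
    l2 <- eff$base_log2 + eff[[paste0("delta_", g$genotype)]] +
      rnorm(nrow(eff), 0, qpcr_noise_sd)
    data.frame(sample_id = g$sample_id, assay = "total",
               genotype = g$genotype, replicate = g$replicate,
               gene_id = eff$gene_id, quantity = g$scale * 2^l2,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate RT-qPCR quantities for an IP experiment
#'
#' Produces matched IP, control-IP and input quantities per gene, genotype
#' and replicate.  IP capture scales the input abundance by the planted IP
#' enrichment (targets only); the control IP captures abundance
#' non-specifically.  Per-sample nuisance factors are planted so that only
#' the full normalization chain (control IP, input, reference gene) cancels
#' them.
#'
#' @inheritParams simulate_qpcr_abundance
#' @param capture_log2 nonspecific log2 capture of the control IP relative
#'   to input (negative: the control pulls down little).
#' @return long data.frame as in [simulate_qpcr_abundance()], with assay in
#'   ip/control_ip/input.
#' @export
simulate_qpcr_ip <- function(truth, config, genes, genotypes = "wt",
                             sample_scale_sd = 0.2, capture_log2 = -5,
                             qpcr_noise_sd = config$noise_sd) {
  validate_config(config)
  set.seed(stage_seed(config, "qpcr_ip"))
  eff <- qpcr_gene_effects(truth, genes)
  grid <- expand.grid(assay = c("ip", "control_ip", "input"),
                      genotype = genotypes,
                      replicate = seq_len(config$n_replicates),
                      stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("qpcrip.%s.%s.r%d", grid$assay, grid$genotype,
                            grid$replicate)
  grid$scale <- exp(rnorm(nrow(grid), 0, sample_scale_sd))

  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(j) {
    g <- grid[j, ]
    l2 <- eff$base_log2 + eff[[paste0("delta_", g$genotype)]]
    l2 <- l2 + switch(g$assay,
                      input = 0,
                      control_ip = capture_log2,
                      ip = capture_log2 + eff$ip_log2_enrichment)
    l2 <- l2 + rnorm(nrow(eff), 0, qpcr_noise_sd)
    data.frame(sample_id = g$sample_id, assay = g$assay,
               genotype = g$genotype, replicate = g$replicate,
               gene_id = eff$gene_id, quantity = g$scale * 2^l2,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Per-gene planted log2 effects, with the unregulated reference gene added.
qpcr_gene_effects <- function(truth, genes) {
  idx <- match(setdiff(genes, "tbb-2"), truth$transcript_id)
  if (anyNA(idx)) stop("unknown gene id(s) requested", call. = FALSE)
  tr <- truth[idx, ]
  eff <- data.frame(gene_id = tr$transcript_id,
                    base_log2 = tr$base_log2,
                    delta_wt = 0,
                    delta_gld1 = tr$delta_gld1,
                    delta_cgh1ts = tr$delta_cgh1,
                    delta_double = tr$delta_double,
                    delta_rnai_mock = 0,
                    delta_rnai_cgh1 = tr$delta_rnai,
                    ip_log2_enrichment = ifelse(tr$is_target,
                                                tr$ip_log2_enrichment, 0),
                    stringsAsFactors = FALSE)
  ref <- data.frame(gene_id = "tbb-2", base_log2 = 10, delta_wt = 0,
                    delta_gld1 = 0, delta_cgh1ts = 0, delta_double = 0,
                    delta_rnai_mock = 0, delta_rnai_cgh1 = 0,
                    ip_log2_enrichment = 0, stringsAsFactors = FALSE)
  rbind(eff, ref)
}
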