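#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator.  The defaults are
#' the study conditions the rest of the package is tested under: 3000
#' transcripts of which 12% are true IP targets, three biological replicates
#' per condition, IP enrichment drawn from N(2.5, 0.7) on the log2 scale
#' (truncated above the 3-fold target-defining cut), a gld-1 stability effect
#' of N(-1.5, 0.4) log2 on the stabilized target subset, and log-scale
#' replicate noise with sd 0.25.
#'
#' @param seed integer; mandatory RNG seed, recorded in every output header.
#' @param n_transcripts number of transcripts tiling the virtual genome.
#' @param n_replicates biological replicates per (assay, genotype) condition.
#' @param target_fraction fraction of transcripts that are true IP targets.
#' @param repressed_fraction_target,repressed_fraction_nontarget probability
#'   that a target / non-target transcript is translationally repressed.
#' @param stabilized_fraction fraction of targets whose abundance depends on
#'   the RBP (the planted stabilized subset).
#' @param cgh1_costab_prob probability that a stabilized target additionally
#'   depends on the helicase (drawn delta_cgh1 effect).
#' @param offtarget_destab_fraction fraction of non-targets destabilized in
#'   both mutants (one correlated flag, so the cross-mutant scatter
#'   correlates as in real data).
#' @param ip_log2_mean,ip_log2_sd planted IP log2 enrichment distribution for
#'   targets; truncated to be > `log2(3)` because target status is defined by
#'   the 3-fold IP cut.
#' @param ip_null_sd log2 sd of IP enrichment noise for non-targets.
#' @param depletion_log2_mean,depletion_log2_sd planted polysomal/total log2
#'   ratio distribution for repressed transcripts.
#' @param translated_ratio_sd log2 sd of the ratio for translated transcripts
#'   (centred at 0).
#' @param gld1_relief fraction of a target's polysome depletion that is
#'   relieved in the gld-1 mutant (the planted shift to polysomes).
#' @param delta_gld1_mean,delta_gld1_sd planted log2 abundance effect in the
#'   gld-1 mutant for stabilized targets.
#' @param delta_cgh1_mean,delta_cgh1_sd planted log2 abundance effect in the
#'   cgh-1(ts) mutant for co-stabilized targets.
#' @param offtarget_delta_mean,offtarget_delta_sd planted log2 effects for
#'   the destabilized non-target pool (applied to both mutants).
#' @param null_delta_sd biological scatter (log2 sd) of deltas for
#'   unaffected transcripts.
#' @param rnai_extra_sd extra log2 noise of the RNAi knockdown effect around
#'   the ts-mutant effect.
#' @param base_signal_mean mean of the exponential distribution of linear
#'   per-transcript signal (the supra-background component of the
#'   normal + exponential intensity model).
#' @param bg_mean,bg_sd additive normal background of raw oligo intensities.
#' @param noise_sd log2 replicate measurement noise per transcript x sample.
#' @param oligo_density_per_kb tiling density of the oligo map.
#' @param oligo_length oligo length in bp.
#' @param multi_fraction,unmapped_fraction fractions of oligos flagged
#'   multi-mapping / unmapped (they never enter transcript summaries).
#' @param transcript_length_range length range (bp) of simulated transcripts.
#' @param intergenic_gap gap (bp) between adjacent transcripts.
#' @param spike_amount nominal spike-in quantity per gradient fraction.
#' @param spike_efficiency_sd log-scale sd of fraction-to-fraction recovery
#'   efficiency (distorts mRNA and spike-in quantities identically).
#' @param fraction_noise_sd log-scale qPCR measurement noise on fraction
#'   quantities only (not cancelled by the spike-in).
#' @param edta_runoff fraction of monosomal + polysomal mass (fractions
#'   7-12) that the EDTA treatment releases into fractions 1-6.
#' @return an object of class `polystab_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_transcripts = 50)
#' cfg$target_fraction
#' @export
sim_config <- function(seed,
                       n_transcripts = 3000,
                       n_replicates = 3,
                       target_fraction = 0.12,
                       repressed_fraction_target = 0.8,
                       repressed_fraction_nontarget = 0.2,
                       stabilized_fraction = 0.14,
                       cgh1_costab_prob = 0.85,
                       offtarget_destab_fraction = 0.05,
                       ip_log2_mean = 2.5,
                       ip_log2_sd = 0.7,
                       ip_null_sd = 0.3,
                       depletion_log2_mean = -2,
                       depletion_log2_sd = 0.5,
                       translated_ratio_sd = 0.3,
                       gld1_relief = 0.6,
                       delta_gld1_mean = -1.5,
                       delta_gld1_sd = 0.4,
                       delta_cgh1_mean = -1.4,
                       delta_cgh1_sd = 0.3,
                       offtarget_delta_mean = -0.8,
                       offtarget_delta_sd = 0.5,
                       null_delta_sd = 0.1,
                       rnai_extra_sd = 0.4,
                       base_signal_mean = 2000,
                       bg_mean = 50,
                       bg_sd = 5,
                       noise_sd = 0.25,
                       oligo_density_per_kb = 4,
                       oligo_length = 25,
                       multi_fraction = 0.05,
                       unmapped_fraction = 0.02,
                       transcript_length_range = c(800L, 3000L),
                       intergenic_gap = 200L,
                       spike_amount = 100,
                       spike_efficiency_sd = 0.3,
                       fraction_noise_sd = 0.02,
                       edta_runoff = 0.9) {
  if (missing(seed)) {
    stop("`seed` is mandatory in a simulation config", call. = FALSE)
  }
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  cfg$n_transcripts <- as.integer(n_transcripts)
  cfg$n_replicates <- as.integer(n_replicates)
  class(cfg) <- "polystab_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "polystab_config"))
  if (is.na(cfg$seed)) stop("seed must be a finite integer", call. = FALSE)
  if (cfg$n_transcripts < 1L) {
    stop("configuration error: need at least one transcript", call. = FALSE)
  }
  if (cfg$oligo_density_per_kb <= 0) {
    stop("configuration error: oligo density must be positive", call. = FALSE)
  }
  fracs <- c(cfg$target_fraction, cfg$repressed_fraction_target,
             cfg$repressed_fraction_nontarget, cfg$stabilized_fraction,
             cfg$cgh1_costab_prob, cfg$offtarget_destab_fraction,
             cfg$multi_fraction, cfg$unmapped_fraction, cfg$gld1_relief,
             cfg$edta_runoff)
  if (any(fracs < 0 | fracs > 1)) {
    stop("configuration error: fractions must lie in [0, 1]", call. = FALSE)
  }
  sds <- c(cfg$ip_log2_sd, cfg$ip_null_sd, cfg$depletion_log2_sd,
           cfg$translated_ratio_sd, cfg$delta_gld1_sd, cfg$delta_cgh1_sd,
           cfg$offtarget_delta_sd, cfg$null_delta_sd, cfg$rnai_extra_sd,
           cfg$bg_sd, cfg$noise_sd, cfg$spike_efficiency_sd,
           cfg$fraction_noise_sd)
  if (any(sds < 0)) {
    stop("configuration error: standard deviations must be >= 0", call. = FALSE)
  }
  if (cfg$base_signal_mean <= 0 || cfg$spike_amount <= 0) {
    stop("configuration error: signal scales must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' Hash of a simulation or pipeline configuration
#'
#' MD5 of the canonical serialized config; written into every TSV artifact
#' header so that stale outputs are detectable.
#'
#' @param cfg a `polystab_config` (or any list of atomic fields).
#' @return a character MD5 digest.
#' @export
config_hash <- function(cfg) {
  txt <- paste(deparse(cfg[order(names(unclass(cfg)))]), collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

# Derived sub-seeds keep each generator deterministic on its own, regardless
# of call order.  Offsets are fixed; the base seed stays well below 2^31.
stage_seed <- function(cfg, stage) {
  offsets <- c(annotation = 11L, intensities = 23L, fractions = 37L,
               qpcr = 53L, qpcr_ip = 71L)
  (cfg$seed %% 2000000000L) + offsets[[stage]]
}

#' @export
print.polystab_config <- function(x, ...) {
  cat("polystab simulation config\n")
  cat(sprintf("  %d transcripts, %.0f%% targets, %d replicates, seed %d\n",
              x$n_transcripts, 100 * x$target_fraction, x$n_replicates,
              x$seed))
  cat(sprintf("  hash %s\n", config_hash(x)))
  invisible(x)
}
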