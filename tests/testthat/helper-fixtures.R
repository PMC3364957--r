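# Shared fixtures: tiny hand-built containers and a memoised default-config
# pipeline run (used by the recovery and determinism tests).

make_expr <- function(values, support = NULL) {
  if (is.null(support)) {
    support <- setNames(rep(1L, nrow(values)), rownames(values))
  }
  structure(list(values = values, support = support, provenance = "test"),
            class = "polystab_expr")
}

sheet_rows <- function(sample_id, dataset, assay, genotype,
                       replicate = 1L, normalization_group = dataset) {
  data.frame(sample_id = sample_id, dataset = dataset, assay = assay,
             genotype = genotype, replicate = replicate,
             normalization_group = normalization_group,
             stringsAsFactors = FALSE)
}

.run_cache <- new.env(parent = emptyenv())

# One pipeline run at the default study conditions (3000 transcripts, 12%
# targets, 3 replicates, seed 7), shared across test files.
default_run <- function() {
  if (is.null(.run_cache$run)) {
    cfg <- sim_config(seed = 7)
    wd <- file.path(tempdir(), "polystab-default-run")
    summary <- run_pipeline(cfg, wd)
    .run_cache$run <- list(config = cfg, workdir = wd, summary = summary)
  }
  .run_cache$run
}

# Small zero-measurement-noise simulation for exact-recovery tests.
zero_noise_sim <- function(n = 300, seed = 5) {
  cfg <- sim_config(seed = seed, n_transcripts = n, noise_sd = 0,
                    bg_sd = 0.5, fraction_noise_sd = 0)
  sim <- simulate_annotation(cfg)
  sheet <- simulate_sample_sheet(cfg)
  raw <- simulate_oligo_intensities(sim$annotation, sim$oligo_map, sim$truth,
                                    sheet, cfg)
  list(cfg = cfg, sim = sim, sheet = sheet, raw = raw,
       params = list(mean = cfg$bg_mean, sd = cfg$bg_sd,
                     alpha = cfg$base_signal_mean))
}
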