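test_that("annotation tiles the genome; every transcript has a contained oligo", {
  cfg <- sim_config(seed = 1, n_transcripts = 10, oligo_density_per_kb = 10)
  sim <- simulate_annotation(cfg)
  ann <- sim$annotation

  expect_equal(nrow(ann), 10)
  expect_false(anyDuplicated(ann$transcript_id) > 0)
  expect_true(all(ann$start < ann$end))
  expect_true(all(ann$gbm_count >= 0))
  # non-overlap on the single chromosome
  ord <- order(ann$start)
  expect_true(all(utils::head(ann$end[ord], -1) <= ann$start[ord][-1]))
  # each transcript covered by >= 1 fully contained oligo
  om <- sim$oligo_map
  idx <- match(om$transcript_origin, ann$transcript_id)
  expect_true(all(om$start >= ann$start[idx] & om$end <= ann$end[idx]))
  expect_setequal(unique(om$transcript_origin), ann$transcript_id)

  expect_error(sim_config(seed = 1, n_transcripts = 0), "transcript")
  expect_error(sim_config(seed = 1, oligo_density_per_kb = 0), "density")
  expect_error(sim_config(), "seed")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 33, n_transcripts = 40)
  a <- simulate_annotation(cfg)
  b <- simulate_annotation(cfg)
  expect_identical(a, b)
  sheet <- simulate_sample_sheet(cfg)
  ra <- simulate_oligo_intensities(a$annotation, a$oligo_map, a$truth, sheet, cfg)
  rb <- simulate_oligo_intensities(b$annotation, b$oligo_map, b$truth, sheet, cfg)
  expect_identical(ra, rb)
  expect_identical(simulate_fraction_profiles(a$truth, cfg),
                   simulate_fraction_profiles(b$truth, cfg))
})

test_that("planted truth realizes the configured target fraction and motif link", {
  cfg <- sim_config(seed = 7, n_transcripts = 3000)
  sim <- simulate_annotation(cfg)
  expect_lt(abs(mean(sim$truth$is_target) - 0.12), 0.02)
  # motif counts are positively associated with target status
  expect_gt(mean(sim$annotation$gbm_count[sim$truth$is_target]),
            mean(sim$annotation$gbm_count[!sim$truth$is_target]) + 1)
  # emitted labels are recomputable from the planted quantities
  tr <- sim$truth
  expect_identical(tr$stabilized, tr$is_target & tr$delta_gld1 < -1)
  expect_identical(tr$co_regulated,
                   tr$is_target & tr$delta_gld1 < -1 & tr$delta_cgh1 < -0.5)
  # targets are IP-enriched above the defining 3-fold cut
  expect_true(all(tr$ip_log2_enrichment[tr$is_target] > log2(3)))
})

test_that("intensity model plants IP enrichment, depletion and deltas exactly", {
  cfg <- sim_config(seed = 3, n_transcripts = 50, noise_sd = 0, bg_sd = 0,
                    bg_mean = 0, depletion_log2_sd = 0, ip_null_sd = 0)
  sim <- simulate_annotation(cfg)
  sheet <- simulate_sample_sheet(cfg)
  raw <- simulate_oligo_intensities(sim$annotation, sim$oligo_map, sim$truth,
                                    sheet, cfg)
  tr <- sim$truth
  first_oligo <- function(tx) which(sim$oligo_map$transcript_origin == tx)[1]
  col <- function(assay, geno, rep = 1) {
    sprintf("%s.%s.%s.r%d",
            c(polysomal = "polysome", total = "polysome", ip = "ip",
              control_ip = "ip")[[assay]], assay, geno, rep)
  }
  # non-target: ip and control_ip signal equal
  nt <- tr$transcript_id[!tr$is_target & tr$translation_state == "translated"][1]
  i <- first_oligo(nt)
  expect_equal(raw[i, col("ip", "wt")], raw[i, col("control_ip", "wt")])
  # repressed non-target with planted 4-fold depletion: polysomal/total = 0.25
  rp <- tr$transcript_id[!tr$is_target & tr$translation_state == "repressed"][1]
  i <- first_oligo(rp)
  expect_equal(raw[i, col("polysomal", "wt")] / raw[i, col("total", "wt")],
               0.25, tolerance = 1e-12)
  expect_error(
    planted_log2_matrix(tr, data.frame(sample_id = "x", dataset = "z",
                                       assay = "total", genotype = "alien",
                                       replicate = 1)),
    "genotype")
})

test_that("replicate noise averages back to the planted mean", {
  cfg <- sim_config(seed = 7, n_transcripts = 1000, bg_sd = 0, bg_mean = 0)
  sim <- simulate_annotation(cfg)
  sheet <- simulate_sample_sheet(cfg)
  raw <- simulate_oligo_intensities(sim$annotation, sim$oligo_map, sim$truth,
                                    sheet, cfg)
  tot <- sprintf("gonad.total.wt.r%d", 1:3)
  one_oligo <- sim$oligo_map$oligo_id[
    match(sim$truth$transcript_id, sim$oligo_map$transcript_origin)]
  obs <- rowMeans(log2(raw[one_oligo, tot]))
  se <- cfg$noise_sd / sqrt(cfg$n_replicates)
  cover <- mean(abs(obs - sim$truth$base_log2) <= 3 * se)
  expect_gte(cover, 0.99)
})

test_that("fraction profiles encode translation state, EDTA runoff and spike-in", {
  cfg <- sim_config(seed = 2, n_transcripts = 80)
  sim <- simulate_annotation(cfg)
  prof <- simulate_fraction_profiles(sim$truth, cfg)

  mass <- function(cond, fr) {
    sub <- prof[prof$condition == cond & prof$fraction %in% fr, ]
    tapply(sub$quantity, sub$transcript_id, sum)
  }
  heavy_unt <- mass("untreated", 8:12)
  heavy_edta <- mass("EDTA", 8:12)
  expect_true(all(heavy_edta[names(heavy_unt)] < heavy_unt))

  # spike-corrected association separates the planted translation classes
  assoc <- polysomal_association(spike_normalize_fractions(prof))
  assoc <- assoc[assoc$condition == "untreated", ]
  st <- sim$truth$translation_state[match(assoc$transcript_id,
                                          sim$truth$transcript_id)]
  expect_gt(median(assoc$association[st == "translated"]),
            median(assoc$association[st == "repressed"]))

  # zero efficiency variation -> constant spike vector
  cfg0 <- sim_config(seed = 2, n_transcripts = 5, spike_efficiency_sd = 0)
  prof0 <- simulate_fraction_profiles(simulate_annotation(cfg0)$truth, cfg0)
  expect_equal(unique(prof0$spike), cfg0$spike_amount)
})

test_that("the EDTA transform conserves totals and strictly moves mass down", {
  set.seed(1)
  for (i in 1:25) {
    q <- rgamma(12, shape = 2, rate = 1 / 50)
    out <- edta_transform(q, runoff = runif(1, 0.1, 1))
    expect_equal(sum(out), sum(q), tolerance = 1e-9)
    expect_true(sum(out[8:12]) < sum(q[8:12]))
    expect_true(all(out >= 0))
  }
  expect_error(edta_transform(rep(1, 11)), "12")
})
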