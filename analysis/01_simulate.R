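#!/usr/bin/env Rscript
# Generate the synthetic study: transcript annotation with UTR motif counts,
# a tiling oligo map, planted regulatory truth, the four array datasets
# (polysome profiling, dissected gonads, RNAi, IP), and 12-fraction sucrose
# gradient profiles with spike-in.  Everything downstream reads these files.

library(polystab)

cfg <- sim_config(seed = 7)
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
hdr <- list(config_hash = config_hash(cfg), seed = cfg$seed)

sim <- simulate_annotation(cfg)
sheet <- simulate_sample_sheet(cfg)
raw <- simulate_oligo_intensities(sim$annotation, sim$oligo_map, sim$truth,
                                  sheet, cfg)
profiles <- simulate_fraction_profiles(sim$truth, cfg)

write_bed6(sim$annotation, file.path(out, "annotation.bed"))
write_tsv(sim$annotation[, c("transcript_id", "gbm_count")],
          file.path(out, "annotation_gbm.tsv"), hdr)
write_bed6(sim$oligo_map, file.path(out, "oligo_map.bed"),
           name_col = "oligo_id", status_col = "mapping_status")
write_tsv(sheet, file.path(out, "sample_sheet.tsv"), hdr)
write_tsv(sim$truth, file.path(out, "truth.tsv"), hdr)
write_tsv(raw, file.path(out, "intensities.tsv"), hdr)
write_tsv(profiles, file.path(out, "fraction_profiles.tsv"), hdr)

tr <- sim$truth
message(sprintf("simulated %d transcripts on a virtual chromosome (seed %d)",
                nrow(tr), cfg$seed))
message(sprintf("  %d (%.1f%%) planted IP targets (configured 12%%)",
                sum(tr$is_target), 100 * mean(tr$is_target)))
message(sprintf("  %d repressed / %d translated; %d stabilized, %d co-regulated",
                sum(tr$translation_state == "repressed"),
                sum(tr$translation_state == "translated"),
                sum(tr$stabilized), sum(tr$co_regulated)))
message(sprintf("  %d oligos (%.1f%% multi-mapping, %.1f%% unmapped), %d samples",
                nrow(sim$oligo_map),
                100 * mean(sim$oligo_map$mapping_status == "multi"),
                100 * mean(sim$oligo_map$mapping_status == "unmapped"),
                nrow(sheet)))
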