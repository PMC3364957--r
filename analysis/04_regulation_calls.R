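#!/usr/bin/env Rscript
# Regulation calls: strict 3-fold IP target calling, mutant abundance
# changes, the stabilized / co-regulated classification (log2 cuts -1 and
# -0.5), hypergeometric target-set enrichment of the co-reduced set,
# cross-mutant concordance, and double-mutant additivity -- each scored
# against the planted truth.

library(polystab)

sheet <- read_tsv("results/data/sample_sheet.tsv")
truth <- read_tsv("results/data/truth.tsv")
em <- read_tsv("results/expression_matrix.tsv")
expr <- structure(list(values = polystab:::tsv_to_matrix(em[, -2]),
                       support = setNames(em$support, em$transcript_id),
                       provenance = "from results/expression_matrix.tsv"),
                  class = "polystab_expr")

calls <- build_regulation_calls(expr, sheet)
write_tsv(calls, "results/regulation_calls.tsv", attr(em, "meta"))
stopifnot(all(calls$transcript_id == truth$transcript_id))

t_rec <- recovery_metrics(calls$is_target, truth$is_target)
c_rec <- recovery_metrics(calls$co_regulated, truth$co_regulated)
message(sprintf("%d transcripts >3-fold IP-enriched (sensitivity %.3f, FDR %.3f vs planted targets)",
                sum(calls$is_target), t_rec$sensitivity, t_rec$fdr))
message(sprintf("%d stabilized (target & gld-1 change < -1); %.0f%% of targets are less abundant in gld-1",
                sum(calls$stabilized),
                100 * mean(calls$delta_gld1[calls$is_target] < -1)))
message(sprintf("%d co-regulated (also cgh-1ts change < -0.5); sensitivity %.3f, FDR %.3f vs planted",
                sum(calls$co_regulated), c_rec$sensitivity, c_rec$fdr))

universe <- define_universe(expr, sheet)
co_reduced <- intersect(
  calls$transcript_id[calls$delta_gld1 < -1 & calls$delta_cgh1 < -0.5],
  universe)
enr <- enrichment(co_reduced, setNames(calls$is_target, calls$transcript_id),
                  universe)
write_tsv(data.frame(k = enr$k, n = enr$n, K = enr$K, N = enr$N,
                     set_fraction = enr$set_fraction,
                     background_fraction = enr$background_fraction,
                     fold = enr$fold, p_hypergeometric = enr$p_hypergeometric,
                     p_two_proportion = enr$p_two_proportion),
          "results/enrichment.tsv", attr(em, "meta"))
message(sprintf("co-reduced transcripts: %.0f%% are targets vs %.0f%% of the expressed universe -- %.1f-fold enrichment (hypergeometric p = %.3g)",
                100 * enr$set_fraction, 100 * enr$background_fraction,
                enr$fold, enr$p_hypergeometric))

r_gc <- cross_mutant_concordance(
  setNames(calls$delta_gld1, calls$transcript_id),
  setNames(calls$delta_cgh1, calls$transcript_id))
r_rt <- cross_mutant_concordance(
  setNames(calls$delta_rnai, calls$transcript_id),
  setNames(calls$delta_cgh1, calls$transcript_id))
message(sprintf("cross-mutant concordance: r = %.3f (gld-1 vs cgh-1ts), r = %.3f (cgh-1 RNAi vs cgh-1ts)",
                r_gc, r_rt))

add <- additivity_score(calls$delta_gld1, calls$delta_cgh1,
                        calls$delta_double)
co <- calls$co_regulated
message(sprintf("double mutant: mean additivity score %+.3f; %.0f%% of co-regulated mRNAs further reduced below both single mutants",
                add$mean_score, 100 * mean(
                  (calls$delta_double < pmin(calls$delta_gld1,
                                             calls$delta_cgh1))[co])))

write_tsv(calls[, c("transcript_id", "ip_log2_enrichment", "delta_gld1",
                    "is_target")],
          "results/scatter_gld1_vs_ip.tsv", attr(em, "meta"))
write_tsv(calls[, c("transcript_id", "delta_gld1", "delta_cgh1", "is_target",
                    "co_regulated")],
          "results/scatter_cgh1_vs_gld1.tsv", attr(em, "meta"))
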