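polysome_sheet <- function() {
  rbind(
    sheet_rows("pol.wt", "polysome", "polysomal", "wt", 1, "pp"),
    sheet_rows("tot.wt", "polysome", "total", "wt", 1, "pt"),
    sheet_rows("pol.gld1", "polysome", "polysomal", "gld1", 1, "pp"),
    sheet_rows("tot.gld1", "polysome", "total", "gld1", 1, "pt")
  )
}

test_that("polysomal/total ratios and depletion boundaries behave strictly", {
  v <- rbind(t1 = c(5, 5, 5, 5),      # ratio 0 in both genotypes
             t2 = c(4, 5, 5, 5),      # ratio exactly -1 in wt
             t3 = c(2.8, 4, 4.5, 4))  # ratio -1.2 wt, +0.5 gld1
  colnames(v) <- c("pol.wt", "tot.wt", "pol.gld1", "tot.gld1")
  tab <- polysome_total_ratio(make_expr(v), polysome_sheet())
  expect_equal(tab$ratio_wt, c(0, -1, -1.2))
  expect_equal(tab$shift, c(0, 1, 1.7))
  # "more than two-fold depleted" is strict: -1.0 is NOT depleted
  expect_identical(tab$depleted, c(FALSE, FALSE, TRUE))
  expect_identical(call_depleted(c(-1.2, -1, 0.3)), c(TRUE, FALSE, FALSE))
})

test_that("zero-noise ratios equal the planted depletions", {
  zs <- zero_noise_sim(n = 200, seed = 8)
  expr <- process_arrays(zs$raw, zs$sim$oligo_map, zs$sim$annotation,
                         zs$sheet, params = zs$params, normalize = FALSE)
  tab <- polysome_total_ratio(expr, zs$sheet)
  truth <- zs$sim$truth
  well <- truth$base_log2 > 3
  err <- abs(tab$ratio_wt - truth$ratio_log2_wt)[well]
  expect_lt(max(err, na.rm = TRUE), 0.05)
  err_g <- abs(tab$ratio_gld1 - truth$ratio_log2_gld1)[well]
  expect_lt(max(err_g, na.rm = TRUE), 0.05)
})

test_that("the genotype shift test matches the Welch formula and is symmetric", {
  x <- c(-2.1, -1.7, -2.5, -1.9, -2.2)
  y <- c(-0.9, -1.4, -0.6, -1.1, -1.3)
  tab <- data.frame(transcript_id = sprintf("t%d", 1:5),
                    ratio_wt = x, ratio_gld1 = y)
  res <- shift_test(tab, tab$transcript_id)

  # textbook Welch computation as the independent oracle
  se2 <- var(x) / 5 + var(y) / 5
  t_oracle <- (mean(y) - mean(x)) / sqrt(se2)
  df_oracle <- se2^2 / ((var(x) / 5)^2 / 4 + (var(y) / 5)^2 / 4)
  p_oracle <- 2 * stats::pt(-abs(t_oracle), df_oracle)
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  expect_equal(res$median_shift, median(y - x))
  expect_equal(unname(res$n), c(5L, 5L))

  # identical distributions: t = 0, p = 1
  tab2 <- data.frame(transcript_id = sprintf("t%d", 1:4),
                     ratio_wt = c(1, 2, 3, 4), ratio_gld1 = c(1, 2, 3, 4))
  same <- shift_test(tab2, tab2$transcript_id)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # label swap negates t, preserves p
  tab_sw <- tab
  names(tab_sw)[2:3] <- c("ratio_gld1", "ratio_wt")
  res_sw <- shift_test(tab_sw, tab_sw$transcript_id)
  expect_equal(res_sw$t, -res$t)
  expect_equal(res_sw$p, res$p)

  expect_error(shift_test(tab[1, ], tab$transcript_id[1]), "at least 2")
})

test_that("spike-in correction removes per-fraction efficiency factors", {
  prof <- data.frame(transcript_id = "t1", condition = "untreated",
                     fraction = 1:2, quantity = c(2, 4), spike = c(1, 2))
  out <- spike_normalize_fractions(prof)
  expect_equal(out$corrected, c(3, 3))   # q/s * mean(s) with mean(s) = 1.5

  # constant spike: output equals input
  prof2 <- data.frame(transcript_id = "t1", condition = "untreated",
                      fraction = 1:12, quantity = rgamma(12, 2), spike = 5)
  expect_equal(spike_normalize_fractions(prof2)$corrected, prof2$quantity)

  # scaling one fraction's quantity and spike together leaves the corrected
  # profile unchanged up to a common factor, and the association exactly
  prof3 <- prof2
  prof3$spike <- runif(12, 0.5, 2)
  base <- spike_normalize_fractions(prof3)$corrected
  a_base <- polysomal_association(spike_normalize_fractions(prof3))$association
  prof3$quantity[3] <- prof3$quantity[3] * 7
  prof3$spike[3] <- prof3$spike[3] * 7
  scaled <- spike_normalize_fractions(prof3)$corrected
  expect_equal(scaled / sum(scaled), base / sum(base), tolerance = 1e-12)
  expect_equal(polysomal_association(spike_normalize_fractions(prof3))$association,
               a_base, tolerance = 1e-12)

  prof_bad <- prof
  prof_bad$spike[1] <- 0
  expect_error(spike_normalize_fractions(prof_bad), "positive")
})

test_that("polysomal association is a scale-invariant fraction in [0, 1]", {
  uniform <- data.frame(transcript_id = "t1", condition = "c",
                        fraction = 1:12, quantity = 1, spike = 1)
  uniform <- spike_normalize_fractions(uniform)
  expect_equal(polysomal_association(uniform)$association, 5 / 12)

  mono <- uniform
  mono$corrected <- ifelse(mono$fraction == 7, 10, 0)
  expect_equal(polysomal_association(mono)$association, 0)

  zero <- uniform
  zero$corrected <- 0
  expect_true(is.na(polysomal_association(zero)$association))

  set.seed(6)
  r <- uniform
  r$corrected <- rgamma(12, 1)
  a1 <- polysomal_association(r)$association
  expect_true(a1 >= 0 && a1 <= 1)
  r$corrected <- r$corrected * 1e4
  expect_equal(polysomal_association(r)$association, a1, tolerance = 1e-12)
})
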