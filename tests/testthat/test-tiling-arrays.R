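test_that("background correction is monotone, positive, and matches quadrature", {
  set.seed(10)
  x <- sort(c(runif(200, 40, 400), rexp(300, 1 / 500) + 50))
  raw <- matrix(x, ncol = 1, dimnames = list(NULL, "s1"))
  corr <- background_correct(raw)
  expect_true(all(is.finite(corr)))
  expect_true(all(diff(corr[, 1]) >= 0))         # order-preserving
  expect_true(all(2^corr > 0))

  # pure background: corrected values small and positive
  bg_only <- matrix(abs(rnorm(500, 100, 10)), ncol = 1,
                    dimnames = list(NULL, "s1"))
  cb <- background_correct(bg_only)
  expect_true(all(2^cb > 0))
  expect_lt(median(2^cb), 25)

  # fixed parameters (mean 100, sd 10, exponential mean 200) vs brute-force
  # quadrature of the truncated-normal posterior, 4 significant digits
  pars <- list(mean = 100, sd = 10, alpha = 200)
  xs <- c(90, 120, 250, 500, 1500)
  got <- 2^background_correct(matrix(xs, ncol = 1,
                                     dimnames = list(NULL, "s1")),
                              params = pars)[, 1]
  oracle <- vapply(xs, function(xx) {
    lo <- max(0, xx - pars$mean - 8 * pars$sd)
    hi <- xx - pars$mean + 8 * pars$sd
    dens <- function(s) dnorm(xx - s, pars$mean, pars$sd) *
      stats::dexp(s, 1 / pars$alpha)
    stats::integrate(function(s) s * dens(s), lo, hi, rel.tol = 1e-10)$value /
      stats::integrate(dens, lo, hi, rel.tol = 1e-10)$value
  }, 0)
  expect_equal(got, oracle, tolerance = 5e-4)

  expect_error(background_correct(matrix(1:5, ncol = 1)), "10")
  expect_error(background_correct(matrix(c(-1, 2:20), ncol = 1)), "positive")
})

test_that("oligo assignment requires unique mapping, strand and containment", {
  ann <- data.frame(transcript_id = c("tA", "tB", "tC"),
                    chrom = "chr1",
                    start = c(50L, 480L, 1000L),
                    end = c(500L, 600L, 1200L),
                    strand = c("+", "+", "-"))
  om <- data.frame(
    oligo_id = c("in", "multi", "straddle", "wrong_strand", "ambiguous", "rev"),
    chrom = "chr1",
    start = c(100L, 150L, 990L, 200L, 485L, 1100L),
    end = c(125L, 175L, 1015L, 225L, 498L, 1125L),
    strand = c("+", "+", "-", "-", "+", "-"),
    mapping_status = c("unique", "multi", "unique", "unique", "unique",
                       "unique"))
  asg <- map_oligos(om, ann)
  expect_equal(asg$transcript_id[asg$oligo_id == "in"], "tA")
  expect_false("multi" %in% asg$oligo_id)         # never assigned
  expect_false("straddle" %in% asg$oligo_id)      # crosses the 3' boundary
  expect_false("wrong_strand" %in% asg$oligo_id)
  expect_false("ambiguous" %in% asg$oligo_id)     # contained in tA and tB
  expect_equal(asg$transcript_id[asg$oligo_id == "rev"], "tC")

  bad <- om
  bad$end[1] <- bad$start[1]
  expect_error(map_oligos(bad, ann), "half-open")
})

test_that("transcript summaries are oligo means with missing flagged NA", {
  corrected <- matrix(c(7.3, 4, 6, 9), ncol = 1,
                      dimnames = list(c("o1", "o2", "o3", "o4"), "s1"))
  ann <- data.frame(transcript_id = c("t1", "t2", "t3"), chrom = "c",
                    start = c(0L, 100L, 200L), end = c(50L, 150L, 250L),
                    strand = "+")
  asg <- data.frame(oligo_id = c("o1", "o2", "o3"),
                    transcript_id = c("t1", "t2", "t2"))
  expr <- summarize_transcripts(corrected, asg, ann)
  expect_equal(expr$values["t1", "s1"], 7.3)
  expect_equal(expr$values["t2", "s1"], 5)        # mean of 4 and 6
  expect_true(is.na(expr$values["t3", "s1"]))     # no support, not 0
  expect_equal(unname(expr$support), c(1L, 2L, 0L))

  # the mean stays within the member range
  set.seed(4)
  big <- matrix(rnorm(300), 100, 3,
                dimnames = list(sprintf("o%03d", 1:100), c("a", "b", "c")))
  asg2 <- data.frame(oligo_id = rownames(big),
                     transcript_id = rep(sprintf("t%02d", 1:20), each = 5))
  ann2 <- data.frame(transcript_id = sprintf("t%02d", 1:20), chrom = "c",
                     start = 0L, end = 10L, strand = "+")
  e2 <- summarize_transcripts(big, asg2, ann2)
  for (t in ann2$transcript_id) {
    member <- big[asg2$oligo_id[asg2$transcript_id == t], , drop = FALSE]
    expect_true(all(e2$values[t, ] >= apply(member, 2, min) - 1e-12))
    expect_true(all(e2$values[t, ] <= apply(member, 2, max) + 1e-12))
  }
})

test_that("quantile normalization equalizes groups and spares exempt IP columns", {
  v <- cbind(a = c(1, 2, 3), b = c(2, 4, 6), ip1 = c(9, 1, 5),
             ip2 = c(0.3, 8, 2))
  rownames(v) <- c("t1", "t2", "t3")
  sheet <- sheet_rows(colnames(v), dataset = c("d", "d", "ip", "ip"),
                      assay = c("total", "total", "ip", "control_ip"),
                      genotype = "wt", replicate = c(1, 2, 1, 1),
                      normalization_group = c("g", "g", "ip", "ip"))
  out <- quantile_normalize(make_expr(v), sheet)
  expect_equal(unname(out$values[, "a"]), c(1.5, 3, 4.5))
  expect_equal(unname(out$values[, "b"]), c(1.5, 3, 4.5))
  expect_identical(out$values[, c("ip1", "ip2")], v[, c("ip1", "ip2")])

  # identical columns are unchanged
  v2 <- cbind(a = c(5, 1, 3), b = c(5, 1, 3))
  rownames(v2) <- rownames(v)
  s2 <- sheet_rows(c("a", "b"), "d", "total", "wt", c(1, 2), "g")
  expect_equal(quantile_normalize(make_expr(v2), s2)$values, v2)

  # a singleton group warns and passes through
  s3 <- sheet_rows("a", "d", "total", "wt", 1, "solo")
  v3 <- v2[, "a", drop = FALSE]
  expect_warning(out3 <- quantile_normalize(make_expr(v3), s3), "single")
  expect_identical(out3$values, v3)

  # sorted value vectors agree within a group after normalization
  set.seed(20)
  v4 <- matrix(rnorm(40), 10, 4,
               dimnames = list(sprintf("t%02d", 1:10), c("w", "x", "y", "z")))
  s4 <- sheet_rows(colnames(v4), "d", "total", "wt", 1:4, "g")
  n4 <- quantile_normalize(make_expr(v4), s4)$values
  sorted <- apply(n4, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-9)
})

test_that("the pipeline is equivariant under row and column permutations", {
  zs <- zero_noise_sim(n = 40, seed = 9)
  expr <- process_arrays(zs$raw, zs$sim$oligo_map, zs$sim$annotation,
                         zs$sheet, params = zs$params)
  set.seed(31)
  rperm <- sample(nrow(zs$raw))
  cperm <- sample(ncol(zs$raw))
  expr_p <- process_arrays(zs$raw[rperm, cperm],
                           zs$sim$oligo_map[rperm, ],
                           zs$sim$annotation, zs$sheet[cperm, ],
                           params = zs$params)
  expect_equal(expr_p$values[, colnames(expr$values)], expr$values)
  expect_equal(expr_p$support, expr$support)
})

test_that("zero-noise processing recovers the planted deltas", {
  zs <- zero_noise_sim(n = 300, seed = 5)
  truth <- zs$sim$truth
  well <- truth$base_log2 > 3   # linear signal clearly above background
  expect_gt(mean(well), 0.95)

  expr0 <- process_arrays(zs$raw, zs$sim$oligo_map, zs$sim$annotation,
                          zs$sheet, params = zs$params, normalize = FALSE)
  d0 <- abundance_change(expr0, zs$sheet, "gld1")
  err0 <- abs(d0 - truth$delta_gld1)[well]
  expect_lt(max(err0, na.rm = TRUE), 0.05)

  # joint quantile normalization across genotypes with genuinely different
  # distributions compensates: values are distorted by up to a few tenths of
  # a log2 unit at this small problem size, but the classification-relevant
  # structure survives (near-perfect correlation; null transcripts stay near
  # zero; strongly reduced transcripts stay clearly reduced)
  exprq <- process_arrays(zs$raw, zs$sim$oligo_map, zs$sim$annotation,
                          zs$sheet, params = zs$params)
  dq <- abundance_change(exprq, zs$sheet, "gld1")
  expect_gt(cor(dq[well], truth$delta_gld1[well]), 0.97)
  null_t <- well & abs(truth$delta_gld1) < 0.3
  expect_true(all(abs(dq[null_t]) < 0.5))
  stab <- well & truth$delta_gld1 < -1.2
  expect_true(all(dq[stab] < -0.5))
})
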