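# Distance distributions, resampling null, co-direction, binning, nested
# correlations and the delta screen.

test_that("neighbor distances are per-chromosome successive differences", {
  d <- neighbor_distances(data.frame(chrom = "chr1", pos = c(100, 250, 1000)))
  expect_equal(d$distance, c(150, 750))
  d2 <- neighbor_distances(data.frame(chrom = c("chr1", "chr2"), pos = c(5, 5)))
  expect_equal(nrow(d2), 0)
  expect_error(neighbor_distances(data.frame(chrom = "chr1", pos = c(7, 7))),
               "duplicated")
})

test_that("the resampling null is deterministic and degenerates correctly", {
  bg <- data.frame(chrom = rep(c("chr1", "chr2"), each = 50),
                   pos = c(sort(sample.int(1e6, 50)), sort(sample.int(1e6, 50))))
  n1 <- resample_null(30, bg, n_resamples = 20, seed = 9)
  n2 <- resample_null(30, bg, n_resamples = 20, seed = 9)
  expect_identical(n1, n2)
  # sampling the whole background: every draw is the background itself
  full <- resample_null(nrow(bg), bg, n_resamples = 5, seed = 9)
  obs <- neighbor_distances(bg)
  expect_equal(full$mean,
               as.numeric(table(cut(obs$distance, c(full$breaks, Inf),
                                    include.lowest = TRUE))))
  expect_true(all(full$sd == 0))
  expect_error(resample_null(nrow(bg) + 1, bg, seed = 1), "exceeds")
})

test_that("clustered DMS exceed the null in the short-distance bins", {
  set.seed(11)
  bg <- data.frame(chrom = "chr1", pos = sort(sample.int(1e7, 10000)))
  anchors <- sort(sample(bg$pos, 50))
  dms <- data.frame(chrom = "chr1", pos = sort(unique(c(anchors, anchors + 60))))
  dd <- distance_distribution(dms, bg, n_resamples = 50, seed = 21)
  short <- which(dd$breaks <= 100)
  expect_gt(sum(dd$observed[short]), sum(dd$null_mean[short]))
})

test_that("same-direction fractions enumerate close pairs correctly", {
  r <- data.frame(chrom = "chr1", pos = c(100, 150, 500), meth_diff = c(10, 12, -30))
  s <- same_direction_fraction(r, radius = 100)
  expect_equal(s$n_pairs, 1L)
  expect_equal(s$fraction, 1)
  expect_equal(s$median_amplitude_diff, 2)
  s2 <- same_direction_fraction(data.frame(chrom = "chr1", pos = c(100, 150),
                                           meth_diff = c(10, -10)))
  expect_equal(s2$fraction, 0)
  expect_message(
    s3 <- same_direction_fraction(data.frame(chrom = "chr1", pos = c(100, 5000),
                                             meth_diff = c(1, 2))),
    "undefined")
  expect_true(is.na(s3$fraction))
})

test_that("1-Mb bins are half-open, conserve totals, and difference correctly", {
  d1 <- data.frame(chrom = "chr1", pos = c(999999, 1000000, 1500000))
  same <- bin_difference(d1, d1)
  expect_true(all(same$difference == 0))
  expect_equal(sum(same$count_1), nrow(d1))
  # 999,999 and 1,000,000 land in different bins
  expect_equal(sort(same$bin_start[same$count_1 > 0]), c(0L, 1000000L))
  d2 <- rbind(d1, data.frame(chrom = "chr2", pos = 3e6 + seq_len(9) * 100))
  diff2 <- bin_difference(d1, d2)
  expect_equal(diff2$difference[1], 9) # ranked by |difference|
  expect_equal(diff2$chrom[1], "chr2")
  expect_equal(sum(diff2$count_2) - sum(diff2$count_1), 9)
  expect_equal(sum(diff2$difference), nrow(d2) - nrow(d1))
})

test_that("nested correlations behave on exact and degenerate inputs", {
  x <- c(1, 2, 3, 4, 5)
  flags <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  r <- nested_correlations(x, x, flags, flags)
  expect_equal(r$r_all, 1)
  expect_equal(r$r_dms_any, 1)
  expect_equal(r$r_dms_both, 1)
  r2 <- nested_correlations(x, -x, flags, flags)
  expect_equal(r2$r_all, -1)
  r3 <- nested_correlations(x, x, c(TRUE, TRUE, FALSE, FALSE, FALSE), rep(FALSE, 5))
  expect_true(is.na(r3$r_dms_any)) # 2 points only
  expect_equal(r3$n_both, 0)
})

test_that("the delta screen applies the inclusive 20-point rule", {
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L))
  diff_1 <- c(25, 25, 30, 5)
  diff_2 <- c(2, 10, 10, 6)
  dms_1 <- c(TRUE, TRUE, TRUE, FALSE)
  dms_2 <- c(FALSE, FALSE, FALSE, FALSE)
  out <- delta_screen(sites, diff_1, diff_2, dms_1, dms_2, threshold = 20)
  expect_setequal(out$pos, c(10L, 30L)) # abs 23 in, abs 15 out, non-DMS out
  expect_equal(out$abs_delta[out$pos == 10L], 23)
  at20 <- delta_screen(sites[1, ], 25, 5, TRUE, FALSE, threshold = 20)
  expect_equal(nrow(at20), 1) # exactly 20: included
  # order of comparisons only permutes bookkeeping
  swapped <- delta_screen(sites, diff_2, diff_1, dms_2, dms_1, threshold = 20)
  expect_setequal(swapped$abs_delta, out$abs_delta)
})
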