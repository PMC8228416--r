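# Coverage filtering, pooled differences, the overdispersion-corrected test,
# and BH calling.

test_that("the coverage filter keeps >=10 reads and applies the per-group rule", {
  # site 1: one group-a cell at coverage 9 (dropped) -> only 5 of 6 usable
  # site 2: coverages 10 everywhere
  # site 3: only 3 usable cells in group a
  cov <- rbind(c(9, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10),
               c(10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10),
               c(9, 9, 9, 10, 10, 10, 10, 10, 10, 10, 10, 10))
  meth <- matrix(5, nrow = 3, ncol = 12)
  x <- mk_matrix(c(100L, 200L, 300L), meth, cov, groups = rep(c("A", "B"), each = 6))
  spec_all <- comparison_spec("t", sprintf("s%02d", 1:6), sprintf("s%02d", 7:12),
                              min_coverage = 10)
  xf <- filter_by_coverage(x, spec_all, quiet = TRUE)
  expect_equal(xf$sites$pos, 200L) # full-presence rule keeps only site 2
  spec4 <- comparison_spec("t", sprintf("s%02d", 1:6), sprintf("s%02d", 7:12),
                           min_coverage = 10, min_samples_per_group = 4)
  xf4 <- filter_by_coverage(x, spec4, quiet = TRUE)
  expect_setequal(xf4$sites$pos, c(100L, 200L)) # 5-of-6 kept, 3-of-6 dropped
  # the coverage-9 cell itself was masked, not counted
  expect_true(is.na(xf4$cov[xf4$sites$pos == 100L, "s01"]))
})

test_that("pooled differences follow coverage-weighted arithmetic", {
  expect_equal(pooled_difference(c(5, 5), c(10, 10), c(5, 5), c(10, 10)), 0)
  expect_equal(pooled_difference(c(0, 0), c(10, 10), c(10, 10), c(10, 10)), 100)
  expect_equal(pooled_difference(c(3, 7), c(10, 10), c(2, 2), c(10, 10)), -30)
  expect_true(is.na(pooled_difference(c(0, 0), c(0, 0), c(5, 5), c(10, 10))))
})

test_that("identical groups give a zero statistic and p = 1", {
  r <- test_site(c(5, 6, 4), c(10, 12, 10), c(5, 6, 4), c(10, 12, 10))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_equal(r$meth_diff, 0)
})

test_that("a saturated boundary contrast is finite and extreme", {
  r <- test_site(c(0, 0, 0), c(20, 20, 20), c(20, 20, 20), c(20, 20, 20))
  expect_equal(r$meth_diff, 100)
  expect_lt(r$p, 1e-6)
  expect_true(is.finite(r$statistic))
})

test_that("the statistic matches the independent GLM oracle", {
  set.seed(101)
  for (i in 1:25) {
    inst <- random_instance()
    r <- test_site(inst$ma, inst$ca, inst$mb, inst$cb)
    o <- oracle_test(inst$ma, inst$ca, inst$mb, inst$cb)
    expect_equal(r$statistic, o$statistic, tolerance = 1e-6)
    expect_equal(r$p, o$p, tolerance = 1e-6)
  }
})

test_that("swapping the groups negates the difference and keeps p", {
  set.seed(202)
  for (i in 1:20) {
    inst <- random_instance()
    r1 <- test_site(inst$ma, inst$ca, inst$mb, inst$cb)
    r2 <- test_site(inst$mb, inst$cb, inst$ma, inst$ca)
    expect_equal(r1$meth_diff, -r2$meth_diff, tolerance = 1e-9)
    expect_equal(r1$p, r2$p, tolerance = 1e-9)
  }
})

test_that("the dispersion correction is never anti-conservative", {
  set.seed(303)
  n_over <- 0L
  for (i in 1:200) {
    # beta-binomial scatter within groups produces raw_phi > 1 frequently
    ca <- rep(30L, 4); cb <- rep(30L, 4)
    pa <- stats::rbeta(4, 4, 6); pb <- stats::rbeta(4, 4, 6)
    ma <- stats::rbinom(4, ca, pa); mb <- stats::rbinom(4, cb, pb)
    if (sum(ma) == 0 || sum(mb) == 0) next
    r <- test_site(ma, ca, mb, cb)
    p_uncorrected <- stats::pchisq(r$statistic * r$phi, 1, lower.tail = FALSE)
    if (!is.na(r$raw_phi) && r$raw_phi > 1) {
      n_over <- n_over + 1L
      expect_gte(r$p, p_uncorrected)
      expect_equal(r$phi, r$raw_phi)
    } else {
      expect_equal(r$phi, 1) # clamped from below
    }
  }
  expect_gt(n_over, 50)
})

test_that("the median statistic grows with the injected difference", {
  stat_median <- function(delta) {
    stats <- vapply(1:150, function(i) {
      ma <- stats::rbinom(3, 30, 0.45)
      mb <- stats::rbinom(3, 30, 0.45 + delta / 100)
      test_site(ma, rep(30, 3), mb, rep(30, 3))$statistic
    }, numeric(1))
    stats::median(stats)
  }
  set.seed(404)
  med <- vapply(c(0, 15, 30, 45), stat_median, numeric(1))
  expect_true(all(diff(med) >= 0))
})

test_that("BH adjustment and strict-threshold calling match hand arithmetic", {
  tests <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                      p = c(0.001, 0.02, 0.04, 0.9),
                      meth_diff = c(50, -30, 20, 10))
  out <- adjust_and_call(tests, q_threshold = 0.01)
  expect_equal(out$q, c(0.004, 0.04, 0.16 / 3, 0.9), tolerance = 1e-12)
  expect_equal(out$is_dms, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$direction, c("hyper", "hypo", "hyper", "hyper"))
})

test_that("calling applies no minimum-difference filter but is strict at q", {
  # a 1-point difference with tiny q is a DMS; q exactly at the threshold is not
  tests <- data.frame(chrom = "chr1", pos = c(1L, 2L),
                      p = c(1e-6, 1), meth_diff = c(1, 40))
  out <- adjust_and_call(tests, q_threshold = 0.01)
  expect_true(out$is_dms[out$pos == 1])
  tie <- adjust_and_call(data.frame(chrom = "chr1", pos = 1L, p = 0.01, meth_diff = 5),
                         q_threshold = 0.01)
  expect_false(tie$is_dms)
  none <- adjust_and_call(data.frame(chrom = "chr1", pos = 1:3, p = rep(1, 3),
                                     meth_diff = c(1, 2, 3)))
  expect_false(any(none$is_dms))
  # a zero difference is never a DMS even at tiny q
  zero <- adjust_and_call(data.frame(chrom = "chr1", pos = 1L, p = 1e-10, meth_diff = 0))
  expect_false(zero$is_dms)
})

test_that("diff_methylation composes the stages and reports consistent counts", {
  set.seed(7)
  n <- 50
  cov <- matrix(30L, n, 12)
  meth <- cbind(matrix(stats::rbinom(n * 6, 30, 0.3), n, 6),
                matrix(stats::rbinom(n * 6, 30, 0.7), n, 6))
  x <- mk_matrix(seq_len(n) * 100L, meth, cov, groups = rep(c("A", "B"), each = 6))
  fit <- diff_methylation(x, "A", "B", quiet = TRUE)
  expect_s3_class(fit, "dms_fit")
  expect_equal(fit$n_dms, fit$n_hyper + fit$n_hypo)
  expect_equal(fit$n_tested, n)
  expect_gt(fit$n_dms, 0)
  expect_true(all(dms(fit)$direction == "hyper"))
  expect_equal(unname(coef(fit)), fit$results$meth_diff)
  expect_output(print(fit), "DMS at q < 0.01")
  expect_output(print(summary(fit)), "phi")
})

test_that("hemisphere restriction selects the right samples", {
  n <- 10
  cov <- matrix(30L, n, 12)
  meth <- matrix(15L, n, 12)
  hem <- rep(c("control", "lesioned"), 6)
  x <- mk_matrix(seq_len(n) * 10L, meth, cov, groups = rep(c("A", "B"), each = 6),
                 hemis = hem)
  fit <- diff_methylation(x, "A", "B", hemisphere = "control", quiet = TRUE)
  expect_length(fit$spec$a_samples, 3)
  expect_length(fit$spec$b_samples, 3)
  side <- diff_methylation(x, "A", "A", hemisphere_a = "control",
                           hemisphere_b = "lesioned", quiet = TRUE)
  expect_equal(side$spec$name, "A.lesioned-vs-A.control")
  expect_equal(side$n_dms, 0)
})
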