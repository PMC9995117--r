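test_that("residualization removes means and linear curvature dependence exactly", {
  set.seed(5)
  n <- 200
  curv <- rnorm(n, 0, 0.2)
  v2 <- rep(TRUE, n)
  # exactly linear map -> residual identically zero
  q <- 0.6 + 0.03 * curv
  expect_equal(residualize(q, curv, v2), rep(0, n), tolerance = 1e-12)
  # zero curvature -> mean subtraction only
  q2 <- rnorm(n, 0.58, 0.05)
  expect_equal(residualize(q2, rep(0, n), v2), q2 - mean(q2))
  # constant curvature degrades gracefully to mean subtraction
  expect_equal(residualize(q2, rep(0.1, n), v2), q2 - mean(q2))
  expect_error(residualize(q2, curv, rep(FALSE, n)), "empty")
})

test_that("injected curvature coupling is removed on a synthetic hemisphere", {
  cfg <- small_cohort_config(curvature_coupling = 0.02)
  h <- simulate_hemisphere(cfg, seed = 21)
  r <- residualize(h$qmri$r1, h$patch$curvature, h$patch$v2_mask)
  expect_lt(abs(cor(r[h$patch$v2_mask], h$patch$curvature[h$patch$v2_mask])),
            0.01)
})

test_that("stripe ROIs follow the exclusive-threshold set logic", {
  zc <- c(3, 1, 3, 0, 2)
  zd <- c(0, 3, 3, 1, 0)
  v2 <- rep(TRUE, 5)
  roi <- define_stripe_rois(zc, zd, v2, 1.96)
  expect_equal(which(roi$thin), c(1, 5))       # v2 overlap discarded
  expect_equal(which(roi$thick), 2)
  expect_equal(which(roi$rest_minus_thick), c(1, 4, 5))
  expect_equal(which(roi$rest_minus_thin), c(2, 4))
  expect_false(roi$thin_empty)

  # threshold above max z: empty ROIs flagged
  hi <- define_stripe_rois(zc, zd, v2, 10)
  expect_true(hi$thin_empty && hi$thick_empty)

  # thr = 0: every vertex supra-threshold in exactly one map is assigned
  z0 <- define_stripe_rois(c(1, -1, 2), c(-2, 5, 3), rep(TRUE, 3), 0)
  expect_equal(which(z0$thin), 1)
  expect_equal(which(z0$thick), 2)
  expect_error(define_stripe_rois(zc, zd, v2, -1), ">= 0")
})

test_that("ROI partition is verified against brute-force set enumeration", {
  set.seed(8)
  for (rep in 1:20) {
    n <- 60
    zc <- rnorm(n); zd <- rnorm(n)
    v2 <- runif(n) < 0.9
    thr <- runif(1, 0, 2)
    roi <- define_stripe_rois(zc, zd, v2, thr)
    supra <- v2 & (zc >= thr | zd >= thr)
    overlap <- v2 & zc >= thr & zd >= thr
    # thin, thick, overlap partition the supra-threshold set
    expect_equal(sort(c(which(roi$thin), which(roi$thick), which(overlap))),
                 which(supra))
    expect_false(any(roi$thin & roi$thick))
    expect_true(all(which(roi$thin) %in% which(v2)))
  }
})

test_that("stripe statistic reproduces hand arithmetic and zero cases", {
  res <- c(-1, 0, 0, 0, 0)
  roi <- list(thin = c(TRUE, FALSE, FALSE, FALSE, FALSE),
              thick = c(FALSE, TRUE, FALSE, FALSE, FALSE),
              rest_minus_thick = c(TRUE, FALSE, FALSE, TRUE, TRUE),
              rest_minus_thin = c(FALSE, TRUE, FALSE, TRUE, FALSE))
  d <- stripe_statistic(res, roi)
  expect_equal(unname(d[["d_thin"]]), -1 - (-1 / 3))
  # constant residuals give zero statistics
  expect_equal(unname(stripe_statistic(rep(2, 5), roi)),
               c(0, 0))
  # empty ROI -> NA
  roi$thin <- rep(FALSE, 5)
  expect_true(is.na(stripe_statistic(res, roi)[["d_thin"]]))
})

test_that("statistic is invariant to map offsets and linear curvature confounds", {
  h <- simulate_hemisphere(small_cohort_config(), seed = 13)
  p <- h$patch
  roi <- define_stripe_rois(h$color, h$disparity, p$v2_mask, 1.96)
  base <- stripe_statistic(residualize(h$qmri$r1, p$curvature, p$v2_mask),
                           roi, p$vertex_area)
  shifted <- stripe_statistic(
    residualize(h$qmri$r1 + 0.3, p$curvature, p$v2_mask), roi, p$vertex_area)
  expect_equal(shifted, base, tolerance = 1e-10)
  confounded <- stripe_statistic(
    residualize(h$qmri$r1 + 0.5 * p$curvature, p$curvature, p$v2_mask),
    roi, p$vertex_area)
  expect_equal(confounded, base, tolerance = 1e-10)
})

test_that("group pooling is an unweighted hemisphere mean", {
  expect_equal(group_statistic(c(-0.004, -0.006)), -0.005)
  expect_equal(group_statistic(c(-0.006, -0.004)), -0.005)  # order invariant
  m <- rbind(c(-0.004, -0.01), c(-0.006, -0.02))
  expect_equal(unname(group_statistic(m)), c(-0.005, -0.015))
  expect_equal(group_statistic(c(2, 2, 2)), 2)
})

test_that("binomial 3-sigma correction matches direct arithmetic", {
  expect_equal(corrected_pvalue(100, 10000), (100 + 3 * sqrt(99)) / 10000)
  expect_equal(corrected_pvalue(100, 10000), 0.0129850, tolerance = 1e-5)
  expect_equal(corrected_pvalue(0, 10000),
               3 * sqrt(10000 * 1e-4 * (1 - 1e-4)) / 10000)
  expect_equal(corrected_pvalue(0, 10000), 2.99985e-4, tolerance = 1e-6)
  expect_equal(corrected_pvalue(10000, 10000), 1)  # sigma = 0, capped at 1
  expect_gt(corrected_pvalue(0, 500), 0)           # never exactly zero
  expect_error(corrected_pvalue(5, 0), "> 0")
  expect_error(corrected_pvalue(-1, 10), "0, n")
})

test_that("permutation p is ~0.5 when the observation sits at the null median", {
  h <- simulate_hemisphere(small_cohort_config(delta_thin = 0,
                                               delta_thick = 0), seed = 2)
  coh <- structure(list(hemispheres = list(h)), class = "stripe_cohort")
  pt <- permutation_test(coh, threshold = 1.96, n = 200, seed = 3,
                         samplers = list(small_patch_sampler()))
  # null cohort: observed is a typical draw from its own null
  for (res in pt) {
    expect_gte(res$p_corrected, 0.05)
    expect_equal(res$n, 200)
    expect_lte(res$k, res$n)
  }
  # manufactured observation at the exact null median
  med <- median(pt$thin$null_values)
  k <- sum(pt$thin$null_values <= med)
  expect_equal(k / pt$thin$n, 0.5, tolerance = 0.05)
})

test_that("threshold sweep has one row per threshold with monotone ROI sizes", {
  coh <- simulate_cohort(small_cohort_config(seed = 6))
  sw <- threshold_sweep(coh)
  expect_equal(nrow(sw), 10)
  expect_equal(sw$threshold, seq(0, 4.5, by = 0.5))
  # supra-threshold sets shrink monotonically; the exclusive ROIs inherit
  # this once the overlap-exclusion correction is small (thresholds >= 1)
  mono <- sw$threshold >= 1
  expect_true(all(diff(sw$mean_thin_vertices[mono]) <= 0))
  expect_true(all(diff(sw$mean_thick_vertices[mono]) <= 0))
  expect_true(all(is.na(sw$p_thin)))  # n = 0: statistics only
})

test_that("null cohorts show no systematic sign across thresholds", {
  signs <- vapply(1:50, function(ci) {
    coh <- simulate_cohort(small_cohort_config(delta_thin = 0, delta_thick = 0,
                                               seed = 3000 + ci))
    sw <- threshold_sweep(coh, thresholds = c(1, 1.96, 3))
    sign(mean(sw$d_thin, na.rm = TRUE))
  }, numeric(1))
  bt <- binom.test(sum(signs > 0), sum(signs != 0))
  expect_gt(bt$p.value, 0.05)
})

test_that("coverage summary counts areas and completes to 100 %", {
  roi <- list(thin = c(TRUE, FALSE, FALSE, FALSE, TRUE),
              thick = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  v2 <- rep(TRUE, 5)
  cov <- coverage_summary(roi, v2)
  expect_equal(unname(cov), c(40, 20, 40))
  # empty ROIs: all pale
  none <- list(thin = rep(FALSE, 5), thick = rep(FALSE, 5))
  expect_equal(unname(coverage_summary(none, v2)), c(0, 0, 100))
  # area weighting matters
  w <- c(2, 1, 1, 1, 1)
  expect_equal(unname(coverage_summary(roi, v2, w))[1], 100 * 3 / 6)
  expect_error(coverage_summary(roi, rep(FALSE, 5)), "> 0")
})

test_that("reliability correlation handles identity, reversal and inference", {
  h <- simulate_hemisphere(small_cohort_config(), seed = 17)
  D <- patch_distances(h$patch)
  m1 <- h$color_sessions[, 1]
  rr <- reliability_correlation(m1, m1, h$patch$v2_mask, D, n = 100, seed = 1)
  expect_equal(rr$r, 1)
  expect_lt(rr$p_corrected, 0.05)
  # rank reversal
  rev <- -m1
  expect_equal(reliability_correlation(m1, rev, h$patch$v2_mask, D,
                                       n = 100, seed = 1)$r, -1)
  # the two sessions of the generator correlate (shared stripe effect;
  # Spearman on the bimodal stripe/background mixture plateaus well below 1)
  rs <- reliability_correlation(h$color_sessions[, 1], h$color_sessions[, 2],
                                h$patch$v2_mask, D, n = 100, seed = 2)
  expect_gt(rs$r, 0.25)
  expect_lt(rs$p_corrected, 0.05)
})

test_that("power grows with effect size and cohort size", {
  sam <- small_patch_sampler()
  rej_rate <- function(effect_mult, n_subj) {
    mean(vapply(1:8, function(ci) {
      cfg <- small_cohort_config(n_subjects = n_subj,
                                 delta_thin = -0.0079 * effect_mult,
                                 delta_thick = -0.0233 * effect_mult,
                                 seed = 8000 + 97 * ci)
      coh <- simulate_cohort(cfg)
      pt <- permutation_test(coh, 1.96, n = 100, seed = ci,
                             samplers = rep(list(sam), n_subj))
      pt$thick$p_corrected < 0.05
    }, logical(1)))
  }
  p0 <- rej_rate(0, 1)
  p2 <- rej_rate(2, 1)
  expect_lte(p0, p2)
  p2b <- rej_rate(2, 3)
  expect_lte(p2 - 0.15, p2b)  # non-decreasing up to Monte-Carlo slack
  expect_lte(p0, 0.25)
  expect_gte(p2b, 0.5)
})
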