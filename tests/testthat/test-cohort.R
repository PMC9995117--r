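test_that("noiseless activation maps equal the effect on the target stripe", {
  p <- generate_patch(16, 8, 0.8, list(type = "zero"))
  s <- generate_stripe_labels(p)
  m <- generate_activation_maps(p, s, effect_z = 3, noise_sd = 0, seed = 1)
  expect_equal(m$color, 3 * (s$labels == "thin"), ignore_attr = TRUE)
  expect_equal(m$disparity, 3 * (s$labels == "thick"), ignore_attr = TRUE)
})

test_that("in-stripe mean z matches the configured effect over replicates", {
  p <- generate_patch(16, 8, 0.8, list(type = "zero"))
  s <- generate_stripe_labels(p)
  thin <- s$labels == "thin"
  mu <- mean(vapply(1:100, function(r)
    mean(generate_activation_maps(p, s, 3, 2, 1, seed = r)$color[thin]),
    numeric(1)))
  # Monte-Carlo oracle: sample mean of z over thin vertices across replicates
  expect_equal(mu, 3.0, tolerance = 0.05)
})

test_that("activation generation is deterministic and maps are independent", {
  p <- generate_patch(16, 8, 0.8, list(type = "zero"))
  s <- generate_stripe_labels(p)
  a <- generate_activation_maps(p, s, 3, 2, 1, seed = 7)
  b <- generate_activation_maps(p, s, 3, 2, 1, seed = 7)
  expect_identical(a, b)
  expect_lt(abs(cor(a$color - 3 * (s$labels == "thin"),
                    a$disparity - 3 * (s$labels == "thick"))), 0.2)
})

test_that("noiseless qMRI maps take exactly three R1 levels with the configured offsets", {
  p <- generate_patch(16, 8, 0.8, list(type = "zero"))
  s <- generate_stripe_labels(p)
  cfg <- small_cohort_config(noise_cv = 0, curvature_coupling = 0)
  q <- generate_qmri_maps(p, s, cfg)
  expect_equal(length(unique(q$r1)), 3L)
  lab <- s$labels
  expect_equal(mean(q$r1[lab == "thin"]) - mean(q$r1[lab == "pale"]),
               cfg$delta_thin)
  expect_equal(mean(q$r1[lab == "thick"]) - mean(q$r1[lab == "pale"]),
               cfg$delta_thick)
  expect_equal(q$mtvf, 100 - q$pd)
})

test_that("calibrate_stripe_effects deltas hit the target ideal-label statistics to float precision", {
  p <- generate_patch(32, 16, 0.4, list(type = "zero"))
  s <- generate_stripe_labels(p)
  cfg <- calibrate_stripe_effects(cohort_config(noise_cv = 0, curvature_coupling = 0),
                           p, s)
  q <- generate_qmri_maps(p, s, cfg)
  r <- residualize(q$r1, p$curvature, p$v2_mask)
  ideal <- list(thin = s$labels == "thin", thick = s$labels == "thick",
                rest_minus_thick = s$labels != "thick",
                rest_minus_thin = s$labels != "thin")
  d <- stripe_statistic(r, ideal, p$vertex_area)
  expect_equal(unname(d[["d_thin"]]), -0.005, tolerance = 1e-12)
  expect_equal(unname(d[["d_thick"]]), -0.014, tolerance = 1e-12)

  # brute-force oracle: direct area-weighted means of the raw label map
  w <- p$vertex_area
  wm <- function(m) sum(q$r1[m] * w[m]) / sum(w[m])
  expect_equal(wm(ideal$thin) - wm(ideal$rest_minus_thick), -0.005,
               tolerance = 1e-12)
  expect_equal(wm(ideal$thick) - wm(ideal$rest_minus_thin), -0.014,
               tolerance = 1e-12)
})

test_that("calibrate_stripe_effects with zero targets returns zero deltas and flags degenerate geometry", {
  cfg <- cohort_config()
  z <- calibrate_stripe_effects(cfg, target_thin = 0, target_thick = 0)
  expect_equal(z$delta_thin, 0)
  expect_equal(z$delta_thick, 0)
  # a label map without pale vertices has no reference tissue
  p <- generate_patch(4, 4, 1, list(type = "zero"))
  no_pale <- list(labels = factor(rep(c("thin", "thick"),
                                      length.out = nrow(p$coords)),
                                  levels = c("pale", "thin", "thick")))
  expect_error(calibrate_stripe_effects(cfg, p, no_pale), "pale")
})

test_that("simulated V2 R1 coefficient of variation matches the calibration", {
  cvs <- vapply(1:10, function(i) {
    h <- simulate_hemisphere(small_cohort_config(), seed = i)
    v2 <- h$patch$v2_mask
    100 * sd(h$qmri$r1[v2]) / mean(h$qmri$r1[v2])
  }, numeric(1))
  expect_equal(mean(cvs), 11.3, tolerance = 0.1)  # within ~1.1 percentage pts
})

test_that("FLASH forward simulation is exact and round-trips through the fitter", {
  p <- generate_patch(8, 4, 1, list(type = "zero"))
  s <- generate_stripe_labels(p)
  cfg <- small_cohort_config(noise_cv = 0, curvature_coupling = 0)
  q <- generate_qmri_maps(p, s, cfg)
  pr <- flash_protocol()
  sig <- generate_flash_signals(q, pr, b1_efficiency = 1, noise_sd = 0)
  # noiseless signals equal the forward model exactly
  expect_equal(unname(sig$signal["T1w", 3, 5]),
               flash_signal(q$amplitude_a[5], q$r1[5], q$r2s[5],
                            pr$nominal_fa[["T1w"]], pr$tr[["T1w"]],
                            pr$te_list[3]))
  # b1 = 1 equals the no-correction path
  sig2 <- generate_flash_signals(q, pr, b1_efficiency = rep(1, length(q$r1)),
                                 noise_sd = 0)
  expect_equal(sig$signal, sig2$signal)
  # forward-inverse oracle: noiseless fit recovers R1/R2* within 2 %
  fit <- fit_qmri(sig, pr)
  expect_lt(max(abs(fit$r1 / q$r1 - 1)), 0.02)
  expect_lt(max(abs(fit$r2s / q$r2s - 1)), 1e-8)
})

test_that("retinotopy generator is seeded and reverse runs negate the stimulus phase", {
  p <- generate_patch(4, 4, 2, list(type = "zero"))
  phi <- wrapa(seq(-3, 3, length.out = nrow(p$coords)))
  a <- generate_retino_timeseries(p, phi, noise_sd = 0.5, seed = 3)
  b <- generate_retino_timeseries(p, phi, noise_sd = 0.5, seed = 3)
  expect_identical(a, b)
  # noiseless, zero delay: forward phase +phi, reverse -phi at t = 0 slope
  f0 <- generate_retino_timeseries(p, phi, hemo_delay_s = 0)
  r0 <- generate_retino_timeseries(p, phi, hemo_delay_s = 0,
                                   direction = "reverse")
  expect_equal(f0[1, ] - 100, cos(-phi), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(r0[1, ] - 100, cos(phi), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("cohorts are reproducible and extending subjects preserves existing ones", {
  cfg <- small_cohort_config(n_subjects = 2L, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  cfg3 <- small_cohort_config(n_subjects = 3L, seed = 11)
  c3 <- simulate_cohort(cfg3)
  expect_identical(a$hemispheres[[1]]$qmri, c3$hemispheres[[1]]$qmri)
  expect_identical(a$hemispheres[[2]]$color, c3$hemispheres[[2]]$color)
})

test_that("config validation rejects impossible cohorts", {
  expect_error(cohort_config(n_subjects = 0), "n_subjects")
  expect_error(cohort_config(noise_cv = -1), "noise_cv")
  expect_error(cohort_config(thin_width = 5, thick_width = 4), "cycle_width")
})
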