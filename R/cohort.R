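#' Configuration of a synthetic stripe-mapping cohort
#'
#' Bundles every knob of the synthetic cortical-patch cohort. Defaults are
#' the study conditions the rest of the package is tested against: four
#' subjects with two hemispheres each; two fMRI sessions per contrast whose
#' z-maps are averaged (as in the real analysis); in-stripe mean z of 5 per
#' session so that ROIs survive the full z = 0..4.5 threshold sweep; a V2
#' baseline R1 of 0.58 s^-1 with small negative thin/thick offsets
#' (pre-solved so that the ideal-label stripe statistics are -0.005 and
#' -0.014 s^-1, the printed group effects); R1 measurement noise with a
#' standard deviation of 11.3 % of baseline (the reported V2 coefficient of
#' variation); and a weak linear coupling of R1 to local curvature that the
#' analysis must regress out.
#'
#' @param n_subjects,hemispheres_per_subject cohort size.
#' @param n_sessions fMRI sessions per contrast; the analyzed activation map
#'   is their average.
#' @param effect_z in-stripe mean z-score per session map.
#' @param noise_corr_length spatial correlation length of activation-map
#'   noise, mm.
#' @param activation_noise_sd per-session z-map noise SD (1 = calibrated
#'   z-scores).
#' @param r1_baseline V2 gray-matter R1, s^-1.
#' @param delta_thin,delta_thick additive R1 offsets of thin/thick stripes,
#'   s^-1 (negative = less myelinated than pale).
#' @param curvature_coupling linear R1-curvature coupling, s^-1 per mm^-1.
#' @param noise_cv R1 measurement-noise SD as percent of `r1_baseline`.
#' @param r2s_baseline,delta_thin_r2s,delta_thick_r2s,curvature_coupling_r2s
#'   analogous R2* parameters, s^-1; stripe effects default to 0 (the null
#'   R2* finding).
#' @param pd_baseline gray-matter PD baseline, pu.
#' @param patch_width,patch_height,patch_spacing patch geometry, mm.
#' @param cycle_width,thin_width,thick_width,orientation stripe geometry
#'   (see [generate_stripe_labels()]).
#' @param curvature_sd,curvature_corr_length curvature-field scale (mm^-1)
#'   and correlation length (mm).
#' @param seed root seed; all per-subject/hemisphere/map streams are derived
#'   from it so that identical configs give identical cohorts.
#' @return object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_subjects = 4L, hemispheres_per_subject = 2L,
                          n_sessions = 2L,
                          effect_z = 5.0, noise_corr_length = 2.0,
                          activation_noise_sd = 1.0,
                          r1_baseline = 0.58,
                          delta_thin = -0.005 * 0.675 / 0.425,
                          delta_thick = -0.014 * 0.750 / 0.425,
                          curvature_coupling = 0.02,
                          noise_cv = 11.3,
                          r2s_baseline = 30, delta_thin_r2s = 0,
                          delta_thick_r2s = 0, curvature_coupling_r2s = 1.0,
                          pd_baseline = 80,
                          patch_width = 32, patch_height = 16,
                          patch_spacing = 0.4,
                          cycle_width = 8.0, thin_width = 2.0,
                          thick_width = 2.6, orientation = 0,
                          curvature_sd = 0.15, curvature_corr_length = 5,
                          seed = 1L) {
  cfg <- as.list(environment())
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  if (cfg$hemispheres_per_subject < 1L)
    stop("hemispheres_per_subject must be >= 1", call. = FALSE)
  if (cfg$n_sessions < 1L) stop("n_sessions must be >= 1", call. = FALSE)
  if (cfg$noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (cfg$effect_z < 0) stop("effect_z must be >= 0", call. = FALSE)
  if (cfg$activation_noise_sd < 0)
    stop("activation_noise_sd must be >= 0", call. = FALSE)
  if (cfg$thin_width + cfg$thick_width >= cfg$cycle_width)
    stop("thin + thick width must be below cycle_width", call. = FALSE)
  invisible(TRUE)
}

#' Calibrate stripe R1 offsets to target ideal-label statistics
#'
#' Solves the thin/thick R1 offsets so that the noiseless, true-label
#' stripe-versus-rest statistics equal the requested targets (defaults:
#' the printed group effects, -0.005 and -0.014 s^-1 at z = 1.96). With
#' area fractions f (thin/thick/pale) and pale stripes at baseline, the
#' ideal thin statistic is
#' `delta_thin * f_pale / (f_thin + f_pale)` (the comparison set is V2 minus
#' the other stripe type, so it contains the own stripe plus pale), and
#' symmetrically for thick; the offsets follow by inversion.
#'
#' When `patch` and `stripes` are supplied the realized area-weighted label
#' fractions of the discrete grid are used, making the ideal-label statistic
#' exact to float precision; otherwise the analytic width ratios from the
#' config are used.
#'
#' @param config a `cohort_config`.
#' @param patch,stripes optional realized geometry.
#' @param target_thin,target_thick target statistics, s^-1.
#' @return the config with `delta_thin`/`delta_thick` replaced.
#' @export
calibrate_stripe_effects <- function(config, patch = NULL, stripes = NULL,
                              target_thin = -0.005, target_thick = -0.014) {
  if (!is.null(patch) && !is.null(stripes)) {
    f <- stripe_area_fractions(patch, stripes)
  } else {
    pale <- config$cycle_width - config$thin_width - config$thick_width
    f <- c(pale = pale, thin = config$thin_width,
           thick = config$thick_width) / config$cycle_width
  }
  if (f[["pale"]] <= 0) stop("degenerate geometry: zero pale area",
                             call. = FALSE)
  config$delta_thin <- target_thin * (f[["thin"]] + f[["pale"]]) / f[["pale"]]
  config$delta_thick <- target_thick * (f[["thick"]] + f[["pale"]]) / f[["pale"]]
  config
}

#' Synthetic activation z-maps for one session
#'
#' Color-contrast map: `effect_z` on thin-stripe vertices plus a smooth
#' Gaussian-random-field noise term; disparity-contrast map: `effect_z` on
#' thick-stripe vertices plus an independent GRF. The two maps share no
#' noise given the seed split.
#'
#' @param patch a `cortical_patch`.
#' @param stripes a `stripe_model`.
#' @param effect_z in-stripe mean z.
#' @param noise_corr_length GRF correlation length, mm.
#' @param noise_sd noise SD in z units.
#' @param seed integer seed.
#' @return list with numeric vectors `color` and `disparity`.
#' @export
generate_activation_maps <- function(patch, stripes, effect_z = 5.0,
                                     noise_corr_length = 2.0, noise_sd = 1.0,
                                     seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (effect_z < 0) stop("effect_z must be >= 0", call. = FALSE)
  g1 <- if (noise_sd > 0)
    as.vector(grf_grid(patch$nx, patch$ny, patch$spacing, noise_corr_length,
                       child_seed(seed, 1))) * noise_sd else 0
  g2 <- if (noise_sd > 0)
    as.vector(grf_grid(patch$nx, patch$ny, patch$spacing, noise_corr_length,
                       child_seed(seed, 2))) * noise_sd else 0
  list(color = effect_z * (stripes$labels == "thin") + g1,
       disparity = effect_z * (stripes$labels == "thick") + g2)
}

#' Synthetic quantitative MRI maps for one hemisphere
#'
#' R1 is baseline plus stripe offsets plus a linear curvature coupling plus
#' white measurement noise with SD `noise_cv`/100 x baseline; R2* and PD are
#' generated analogously with their own baselines (R2* stripe offsets
#' default to zero). PD is converted to MTVF as well; `amplitude_a` is a
#' PD-proportional pre-calibration amplitude.
#'
#' @param patch a `cortical_patch`.
#' @param stripes a `stripe_model`.
#' @param config a `cohort_config`.
#' @param seed integer seed (defaults to the config seed).
#' @return object of class `qmri_maps`: list with `r1`, `r2s`, `pd`, `mtvf`,
#'   `amplitude_a` vectors.
#' @export
generate_qmri_maps <- function(patch, stripes, config, seed = config$seed) {
  validate_cohort_config(config)
  thin <- stripes$labels == "thin"
  thick <- stripes$labels == "thick"
  n <- nrow(patch$coords)
  nsd <- config$noise_cv / 100

  noise <- function(idx, base) {
    if (nsd == 0) 0
    else with_seed(child_seed(seed, idx), stats::rnorm(n, 0, nsd * base))
  }
  r1 <- config$r1_baseline + config$delta_thin * thin +
    config$delta_thick * thick +
    config$curvature_coupling * patch$curvature + noise(11, config$r1_baseline)
  r2s <- config$r2s_baseline + config$delta_thin_r2s * thin +
    config$delta_thick_r2s * thick +
    config$curvature_coupling_r2s * patch$curvature +
    noise(12, config$r2s_baseline)
  pd <- rep(config$pd_baseline, n) + noise(13, config$pd_baseline)
  structure(list(r1 = r1, r2s = r2s, pd = pd, mtvf = mtvf(pd),
                 amplitude_a = pd), class = "qmri_maps")
}

#' Forward-simulate multi-echo dual flip angle FLASH signals
#'
#' Evaluates [flash_signal()] per vertex, contrast and echo with the true
#' flip angle equal to `b1_efficiency` times the nominal angle, plus
#' additive Gaussian noise.
#'
#' @param qmri_maps a `qmri_maps` object (uses `amplitude_a`, `r1`, `r2s`).
#' @param protocol a `flash_protocol`.
#' @param b1_efficiency scalar or per-vertex B1+ efficiency.
#' @param noise_sd additive noise SD in signal units.
#' @param seed integer seed.
#' @return object of class `multi_echo_signals`: list with `signal`
#'   (`[contrast, echo, location]`, contrasts PDw/T1w) and `b1_efficiency`.
#' @export
generate_flash_signals <- function(qmri_maps, protocol, b1_efficiency = 1,
                                   noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  n <- length(qmri_maps$r1)
  fT <- rep_len(b1_efficiency, n)
  ne <- length(protocol$te_list)
  sig <- array(NA_real_, c(2, ne, n),
               dimnames = list(c("PDw", "T1w"), NULL, NULL))
  for (ci in 1:2) {
    cn <- c("PDw", "T1w")[ci]
    fa <- protocol$nominal_fa[[cn]] * fT
    for (ei in seq_len(ne)) {
      sig[ci, ei, ] <- flash_signal(qmri_maps$amplitude_a, qmri_maps$r1,
                                    qmri_maps$r2s, fa, protocol$tr[[cn]],
                                    protocol$te_list[ei])
    }
  }
  if (noise_sd > 0)
    sig <- sig + with_seed(seed, array(stats::rnorm(length(sig), 0, noise_sd),
                                       dim(sig)))
  structure(list(signal = sig, b1_efficiency = fT),
            class = "multi_echo_signals")
}

#' Traveling-wave retinotopy time series
#'
#' Per-vertex cosine at the stimulus frequency whose phase encodes the true
#' eccentricity/polar-angle phase, delayed by a fixed hemodynamic lag:
#' the response is `cos(2 pi f t - theta)` with
#' `theta = s * phase_true + 2 pi hemo_delay_s / period_s`, `s = +1` for the
#' forward and `-1` for the reverse stimulus direction, plus optional linear
#' drift and Gaussian noise.
#'
#' @param patch a `cortical_patch` (sets the vertex count).
#' @param phase_map_true per-vertex stimulus phase in (-pi, pi].
#' @param period_s stimulus cycle period, s.
#' @param tr_s sampling interval (volume TR), s.
#' @param n_cycles number of stimulus cycles acquired.
#' @param hemo_delay_s hemodynamic delay, s.
#' @param noise_sd additive noise SD (percent-signal units).
#' @param direction `"forward"` or `"reverse"`.
#' @param amplitude response amplitude.
#' @param drift linear drift amplitude over the whole run.
#' @param baseline mean signal level added to every vertex.
#' @param seed integer seed.
#' @return timepoints x vertices matrix.
#' @export
generate_retino_timeseries <- function(patch, phase_map_true, period_s = 32,
                                       tr_s = 2, n_cycles = 8.25,
                                       hemo_delay_s = 5, noise_sd = 0,
                                       direction = c("forward", "reverse"),
                                       amplitude = 1, drift = 0,
                                       baseline = 100, seed = 1L) {
  direction <- match.arg(direction)
  stop_if_not_scalar_pos(period_s, "period_s")
  stop_if_not_scalar_pos(tr_s, "tr_s")
  n <- nrow(patch$coords)
  stopifnot(length(phase_map_true) == n)
  nt <- round(n_cycles * period_s / tr_s)
  t <- (seq_len(nt) - 1) * tr_s
  s <- if (direction == "forward") 1 else -1
  theta <- s * phase_map_true + 2 * pi * hemo_delay_s / period_s
  ts <- baseline + amplitude *
    cos(outer(2 * pi * t / period_s, theta, `-`))
  if (drift != 0) ts <- ts + drift * outer(t / max(t), rep(1, n))
  if (noise_sd > 0)
    ts <- ts + with_seed(seed, matrix(stats::rnorm(nt * n, 0, noise_sd), nt, n))
  ts
}

#' Simulate one hemisphere of the synthetic cohort
#'
#' Generates the patch (shared grid geometry, hemisphere-specific curvature
#' field), stripe labels, per-session activation maps for both contrasts,
#' their across-session averages (the maps the analysis consumes) and the
#' qMRI maps.
#'
#' @param config a `cohort_config`.
#' @param seed hemisphere-level seed.
#' @return list with `patch`, `stripes`, `color_sessions`/`disp_sessions`
#'   (matrices, one column per session), analysis maps `color`/`disparity`,
#'   and `qmri`.
#' @export
simulate_hemisphere <- function(config, seed = config$seed) {
  patch <- generate_patch(config$patch_width, config$patch_height,
                          config$patch_spacing,
                          list(type = "grf", sd = config$curvature_sd,
                               corr_length = config$curvature_corr_length),
                          seed = child_seed(seed, 7))
  stripes <- generate_stripe_labels(patch, config$cycle_width,
                                    config$thin_width, config$thick_width,
                                    config$orientation)
  col_s <- disp_s <- matrix(NA_real_, nrow(patch$coords), config$n_sessions)
  for (s in seq_len(config$n_sessions)) {
    m <- generate_activation_maps(patch, stripes, config$effect_z,
                                  config$noise_corr_length,
                                  config$activation_noise_sd,
                                  seed = child_seed(seed, 20 + s))
    col_s[, s] <- m$color
    disp_s[, s] <- m$disparity
  }
  qmri <- generate_qmri_maps(patch, stripes, config,
                             seed = child_seed(seed, 40))
  list(patch = patch, stripes = stripes,
       color_sessions = col_s, disp_sessions = disp_s,
       color = rowMeans(col_s), disparity = rowMeans(disp_s),
       qmri = qmri)
}

#' Simulate a full synthetic cohort
#'
#' Seeds are split hierarchically (cohort -> subject -> hemisphere), so
#' adding subjects never changes existing ones.
#'
#' @param config a `cohort_config`.
#' @return object of class `stripe_cohort`: list of hemispheres (each as in
#'   [simulate_hemisphere()], plus `subject` and `hemi` ids) with the config
#'   attached.
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  hemis <- list()
  for (si in seq_len(config$n_subjects)) {
    sseed <- child_seed(config$seed, si)
    for (hi in seq_len(config$hemispheres_per_subject)) {
      h <- simulate_hemisphere(config, seed = child_seed(sseed, hi))
      h$subject <- si; h$hemi <- hi
      hemis[[length(hemis) + 1L]] <- h
    }
  }
  structure(list(hemispheres = hemis, config = config),
            class = "stripe_cohort")
}

#' @export
print.stripe_cohort <- function(x, ...) {
  cat(sprintf("<stripe_cohort> %d subjects x %d hemispheres, %d vertices each\n",
              x$config$n_subjects, x$config$hemispheres_per_subject,
              nrow(x$hemispheres[[1]]$patch$coords)))
  invisible(x)
}
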