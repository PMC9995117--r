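#' Mean-centre a qMRI map and regress out curvature
#'
#' Following the deconfounding used for the stripe comparison: subtract the
#' V2 mean (removes inter-subject offsets), then ordinary least squares of
#' the map on curvature (intercept + slope, fitted within V2) and return the
#' residuals. Partial-volume effects of cortical folding are linear in
#' curvature, so a linear regression suffices. A constant curvature reduces
#' to mean subtraction only.
#'
#' @param qmap per-vertex quantitative values (e.g. R1, s^-1).
#' @param curvature per-vertex curvature, mm^-1.
#' @param v2_mask logical mask; the fit uses V2 vertices only.
#' @return per-vertex residual map (all vertices, residualized with the
#'   V2-fitted coefficients).
#' @export
residualize <- function(qmap, curvature, v2_mask) {
  if (!any(v2_mask)) stop("v2_mask is empty", call. = FALSE)
  x <- qmap - mean(qmap[v2_mask])
  cv <- curvature[v2_mask]
  if (stats::var(cv) == 0) return(x)
  cc <- curvature - mean(cv)
  beta <- sum((x[v2_mask]) * (cv - mean(cv))) / sum((cv - mean(cv))^2)
  alpha <- mean(x[v2_mask])
  x - alpha - beta * cc
}

#' Stripe ROIs by z-score thresholding with overlap exclusion
#'
#' Thin-stripe ROI: vertices with color-contrast z at or above the
#' threshold that are not supra-threshold in the disparity contrast (and
#' vice versa for thick) - vertices activated in both maps do not belong
#' exclusively to one stripe type and are discarded. The comparison sets
#' are whole V2 minus all supra-threshold vertices of the *other* contrast,
#' so they deliberately retain own-stripe and pale contributions.
#'
#' @param color_map,disparity_map per-vertex z maps.
#' @param v2_mask logical V2 mask.
#' @param threshold z threshold (>= 0).
#' @return object of class `roi_set`: logical masks `thin`, `thick`,
#'   `rest_minus_thick`, `rest_minus_thin`, the `threshold`, and flags
#'   `thin_empty`/`thick_empty`.
#' @export
define_stripe_rois <- function(color_map, disparity_map, v2_mask, threshold) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  supra_c <- v2_mask & color_map >= threshold
  supra_d <- v2_mask & disparity_map >= threshold
  thin <- supra_c & !supra_d
  thick <- supra_d & !supra_c
  structure(list(thin = thin, thick = thick,
                 rest_minus_thick = v2_mask & !supra_d,
                 rest_minus_thin = v2_mask & !supra_c,
                 threshold = threshold,
                 thin_empty = !any(thin), thick_empty = !any(thick)),
            class = "roi_set")
}

#' Stripe-versus-rest contrast statistic
#'
#' `d_thin` = area-weighted mean of the residual map over the thin ROI
#' minus the area-weighted mean over V2 excluding supra-threshold disparity
#' vertices; `d_thick` symmetrically. Negative values mean the stripe type
#' carries lower values than surrounding (pale-containing) cortex.
#'
#' @param residual_map per-vertex residualized values.
#' @param roiset a `roi_set`.
#' @param weights per-vertex weights (vertex areas; uniform if `NULL`).
#' @return named vector `c(d_thin, d_thick)`; `NA` where the stripe ROI is
#'   empty.
#' @export
stripe_statistic <- function(residual_map, roiset, weights = NULL) {
  w <- weights %||% rep(1, length(residual_map))
  d_one <- function(stripe, rest) {
    if (!any(stripe) || !any(rest)) return(NA_real_)
    wmean(residual_map[stripe], w[stripe]) -
      wmean(residual_map[rest], w[rest])
  }
  c(d_thin = d_one(roiset$thin, roiset$rest_minus_thick),
    d_thick = d_one(roiset$thick, roiset$rest_minus_thin))
}

#' Pool per-hemisphere statistics
#'
#' Unweighted mean across all hemispheres of all subjects (each hemisphere
#' contributes equally), dropping hemispheres with undefined statistics.
#'
#' @param per_hemisphere_stats numeric vector (or rows of a matrix) of
#'   per-hemisphere d values.
#' @return pooled statistic.
#' @export
group_statistic <- function(per_hemisphere_stats) {
  if (is.matrix(per_hemisphere_stats))
    return(colMeans(per_hemisphere_stats, na.rm = TRUE))
  mean(per_hemisphere_stats, na.rm = TRUE)
}

#' Permutation p-value with binomial 3-sigma correction
#'
#' The finite null sample makes the exceedance rate `k/n` itself uncertain;
#' the estimate is inflated by three binomial standard deviations:
#' `p = min(1, (k + 3 sigma)/n)` with `sigma = sqrt(n p_hat (1 - p_hat))`
#' and `p_hat = k/n` (substituting `1/n` at `k = 0` so the correction never
#' returns 0).
#'
#' @param k number of null samples at least as extreme as the observation.
#' @param n number of null samples.
#' @return corrected p-value in (0, 1].
#' @export
corrected_pvalue <- function(k, n) {
  if (n <= 0) stop("n must be > 0", call. = FALSE)
  if (k < 0 || k > n) stop("k must lie in [0, n]", call. = FALSE)
  p_hat <- if (k == 0) 1 / n else k / n
  sigma <- sqrt(n * p_hat * (1 - p_hat))
  min(1, (k + 3 * sigma) / n)
}

# exceedance count of a null sample against an observed value
exceedance_count <- function(null_values, observed, sided) {
  if (sided == "two") sum(abs(null_values) >= abs(observed))
  else if (observed >= 0) sum(null_values >= observed)
  else sum(null_values <= observed)
}

# Observed pooled statistics of a cohort at one threshold. Residual maps are
# precomputed per hemisphere (list `resid`).
cohort_observed <- function(cohort, resid, threshold,
                            color_maps = NULL, disp_maps = NULL) {
  nh <- length(cohort$hemispheres)
  st <- matrix(NA_real_, nh, 2)
  for (i in seq_len(nh)) {
    h <- cohort$hemispheres[[i]]
    roi <- define_stripe_rois(color_maps[[i]] %||% h$color,
                              disp_maps[[i]] %||% h$disparity,
                              h$patch$v2_mask, threshold)
    st[i, ] <- stripe_statistic(resid[[i]], roi, h$patch$vertex_area)
  }
  colnames(st) <- c("d_thin", "d_thick")
  st
}

#' Surrogate permutation test of the pooled stripe statistics
#'
#' For each of `n` iterations, the color and disparity activation maps of
#' every hemisphere are replaced by variogram-matched surrogates, the ROIs
#' are rebuilt at the same threshold, and the pooled statistics recomputed;
#' the observed statistics are compared against this spatially-informed
#' null. Iterations in which an ROI comes out empty are redrawn (count
#' reported). The exceedance count uses "at least as extreme" (>=).
#'
#' @param cohort a `stripe_cohort` (or compatible list of hemispheres).
#' @param threshold z threshold for ROI definition.
#' @param n number of permutations (>= 100 recommended; the study used
#'   10,000).
#' @param seed integer seed for the surrogate draws.
#' @param sided `"one"` (direction of the observed statistic; the
#'   directional stripe hypothesis) or `"two"`.
#' @param qmri_param which map to test, `"r1"` or `"r2s"`.
#' @param samplers optional precomputed list of `surrogate_sampler`s, one
#'   per hemisphere (built from patch distances otherwise).
#' @return list of two `permutation_result`s (`thin`, `thick`), each with
#'   `observed`, `null_values`, `n`, `k`, `p_corrected`, `sided`, and the
#'   total `n_redrawn`.
#' @export
permutation_test <- function(cohort, threshold = 1.96, n = 1000,
                             seed = 1L, sided = c("one", "two"),
                             qmri_param = c("r1", "r2s"), samplers = NULL) {
  sided <- match.arg(sided)
  qmri_param <- match.arg(qmri_param)
  if (n < 100) stop("n must be >= 100", call. = FALSE)
  hemis <- cohort$hemispheres
  nh <- length(hemis)
  resid <- lapply(hemis, function(h)
    residualize(h$qmri[[qmri_param]], h$patch$curvature, h$patch$v2_mask))
  if (is.null(samplers))
    samplers <- lapply(hemis, function(h)
      surrogate_sampler(patch_distances(h$patch)))

  obs <- group_statistic(cohort_observed(cohort, resid, threshold))

  pre <- lapply(seq_len(nh), function(i) {
    h <- hemis[[i]]
    list(gc = variogram_gamma(h$color, samplers[[i]]$pairs)$gamma,
         gd = variogram_gamma(h$disparity, samplers[[i]]$pairs)$gamma,
         sc = sort(h$color), sd = sort(h$disparity))
  })

  null_mat <- matrix(NA_real_, n, 2)
  n_redrawn <- 0L
  for (it in seq_len(n)) {
    draw <- 0L
    repeat {
      st <- matrix(NA_real_, nh, 2)
      iter_seed <- child_seed(seed, it * 1000L + draw)
      for (i in seq_len(nh)) {
        h <- hemis[[i]]
        cs <- with_seed(child_seed(iter_seed, 2L * i - 1L),
                        surrogate_draw(samplers[[i]], h$color, pre[[i]]$gc,
                                       TRUE, pre[[i]]$sc))
        ds <- with_seed(child_seed(iter_seed, 2L * i),
                        surrogate_draw(samplers[[i]], h$disparity, pre[[i]]$gd,
                                       TRUE, pre[[i]]$sd))
        roi <- define_stripe_rois(cs, ds, h$patch$v2_mask, threshold)
        st[i, ] <- stripe_statistic(resid[[i]], roi, h$patch$vertex_area)
      }
      pooled <- colMeans(st, na.rm = FALSE)
      if (all(is.finite(pooled)) || draw >= 20L) break
      draw <- draw + 1L
      n_redrawn <- n_redrawn + 1L
    }
    null_mat[it, ] <- pooled
  }

  res_one <- function(col, name) {
    nv <- null_mat[, col]
    nv <- nv[is.finite(nv)]
    k <- exceedance_count(nv, obs[col], sided)
    structure(list(statistic = name, observed = unname(obs[col]),
                   null_values = nv, n = length(nv), k = k,
                   p_corrected = corrected_pvalue(k, length(nv)),
                   sided = sided, n_redrawn = n_redrawn),
              class = "permutation_result")
  }
  list(thin = res_one(1, "d_thin"), thick = res_one(2, "d_thick"))
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s: observed %.5f, k = %d / n = %d, p = %.4g (%s-sided)\n",
              x$statistic, x$observed, x$k, x$n, x$p_corrected, x$sided))
  invisible(x)
}

#' Threshold sweep of the stripe comparison
#'
#' Recomputes ROIs, pooled statistics and (optionally) permutation p-values
#' over a set of z thresholds, mirroring the published z in {0, 0.5, ...,
#' 4.5} sweep with per-threshold significance stars (* p<0.05, ** p<0.01,
#' *** p<0.001).
#'
#' @param cohort a `stripe_cohort`.
#' @param thresholds z thresholds.
#' @param n permutations per threshold; 0 skips inference (statistics only).
#' @param seed integer seed.
#' @param sided sidedness (see [permutation_test()]).
#' @param qmri_param `"r1"` or `"r2s"`.
#' @return data.frame with one row per threshold: `threshold`, `d_thin`,
#'   `d_thick`, `p_thin`, `p_thick`, stars, and mean ROI vertex counts.
#' @export
threshold_sweep <- function(cohort, thresholds = seq(0, 4.5, by = 0.5),
                            n = 0, seed = 1L, sided = "one",
                            qmri_param = "r1") {
  if (!length(thresholds)) stop("thresholds must be non-empty", call. = FALSE)
  hemis <- cohort$hemispheres
  resid <- lapply(hemis, function(h)
    residualize(h$qmri[[qmri_param]], h$patch$curvature, h$patch$v2_mask))
  samplers <- if (n > 0)
    lapply(hemis, function(h) surrogate_sampler(patch_distances(h$patch)))

  rows <- lapply(thresholds, function(thr) {
    st <- cohort_observed(cohort, resid, thr)
    sizes <- vapply(hemis, function(h) {
      roi <- define_stripe_rois(h$color, h$disparity, h$patch$v2_mask, thr)
      c(sum(roi$thin), sum(roi$thick))
    }, numeric(2))
    p_thin <- p_thick <- NA_real_
    if (n > 0) {
      pt <- permutation_test(cohort, thr, n, seed = child_seed(seed, round(thr * 10)),
                             sided = sided, qmri_param = qmri_param,
                             samplers = samplers)
      p_thin <- pt$thin$p_corrected
      p_thick <- pt$thick$p_corrected
    }
    data.frame(threshold = thr,
               d_thin = group_statistic(st)[["d_thin"]],
               d_thick = group_statistic(st)[["d_thick"]],
               p_thin = p_thin, p_thick = p_thick,
               stars_thin = signif_stars(p_thin),
               stars_thick = signif_stars(p_thick),
               mean_thin_vertices = mean(sizes[1, ]),
               mean_thick_vertices = mean(sizes[2, ]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

signif_stars <- function(p) {
  if (!length(p) || is.na(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Relative V2 coverage of stripe ROIs
#'
#' Area percentages of the non-overlapping thin and thick ROIs within V2;
#' the pale percentage is the remainder (`100 - thin - thick`), consistent
#' with the tripartite-division assumption.
#'
#' @param roiset a `roi_set` (or a list with logical `thin`, `thick`).
#' @param v2_mask logical V2 mask.
#' @param vertex_area per-vertex areas (uniform if `NULL`).
#' @return named vector `c(thin, thick, pale)` in percent.
#' @export
coverage_summary <- function(roiset, v2_mask, vertex_area = NULL) {
  w <- vertex_area %||% rep(1, length(v2_mask))
  tot <- sum(w[v2_mask])
  if (tot <= 0) stop("V2 area must be > 0", call. = FALSE)
  thin <- 100 * sum(w[roiset$thin & v2_mask]) / tot
  thick <- 100 * sum(w[roiset$thick & v2_mask]) / tot
  c(thin = thin, thick = thick, pale = 100 - thin - thick)
}

#' Between-session reliability with a spatial permutation null
#'
#' Spearman rank correlation of two session maps within a mask; the null
#' distribution correlates session one against variogram-matched surrogates
#' of session two, and the (two-sided: "greater or smaller than r")
#' exceedance count is converted with [corrected_pvalue()].
#'
#' @param map1,map2 per-vertex session maps.
#' @param mask logical mask (e.g. V2).
#' @param pairwise_dist distances of the masked vertices (or full patch
#'   distances; subset internally when dimensions require it).
#' @param n number of surrogates.
#' @param seed integer seed.
#' @return object of class `reliability_result`: `r`, `p_corrected`, `n`,
#'   `k`, `null_values`.
#' @export
reliability_correlation <- function(map1, map2, mask, pairwise_dist,
                                    n = 1000, seed = 1L) {
  m1 <- map1[mask]; m2 <- map2[mask]
  D <- if (nrow(pairwise_dist) == length(m1)) pairwise_dist
       else pairwise_dist[mask, mask, drop = FALSE]
  r <- stats::cor(m1, m2, method = "spearman")
  sur <- generate_surrogates(m2, D, n = n, seed = seed)
  rk1 <- rank(m1)
  null_r <- apply(sur$maps, 1, function(s) stats::cor(rk1, rank(s)))
  k <- sum(abs(null_r) >= abs(r))
  structure(list(r = r, n = n, k = k,
                 p_corrected = corrected_pvalue(k, n), null_values = null_r),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("<reliability_result> Spearman r = %.3f, p = %.4g (n = %d surrogates)\n",
              x$r, x$p_corrected, x$n))
  invisible(x)
}
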