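# Shared fixtures and independent oracles, all built in code at test time.

wrapa <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# UV-sphere triangle mesh with outward-oriented faces (analytic-curvature
# oracle surface; mean curvature 1/R everywhere).
sphere_mesh <- function(R = 10, nlat = 24, nlon = 48) {
  th <- seq(0, pi, length.out = nlat)[-c(1, nlat)]
  ph <- seq(0, 2 * pi, length.out = nlon + 1)[-(nlon + 1)]
  V <- cbind(c(outer(sin(th), cos(ph))), c(outer(sin(th), sin(ph))),
             c(outer(cos(th), rep(1, nlon)))) * R
  nla <- length(th)
  idx <- function(i, j) (j - 1L) * nla + i
  tris <- vector("list", 2L * nlon * (nla - 1L) + 2L * nlon)
  k <- 0L
  for (j in 1:nlon) {
    jn <- j %% nlon + 1L
    for (i in 1:(nla - 1L)) {
      tris[[k <- k + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, jn))
      tris[[k <- k + 1L]] <- c(idx(i, j), idx(i + 1L, jn), idx(i, jn))
    }
  }
  np <- nrow(V) + 1L; ns <- nrow(V) + 2L
  V <- rbind(V, c(0, 0, R), c(0, 0, -R))
  for (j in 1:nlon) {
    jn <- j %% nlon + 1L
    tris[[k <- k + 1L]] <- c(np, idx(1L, j), idx(1L, jn))
    tris[[k <- k + 1L]] <- c(ns, idx(nla, jn), idx(nla, j))
  }
  list(coords = V, faces = do.call(rbind, tris))
}

# Exact two-point inversion of the Ernst equation (numerical oracle for the
# rational dual flip angle approximation): solves R1 from the TE = 0 signal
# ratio by bisection, then the amplitude from the PDw signal.
ernst_invert <- function(s_pd, s_t1, protocol, fT = 1) {
  a_pd <- protocol$nominal_fa[["PDw"]] * fT
  a_t1 <- protocol$nominal_fa[["T1w"]] * fT
  tr_pd <- protocol$tr[["PDw"]]; tr_t1 <- protocol$tr[["T1w"]]
  sig <- function(a, tr, r1) {
    e1 <- exp(-tr * r1)
    sin(a) * (1 - e1) / (1 - cos(a) * e1)
  }
  f <- function(r1) s_t1 / s_pd - sig(a_t1, tr_t1, r1) / sig(a_pd, tr_pd, r1)
  r1 <- stats::uniroot(f, c(1e-4, 20), tol = 1e-12)$root
  list(r1 = unname(r1), amplitude_a = unname(s_pd / sig(a_pd, tr_pd, r1)))
}

# Small patch + stripes + analysis-ready cohort used across stripestats and
# surrogate tests (231 vertices, two full stripe cycles).
small_cohort_config <- function(...) {
  defaults <- list(n_subjects = 1L, hemispheres_per_subject = 1L,
                   patch_width = 16, patch_height = 8, patch_spacing = 0.8)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

# Single shared sampler for the small-patch geometry (grid distances are
# identical across hemispheres/cohorts of the same dimensions).
small_patch_sampler <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- generate_patch(16, 8, 0.8, list(type = "zero"))
      cache <<- surrogate_sampler(patch_distances(p))
    }
    cache
  }
})
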