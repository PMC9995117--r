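#' Discrete mean curvature of a triangle mesh
#'
#' Cotangent-Laplacian estimate: the mean-curvature normal at vertex i is
#' `K_i = 1/(2 A_i) * sum_j (cot a_ij + cot b_ij) (x_i - x_j)` over the
#' one-ring (A_i the barycentric vertex area); the returned scalar is
#' `|K_i|` signed by the direction of K relative to the vertex normal, so a
#' sphere triangulated with outward-oriented faces has curvature +1/R and
#' flipping the face orientation flips the sign. A planar mesh gives 0.
#'
#' @param mesh a `cortical_patch` or any list with `coords` (n x 3) and
#'   `faces` (m x 3).
#' @return per-vertex signed mean curvature, mm^-1.
#' @export
mesh_curvature <- function(mesh) {
  V <- mesh$coords; F <- mesh$faces
  if (ncol(V) == 2L) V <- cbind(V, 0)
  n <- nrow(V)

  cross3 <- function(a, b)
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])

  p1 <- V[F[, 1], , drop = FALSE]
  p2 <- V[F[, 2], , drop = FALSE]
  p3 <- V[F[, 3], , drop = FALSE]
  fn <- cross3(p2 - p1, p3 - p1)         # 2 * area * unit normal
  dblA <- sqrt(rowSums(fn^2))
  if (any(dblA <= 0)) stop("degenerate face(s) in mesh", call. = FALSE)

  # cotangent at each corner: cot = dot(e1, e2) / |e1 x e2|
  cot_at <- function(pa, pb, pc) {         # angle at pa between (pb-pa),(pc-pa)
    u <- pb - pa; v <- pc - pa
    rowSums(u * v) / sqrt(rowSums(cross3(u, v)^2))
  }
  c1 <- cot_at(p1, p2, p3)  # opposite edge (2,3)
  c2 <- cot_at(p2, p3, p1)  # opposite edge (3,1)
  c3 <- cot_at(p3, p1, p2)  # opposite edge (1,2)

  K <- matrix(0, n, 3)
  add_edge <- function(K, ia, ib, w) {
    d <- (V[ia, , drop = FALSE] - V[ib, , drop = FALSE]) * w
    for (co in 1:3) {
      K[, co] <- K[, co] + unname(tapply_add(d[, co], ia, n)) -
        unname(tapply_add(d[, co], ib, n))
    }
    K
  }
  K <- add_edge(K, F[, 2], F[, 3], 0.5 * c1)
  K <- add_edge(K, F[, 3], F[, 1], 0.5 * c2)
  K <- add_edge(K, F[, 1], F[, 2], 0.5 * c3)

  A <- vertex_areas(V, F)
  K <- K / (2 * A)

  # vertex normals (area weighted) fix the sign convention
  N <- matrix(0, n, 3)
  for (co in 1:3) {
    N[, co] <- tapply_add(fn[, co], F[, 1], n) +
      tapply_add(fn[, co], F[, 2], n) + tapply_add(fn[, co], F[, 3], n)
  }
  h <- sqrt(rowSums(K^2))
  sgn <- sign(rowSums(K * N))
  sgn[sgn == 0] <- 1
  out <- h * sgn

  # the one-ring of a boundary vertex is incomplete; curvature is undefined
  # there and reported as 0 (open meshes only; closed meshes are unaffected)
  ekey <- c(paste(pmin(F[, 1], F[, 2]), pmax(F[, 1], F[, 2])),
            paste(pmin(F[, 2], F[, 3]), pmax(F[, 2], F[, 3])),
            paste(pmin(F[, 3], F[, 1]), pmax(F[, 3], F[, 1])))
  once <- names(which(table(ekey) == 1L))
  if (length(once)) {
    bv <- unique(as.integer(unlist(strsplit(once, " "))))
    out[bv] <- 0
  }
  out
}

# scatter-add x into a length-n accumulator at indices idx
tapply_add <- function(x, idx, n) {
  out <- numeric(n)
  acc <- tapply(x, idx, sum)
  out[as.integer(names(acc))] <- acc
  out
}

#' Equi-volume cortical depth fraction
#'
#' For a local column whose cross-sectional area varies linearly from the
#' white-matter boundary (area `a_inner`) to the pial boundary (`a_outer`),
#' the depth fraction x enclosing volume fraction `nu` solves
#' `a_inner x + x^2 (a_outer - a_inner)/2 = nu (a_inner + a_outer)/2`,
#' giving the closed form
#' `x = (-a_inner + sqrt((1 - nu) a_inner^2 + nu a_outer^2)) /
#'      (a_outer - a_inner)`.
#' When the areas agree to within a relative tolerance of 1e-9 the
#' equi-distant limit `x = nu` is returned. Vectorized.
#'
#' @param a_inner,a_outer local areas at the white and pial boundary, mm^2
#'   (> 0).
#' @param nu volume fraction in `[0, 1]`; 0 = white boundary.
#' @return depth fraction in `[0, 1]` measured from the white boundary.
#' @export
equivolume_fraction <- function(a_inner, a_outer, nu) {
  if (any(a_inner <= 0) || any(a_outer <= 0))
    stop("areas must be > 0", call. = FALSE)
  if (any(nu < 0 | nu > 1)) stop("nu must lie in [0, 1]", call. = FALSE)
  k <- pmax(length(a_inner), length(a_outer), length(nu))
  aw <- rep_len(a_inner, k); ap <- rep_len(a_outer, k); v <- rep_len(nu, k)
  x <- numeric(k)
  eq <- abs(ap - aw) < 1e-9 * aw
  x[eq] <- v[eq]
  ne <- !eq
  x[ne] <- (-aw[ne] + sqrt((1 - v[ne]) * aw[ne]^2 + v[ne] * ap[ne]^2)) /
    (ap[ne] - aw[ne])
  pmin(pmax(x, 0), 1)
}

#' Surface mesh at an equi-volume cortical depth
#'
#' Interpolates vertex-corresponding inner (white) and outer (pial)
#' boundary surfaces at the per-vertex equi-volume depth fraction for
#' volume fraction `nu`, using barycentric one-ring areas of each boundary
#' surface as the local column areas.
#'
#' @param inner_surface,outer_surface lists with `coords` (n x 3) and
#'   `faces` (m x 3); vertex counts must agree.
#' @param nu volume fraction in `[0, 1]` (0.5 = equi-volume mid-depth).
#' @return list with interpolated `coords`, the shared `faces` and the
#'   per-vertex `depth_fraction`.
#' @export
build_depth_surface <- function(inner_surface, outer_surface, nu = 0.5) {
  Vi <- inner_surface$coords; Vo <- outer_surface$coords
  if (nrow(Vi) != nrow(Vo))
    stop("mismatched vertex counts between surfaces", call. = FALSE)
  aw <- vertex_areas(Vi, inner_surface$faces)
  ap <- vertex_areas(Vo, outer_surface$faces)
  x <- equivolume_fraction(aw, ap, nu)
  list(coords = Vi + x * (Vo - Vi), faces = inner_surface$faces,
       depth_fraction = x)
}

#' Sample a volume onto surface vertices
#'
#' Maps vertex world coordinates into voxel space through the inverse of the
#' volume affine (0-based voxel indices to world, NIfTI RAS convention) and
#' samples nearest-neighbor (default, ties rounded half-down toward the
#' lower index) or trilinearly. Vertices falling outside the volume are
#' flagged invalid and returned as `NA`.
#'
#' @param volume 3D numeric array.
#' @param affine 4 x 4 voxel-to-world matrix (0-based indices).
#' @param vertices n x 3 world coordinates (e.g. `patch$coords`).
#' @param mode `"nearest"` or `"trilinear"`.
#' @return list with `values` (length n, `NA` outside), `valid` (logical)
#'   and `n_invalid`.
#' @export
sample_to_surface <- function(volume, affine, vertices,
                              mode = c("nearest", "trilinear")) {
  mode <- match.arg(mode)
  stopifnot(length(dim(volume)) == 3L, all(dim(affine) == c(4, 4)))
  if (ncol(vertices) == 2L) vertices <- cbind(vertices, 0)
  vox <- t(solve(affine) %*% rbind(t(vertices), 1))[, 1:3, drop = FALSE]
  dm <- dim(volume)
  n <- nrow(vox)
  vals <- rep(NA_real_, n)

  if (mode == "nearest") {
    idx <- ceiling(vox - 0.5)            # round half-down toward lower index
    valid <- idx[, 1] >= 0 & idx[, 1] <= dm[1] - 1 &
             idx[, 2] >= 0 & idx[, 2] <= dm[2] - 1 &
             idx[, 3] >= 0 & idx[, 3] <= dm[3] - 1
    ii <- idx[valid, , drop = FALSE] + 1
    vals[valid] <- volume[cbind(ii[, 1], ii[, 2], ii[, 3])]
  } else {
    lo <- floor(vox)
    fr <- vox - lo
    valid <- lo[, 1] >= 0 & lo[, 1] <= dm[1] - 2 + (fr[, 1] == 0) &
             lo[, 2] >= 0 & lo[, 2] <= dm[2] - 2 + (fr[, 2] == 0) &
             lo[, 3] >= 0 & lo[, 3] <= dm[3] - 2 + (fr[, 3] == 0) &
             vox[, 1] <= dm[1] - 1 & vox[, 2] <= dm[2] - 1 &
             vox[, 3] <= dm[3] - 1
    lv <- lo[valid, , drop = FALSE]
    fv <- fr[valid, , drop = FALSE]
    hi <- pmin(lv + 1, matrix(dm - 1, nrow(lv), 3, byrow = TRUE))
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) fv[, 1] else 1 - fv[, 1]) *
           (if (dy) fv[, 2] else 1 - fv[, 2]) *
           (if (dz) fv[, 3] else 1 - fv[, 3])
      cx <- if (dx) hi[, 1] else lv[, 1]
      cy <- if (dy) hi[, 2] else lv[, 2]
      cz <- if (dz) hi[, 3] else lv[, 3]
      acc <- acc + w * volume[cbind(cx + 1, cy + 1, cz + 1)]
    }
    vals[valid] <- acc
  }
  list(values = vals, valid = valid, n_invalid = sum(!valid))
}
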