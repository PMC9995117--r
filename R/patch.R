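#' Synthetic flattened cortical patch
#'
#' Builds a regular triangulated 2D grid standing in for a flattened V2
#' patch. All downstream stripe analysis operates on per-vertex maps over
#' this geometry. Distances on the flat patch are Euclidean and used as
#' geodesic distances.
#'
#' @param width_mm,height_mm patch extent in mm.
#' @param spacing_mm grid spacing in mm (vertex edge length).
#' @param curvature_field_spec description of the per-vertex mean-curvature
#'   field (mm^-1). A list with `type` one of `"zero"`, `"grf"` (smooth
#'   Gaussian random field; fields `sd` in mm^-1 and `corr_length` in mm) or
#'   `"sinusoid"` (analytic folding pattern; fields `amplitude` in mm^-1 and
#'   `wavelength` in mm).
#' @param seed integer seed; identical arguments give bit-identical patches.
#' @return An object of class `cortical_patch`: list with `coords` (n x 3,
#'   z = 0), `faces` (m x 3 vertex indices), `vertex_area` (mm^2, barycentric
#'   one-ring share), `curvature` (mm^-1), `v2_mask` (logical), grid shape
#'   `nx`, `ny` and `spacing`.
#' @export
generate_patch <- function(width_mm, height_mm, spacing_mm,
                           curvature_field_spec = list(type = "grf", sd = 0.15,
                                                       corr_length = 5),
                           seed = 1L) {
  stop_if_not_scalar_pos(width_mm, "width_mm")
  stop_if_not_scalar_pos(height_mm, "height_mm")
  stop_if_not_scalar_pos(spacing_mm, "spacing_mm")
  if (spacing_mm > width_mm || spacing_mm > height_mm)
    stop("`spacing_mm` must not exceed the patch dimensions", call. = FALSE)

  xs <- seq(0, width_mm, by = spacing_mm)
  ys <- seq(0, height_mm, by = spacing_mm)
  nx <- length(xs); ny <- length(ys)
  coords <- cbind(x = rep(xs, times = ny), y = rep(ys, each = nx), z = 0)
  n <- nx * ny

  faces <- grid_faces(nx, ny)
  area <- vertex_areas(coords, faces)

  curvature <- curvature_field(coords, nx, ny, spacing_mm,
                               curvature_field_spec, seed)

  structure(list(coords = coords, faces = faces, vertex_area = area,
                 curvature = curvature, v2_mask = rep(TRUE, n),
                 nx = nx, ny = ny, spacing = spacing_mm),
            class = "cortical_patch")
}

# Two triangles per grid cell, counter-clockwise in the xy plane.
grid_faces <- function(nx, ny) {
  ix <- rep(seq_len(nx - 1L), times = ny - 1L)
  iy <- rep(seq_len(ny - 1L), each = nx - 1L)
  v00 <- (iy - 1L) * nx + ix
  v10 <- v00 + 1L
  v01 <- v00 + nx
  v11 <- v01 + 1L
  rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
}

# Barycentric vertex areas: one third of each incident triangle.
vertex_areas <- function(coords, faces) {
  p1 <- coords[faces[, 1], , drop = FALSE]
  p2 <- coords[faces[, 2], , drop = FALSE]
  p3 <- coords[faces[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  fa <- 0.5 * sqrt(rowSums(cr^2))
  a <- numeric(nrow(coords))
  for (k in 1:3) {
    acc <- tapply(fa, faces[, k], sum)
    idx <- as.integer(names(acc))
    a[idx] <- a[idx] + acc
  }
  a / 3
}

curvature_field <- function(coords, nx, ny, spacing, spec, seed) {
  type <- spec$type %||% "zero"
  switch(type,
    zero = rep(0, nrow(coords)),
    grf = {
      sd <- spec$sd %||% 0.15
      cl <- spec$corr_length %||% 5
      as.vector(grf_grid(nx, ny, spacing, cl, child_seed(seed, 101))) * sd
    },
    sinusoid = {
      amp <- spec$amplitude %||% 0.15
      wl <- spec$wavelength %||% 10
      amp * sin(2 * pi * coords[, 1] / wl) * cos(2 * pi * coords[, 2] / wl)
    },
    stop("unknown curvature_field_spec type: ", type, call. = FALSE)
  )
}

#' Smooth Gaussian random field on a regular grid
#'
#' White noise spectrally filtered with a Gaussian kernel (periodic
#' convolution via FFT) and rescaled to unit variance. The kernel standard
#' deviation is `corr_length / 2`, so the autocorrelation falls to 1/e at a
#' lag of `corr_length` mm.
#'
#' @param nx,ny grid dimensions (columns are x).
#' @param spacing grid spacing in mm.
#' @param corr_length correlation length in mm; 0 gives white noise.
#' @param seed integer seed.
#' @return nx x ny matrix with (population) zero mean and unit variance.
#' @export
grf_grid <- function(nx, ny, spacing, corr_length, seed) {
  z <- with_seed(seed, matrix(stats::rnorm(nx * ny), nx, ny))
  if (corr_length <= 0) return(z)
  s <- corr_length / 2 / spacing  # kernel sd in grid units
  kx <- gauss_kernel_1d(nx, s)
  ky <- gauss_kernel_1d(ny, s)
  K <- outer(kx, ky)
  Fz <- stats::fft(z) * stats::fft(K)
  sm <- Re(stats::fft(Fz, inverse = TRUE)) / (nx * ny)
  # normalization: variance of the filtered field is sum(K^2) * var(noise)
  sm / sqrt(sum(K^2))
}

gauss_kernel_1d <- function(n, s) {
  d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  k <- exp(-0.5 * (d / s)^2)
  k / 1  # unnormalized; joint normalization happens on the 2D kernel energy
}

#' Pairwise Euclidean vertex distances of a patch
#'
#' Computed on demand (the full matrix is O(n^2) memory and only the
#' surrogate machinery needs it).
#'
#' @param patch a `cortical_patch`.
#' @return symmetric n x n distance matrix in mm with zero diagonal.
#' @export
patch_distances <- function(patch) {
  as.matrix(stats::dist(patch$coords))
}

#' @export
print.cortical_patch <- function(x, ...) {
  cat(sprintf("<cortical_patch> %d vertices (%d x %d grid, %.2f mm spacing), %d faces\n",
              nrow(x$coords), x$nx, x$ny, x$spacing, nrow(x$faces)))
  cat(sprintf("  curvature sd %.3f mm^-1; V2 mask: %d vertices\n",
              stats::sd(x$curvature), sum(x$v2_mask)))
  invisible(x)
}

# Evaluate code under a temporary RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}
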