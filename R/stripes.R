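#' Ground-truth stripe labels for a synthetic patch
#'
#' Tiles the patch with periodic pale-thin-pale-thick cycles, emulating the
#' cytochrome-oxidase stripe layout of V2. Default widths are the macaque
#' values doubled (human stripes are about twice as wide): 8 mm
#' center-to-center cycle, 2.0 mm thin and 2.6 mm thick stripes, the two pale
#' bands sharing the remaining width equally.
#'
#' Labels are assigned from the vertex coordinate along the tiling axis
#' modulo `cycle_width`; half-open intervals `[start, end)` decide boundary
#' vertices. `orientation` is the angle (radians) of the tiling axis relative
#' to the patch x-axis, so with the default 0 the stripes run parallel to the
#' patch height, i.e. perpendicular to a V1/V2 border placed along y.
#'
#' @param patch a `cortical_patch`.
#' @param cycle_width,thin_width,thick_width stripe geometry in mm.
#' @param orientation tiling-axis angle in radians.
#' @return An object of class `stripe_model`: list with `labels` (factor with
#'   levels pale/thin/thick), the widths and orientation.
#' @export
generate_stripe_labels <- function(patch, cycle_width = 8.0, thin_width = 2.0,
                                   thick_width = 2.6, orientation = 0) {
  stop_if_not_scalar_pos(cycle_width, "cycle_width")
  stop_if_not_scalar_pos(thin_width, "thin_width")
  stop_if_not_scalar_pos(thick_width, "thick_width")
  if (thin_width + thick_width >= cycle_width)
    stop("thin_width + thick_width must be smaller than cycle_width",
         call. = FALSE)

  pale_half <- (cycle_width - thin_width - thick_width) / 2
  u <- patch$coords[, 1] * cos(orientation) + patch$coords[, 2] * sin(orientation)
  pos <- u %% cycle_width
  lab <- rep("pale", length(pos))
  lab[pos >= pale_half & pos < pale_half + thin_width] <- "thin"
  lab[pos >= 2 * pale_half + thin_width] <- "thick"
  structure(list(labels = factor(lab, levels = c("pale", "thin", "thick")),
                 cycle_width = cycle_width, thin_width = thin_width,
                 thick_width = thick_width, orientation = orientation),
            class = "stripe_model")
}

#' Area-weighted stripe label fractions within V2
#'
#' @param patch a `cortical_patch`.
#' @param stripes a `stripe_model`.
#' @return named numeric vector (pale, thin, thick) summing to 1.
#' @export
stripe_area_fractions <- function(patch, stripes) {
  w <- patch$vertex_area[patch$v2_mask]
  l <- stripes$labels[patch$v2_mask]
  tot <- sum(w)
  vapply(levels(l), function(lv) sum(w[l == lv]) / tot, numeric(1))
}

#' @export
print.stripe_model <- function(x, ...) {
  cat(sprintf("<stripe_model> cycle %.1f mm (thin %.1f, thick %.1f, 2 x pale %.1f), orientation %.2f rad\n",
              x$cycle_width, x$thin_width, x$thick_width,
              (x$cycle_width - x$thin_width - x$thick_width) / 2, x$orientation))
  print(table(x$labels))
  invisible(x)
}
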