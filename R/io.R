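#' Per-vertex map I/O (CSV)
#'
#' Per-vertex surface maps travel as plain CSV with one row per vertex and
#' one column per map, the interchange format used for cohort export.
#'
#' @param maps named list (or data.frame) of per-vertex vectors.
#' @param path CSV path.
#' @return `write_vertex_maps` the path invisibly; `read_vertex_maps` a
#'   data.frame.
#' @export
write_vertex_maps <- function(maps, path) {
  utils::write.csv(as.data.frame(maps), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vertex_maps
#' @export
read_vertex_maps <- function(path) {
  utils::read.csv(path)
}

#' Export a simulated cohort to disk
#'
#' One directory per subject/hemisphere containing `maps.csv` (activation
#' averages, session maps, qMRI parameters, curvature, V2 mask),
#' `mesh.csv` (vertex coordinates and areas, plus a face list
#' `faces.csv`) and the config echo `config.yaml`.
#'
#' @param cohort a `stripe_cohort`.
#' @param dir target directory.
#' @return the directory invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cohort$config), file.path(dir, "config.yaml"),
                   precision = 15)
  for (h in cohort$hemispheres) {
    hd <- file.path(dir, sprintf("sub-%02d_hemi-%d", h$subject, h$hemi))
    dir.create(hd, showWarnings = FALSE)
    maps <- data.frame(color = h$color, disparity = h$disparity,
                       r1 = h$qmri$r1, r2s = h$qmri$r2s, pd = h$qmri$pd,
                       mtvf = h$qmri$mtvf,
                       curvature = h$patch$curvature,
                       v2_mask = h$patch$v2_mask,
                       stripe_label = as.character(h$stripes$labels))
    for (s in seq_len(ncol(h$color_sessions))) {
      maps[[sprintf("color_ses%d", s)]] <- h$color_sessions[, s]
      maps[[sprintf("disparity_ses%d", s)]] <- h$disp_sessions[, s]
    }
    write_vertex_maps(maps, file.path(hd, "maps.csv"))
    utils::write.csv(data.frame(x = h$patch$coords[, 1],
                                y = h$patch$coords[, 2],
                                z = h$patch$coords[, 3],
                                area = h$patch$vertex_area),
                     file.path(hd, "mesh.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(h$patch$faces),
                     file.path(hd, "faces.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Multi-echo FLASH signals as NIfTI
#'
#' Writes the echo stack of one contrast as a 4D NIfTI volume (echoes along
#' the fourth dimension) for interoperability with volumetric relaxometry
#' tools, and reads it back.
#'
#' @param signals a `multi_echo_signals` object.
#' @param contrast `"PDw"` or `"T1w"`.
#' @param dim3 spatial dimensions to fold the location axis into (product
#'   must equal the number of locations).
#' @param path NIfTI path (`.nii`).
#' @return the path invisibly / a `[contrast, echo, location]`-compatible
#'   array.
#' @export
write_flash_nifti <- function(signals, contrast, dim3, path) {
  sig <- signals$signal[contrast, , , drop = TRUE]  # echo x location
  ne <- nrow(sig)
  stopifnot(prod(dim3) == ncol(sig))
  arr <- array(t(sig), c(dim3, ne))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' @rdname write_flash_nifti
#' @export
read_flash_nifti <- function(path) {
  arr <- RNifti::readNifti(path)
  d <- dim(arr)
  ne <- d[length(d)]
  matrix(arr, ncol = ne)  # location x echo
}
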