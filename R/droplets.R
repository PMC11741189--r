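#' Configuration for the lipid-droplet segmentation pipeline
#'
#' @param rolling_ball_radius radius in pixels of the rolling-ball background
#'   correction (default 50).
#' @param blur_sigma Gaussian sigma in pixels of the low-pass filter used to
#'   build the difference image (default 4).
#' @param threshold fixed manual threshold, in intensity units, applied to
#'   the 32-float difference image (default 3).
#' @param connectivity particle connectivity, 4 or 8 (default 8).
#' @param min_area_px minimum particle size in pixels (default 1: no size
#'   filter, matching a workflow with no stated size gate).
#' @return A `DropletConfig` list.
#' @export
droplet_config <- function(rolling_ball_radius = 50, blur_sigma = 4,
                           threshold = 3, connectivity = 8L,
                           min_area_px = 1L) {
  stopifnot(rolling_ball_radius >= 1, blur_sigma > 0, threshold > 0,
            min_area_px >= 1)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  structure(list(rolling_ball_radius = rolling_ball_radius,
                 blur_sigma = blur_sigma, threshold = threshold,
                 connectivity = connectivity,
                 min_area_px = as.integer(min_area_px)),
            class = "DropletConfig")
}

#' Segment lipid droplets in a BODIPY channel
#'
#' Runs the fixed sequence: cast to the 16-bit intensity range (8-bit input
#' is rescaled by 257; 16-bit input passes through), rolling-ball background
#' subtraction to remove hazy autofluorescence, difference-of-Gaussian
#' enhancement (corrected image minus its Gaussian-blurred copy, kept as a
#' signed 32-float image), fixed manual threshold, and connected-component
#' particle analysis. Touching droplets are not split — the workflow has no
#' watershed step — so well-separated droplets are a precondition for
#' count-accurate results.
#'
#' @param bodipy single-plane BODIPY [image_plane()].
#' @param cfg a [droplet_config()].
#' @param field_id identifier carried into the result.
#' @return A `DropletSegmentation`: list with `mask` ([binary_mask()]),
#'   `particles` (`ParticleTable`), `config_used`, `field_id`.
#' @export
segment_droplets <- function(bodipy, cfg = droplet_config(),
                             field_id = "field") {
  bodipy <- as_image_plane(bodipy)
  img <- bodipy
  if (img$bit_depth == 8L) {
    img$pixels <- img$pixels * 257
    img$bit_depth <- 16L
  }
  corrected <- subtract_rolling_ball(img, cfg$rolling_ball_radius)
  diff <- subtract_images(corrected, gaussian_blur(corrected, cfg$blur_sigma))
  mask <- apply_threshold(diff, cfg$threshold)
  particles <- connected_particles(mask, connectivity = cfg$connectivity,
                                   min_area_px = cfg$min_area_px)
  structure(list(mask = mask, particles = particles, config_used = cfg,
                 field_id = field_id),
            class = "DropletSegmentation")
}

#' @export
print.DropletSegmentation <- function(x, ...) {
  cat(sprintf("<DropletSegmentation> field '%s': %d particles, %d fg px\n",
              x$field_id, nrow(x$particles), sum(x$mask$pixels)))
  invisible(x)
}

#' Field-level mean droplet size
#'
#' Arithmetic mean of the per-particle areas of one field, reported both as
#' area (um^2) and as mean equivalent circular diameter (um). A field with
#' no particles yields an explicit `no_particles` status with `NA` values,
#' never a silent zero.
#'
#' @param seg a [segment_droplets()] result.
#' @return List with `n_particles`, `mean_area_um2`, `mean_area_px`,
#'   `mean_equiv_diam_um`, and `status` (`"ok"` or `"no_particles"`).
#' @export
mean_droplet_area <- function(seg) {
  stopifnot(inherits(seg, "DropletSegmentation"))
  p <- seg$particles
  if (nrow(p) == 0L)
    return(list(n_particles = 0L, mean_area_um2 = NA_real_,
                mean_area_px = NA_real_, mean_equiv_diam_um = NA_real_,
                status = "no_particles"))
  list(n_particles = nrow(p),
       mean_area_um2 = mean(p$area_um2),
       mean_area_px = mean(p$area_px),
       mean_equiv_diam_um = mean(p$equiv_diam_um),
       status = "ok")
}
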