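#' Configuration for the nuclei-counting pipeline
#'
#' Holds the DAPI pre-processing parameters (flat background subtraction and
#' Gaussian low-pass, applied in that order) and the blob-detector settings.
#'
#' @param background_value flat intensity offset removed from the DAPI
#'   channel (default 50).
#' @param blur_sigma Gaussian sigma in pixels for the low-pass filter
#'   (default 4).
#' @param min_separation_um minimum centre-to-centre distance between
#'   detections in micrometres (default 6; a typical murine nucleus is
#'   8-12 um across, so this suppresses double detections within one
#'   nucleus).
#' @param nucleus_radius_um expected nucleus radius in micrometres, which
#'   sets the detection scale of the blob filter (default 5).
#' @param detection `"log_blobs"` (Laplacian-of-Gaussian via a
#'   difference-of-Gaussian approximation, the default) — kept as a named
#'   method so alternatives can be added.
#' @param intensity_floor `"otsu"` to derive the minimum blob intensity from
#'   the preprocessed image by Otsu's method (default), or a fixed number
#'   for degenerate histograms.
#' @return A `NucleiConfig` list.
#' @export
nuclei_config <- function(background_value = 50, blur_sigma = 4,
                          min_separation_um = 6, nucleus_radius_um = 5,
                          detection = "log_blobs", intensity_floor = "otsu") {
  stopifnot(background_value >= 0, blur_sigma > 0, min_separation_um > 0,
            nucleus_radius_um > 0)
  detection <- match.arg(detection, "log_blobs")
  if (!(identical(intensity_floor, "otsu") ||
        (is.numeric(intensity_floor) && length(intensity_floor) == 1L)))
    stop('`intensity_floor` must be "otsu" or a single number', call. = FALSE)
  structure(list(background_value = background_value, blur_sigma = blur_sigma,
                 min_separation_um = min_separation_um,
                 nucleus_radius_um = nucleus_radius_um,
                 detection = detection, intensity_floor = intensity_floor),
            class = "NucleiConfig")
}

#' Pre-process the DAPI channel for nuclei segmentation
#'
#' Subtracts a flat background value, then applies a Gaussian low-pass
#' filter — in that fixed order.
#'
#' @param img DAPI-channel [image_plane()].
#' @param cfg a [nuclei_config()].
#' @return A smoothed, background-corrected `ImagePlane`.
#' @export
preprocess_dapi <- function(img, cfg = nuclei_config()) {
  gaussian_blur(subtract_constant(img, cfg$background_value), cfg$blur_sigma)
}

# Otsu threshold of a numeric matrix (EBImage::otsu works on [0,1] data).
otsu_floor <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi <= lo) return(Inf)   # constant image: nothing can pass the floor
  t01 <- EBImage::otsu(EBImage::Image((m - lo) / (hi - lo)), range = c(0, 1))
  lo + t01 * (hi - lo)
}

#' Detect nuclei in a preprocessed DAPI image
#'
#' Classical blob detection standing in for interactive deep-learning
#' nucleus counters: a difference-of-Gaussian (scale-space) filter tuned to
#' the expected nucleus radius, followed by regional-maximum extraction and
#' greedy non-maximum suppression at the configured minimum separation.
#' Detections must exceed an intensity floor (Otsu by default) on the
#' preprocessed image. Deterministic for fixed input and configuration;
#' nuclei touching the image border are counted.
#'
#' @param img output of [preprocess_dapi()].
#' @param cfg a [nuclei_config()].
#' @param field_id identifier carried into the result.
#' @return A `NucleusSet`: list with `nuclei` (data frame: `nucleus_id`,
#'   `row`, `col`, `est_radius_um`), `count`, and `field_id`.
#' @export
detect_nuclei <- function(img, cfg = nuclei_config(), field_id = "field") {
  img <- as_image_plane(img)
  m <- img$pixels
  px <- img$pixel_size
  empty <- function() nucleus_set(data.frame(
    nucleus_id = integer(), row = numeric(), col = numeric(),
    est_radius_um = numeric()), field_id)
  if (max(m) <= min(m)) return(empty())

  # Two-scale DoG approximation of LoG blob detection. The input has
  # already been blurred by cfg$blur_sigma, so each blur only tops up to
  # its target scale. The blur chain sigma_b/1.6, sigma_b, 1.6*sigma_b
  # yields a fine DoG (detects nuclei well below the nominal radius, which
  # would otherwise ride as shoulders on a larger neighbour's response)
  # and a base DoG, combined by pointwise maximum; matched blobs respond
  # comparably at their own scale, so no extra normalisation is needed.
  sigma_b <- (cfg$nucleus_radius_um / 2) / px
  top_up <- function(target) {
    extra <- sqrt(max(target^2 - cfg$blur_sigma^2, 0.25))
    blur_matrix(m, extra)
  }
  b0 <- top_up(sigma_b / 1.6)
  b1 <- top_up(sigma_b)
  b2 <- top_up(1.6 * sigma_b)
  resp <- pmax(b0 - b1, b1 - b2)

  # The floor's job is to reject background ripple, not to bound nucleus
  # interiors: Otsu partitions the image, and the floor is set well above
  # the background class (mean + 8 sd), never below 2% of the image max.
  # Otsu's threshold itself would clip dim small-radius nuclei whose
  # blurred peaks fall near it.
  floor_val <- if (identical(cfg$intensity_floor, "otsu")) {
    split <- otsu_floor(m)
    bgpx <- m[m < split]
    if (!length(bgpx)) split
    else max(mean(bgpx) + 8 * stats::sd(bgpx), 0.02 * max(m), na.rm = TRUE)
  } else cfg$intensity_floor
  sep_px <- cfg$min_separation_um / px
  k <- max(1L, as.integer(floor(sep_px)))
  brush <- EBImage::makeBrush(2L * k + 1L, shape = "disc")
  local_max <- EBImage::dilate(pad_reflect(resp, k), brush)
  local_max <- local_max[(k + 1L):(k + nrow(m)), (k + 1L):(k + ncol(m))]
  cand <- which(resp >= local_max & resp > 1e-9 * max(resp) & m >= floor_val)
  if (!length(cand)) return(empty())

  nr <- nrow(m)
  r <- ((cand - 1L) %% nr) + 1L
  co <- ((cand - 1L) %/% nr) + 1L
  v <- resp[cand]
  ord <- order(-v, r, co)   # by response, ties broken by position
  r <- r[ord]; co <- co[ord]
  keep <- logical(length(r))
  kr <- numeric(0); kc <- numeric(0)
  for (i in seq_along(r)) {
    if (!length(kr) || min((kr - r[i])^2 + (kc - co[i])^2) >= sep_px^2) {
      keep[i] <- TRUE
      kr <- c(kr, r[i]); kc <- c(kc, co[i])
    }
  }
  d <- data.frame(row = r[keep], col = co[keep])
  d <- d[order(d$row, d$col), , drop = FALSE]
  d <- data.frame(nucleus_id = seq_len(nrow(d)), row = d$row, col = d$col,
                  est_radius_um = sqrt(2) * sigma_b * px)
  nucleus_set(d, field_id)
}

#' Assemble a NucleusSet
#'
#' @param nuclei data frame with columns `nucleus_id`, `row`, `col`,
#'   `est_radius_um`.
#' @param field_id field identifier.
#' @return A `NucleusSet` list with elements `nuclei`, `count`, `field_id`.
#' @export
nucleus_set <- function(nuclei, field_id = "field") {
  stopifnot(is.data.frame(nuclei),
            all(c("nucleus_id", "row", "col", "est_radius_um") %in%
                  names(nuclei)))
  structure(list(nuclei = nuclei, count = nrow(nuclei), field_id = field_id),
            class = "NucleusSet")
}

#' @export
print.NucleusSet <- function(x, ...) {
  cat(sprintf("<NucleusSet> field '%s': %d nuclei\n", x$field_id, x$count))
  invisible(x)
}

#' Count nuclei in a raw DAPI field
#'
#' Convenience wrapper: [preprocess_dapi()] then [detect_nuclei()].
#'
#' @inheritParams detect_nuclei
#' @param img raw DAPI [image_plane()].
#' @return A `NucleusSet`.
#' @export
count_nuclei <- function(img, cfg = nuclei_config(), field_id = "field") {
  detect_nuclei(preprocess_dapi(img, cfg), cfg, field_id)
}
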