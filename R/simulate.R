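#' Parameters of the synthetic two-channel field generator
#'
#' Describes one 20x confocal-like field of an adherent adipogenic culture:
#' DAPI-stained Gaussian-profile nuclei, a configurable fraction of cells
#' bearing rings of bright circular BODIPY lipid droplets, a hazy smooth
#' autofluorescence background, and sensor noise (Poisson shot noise plus
#' Gaussian read noise, then quantization).
#'
#' Intensities occupy an 8-bit-like range inside a 16-bit container,
#' emulating 8-bit confocal acquisitions converted to 16-bit — the regime in
#' which a fixed manual threshold of 3 on a difference image is a meaningful
#' operating point (it sits several noise standard deviations above the
#' background).
#'
#' @param width,height field size in pixels.
#' @param pixel_size micrometres per pixel (default 0.31, typical of a 20x
#'   confocal field).
#' @param bit_depth output container depth (default 16).
#' @param n_cells number of cells (nuclei) in the field.
#' @param differentiated_fraction fraction of cells that are adipocytes
#'   (droplet-bearing); the realized count is `round(fraction * n_cells)`.
#' @param nucleus_radius_um_mean,nucleus_radius_um_sd normal distribution of
#'   nucleus radii in micrometres.
#' @param placement `"lattice"` (jittered triangular lattice, modelling
#'   contact inhibition in a confluent monolayer; the default) or
#'   `"random"` (sequential random placement with a minimum
#'   centre-distance).
#' @param lattice_jitter_frac jitter standard deviation as a fraction of the
#'   lattice pitch (lattice placement).
#' @param min_center_factor for random placement, minimum centre distance
#'   between two nuclei as a multiple of the sum of their radii; 1 means no
#'   overlap, 0.9 allows up to ~10 percent overlap.
#' @param droplets_per_adipocyte_mean Poisson mean droplet count per
#'   adipocyte (default 12).
#' @param droplets_min minimum droplets per adipocyte (default 3).
#' @param droplet_diam_um_median,droplet_diam_um_sdlog lognormal droplet
#'   diameter distribution (micrometres).
#' @param droplet_diam_um_range hard truncation range of droplet diameters.
#' @param droplet_annulus_um inner and outer radius (micrometres) of the
#'   annulus around the nucleus centre in which droplets are placed.
#' @param droplet_min_gap_px minimum edge-to-edge gap between any two
#'   droplets in pixels (default 4; the segmentation does not split touching
#'   droplets).
#' @param dapi_background,nucleus_amplitude DAPI background level and peak
#'   nucleus intensity above background.
#' @param bodipy_background,droplet_amplitude BODIPY base level and droplet
#'   intensity above background.
#' @param haze_fraction amplitude of the smooth autofluorescence haze as a
#'   fraction of `droplet_amplitude` (default 0.15).
#' @param haze_scale_px spatial scale of the haze field (default 150,
#'   comfortably broader than twice the rolling-ball radius so background
#'   correction can remove it).
#' @param shot_noise_gain intensity units per photon-equivalent: shot-noise
#'   variance at intensity I is `gain * I` (default 0.008). The default puts
#'   the background noise floor, even over the haze, more than four standard
#'   deviations below the fixed difference-image threshold of 3 — the regime
#'   a fixed manual threshold presumes (heavily line-averaged acquisition of
#'   fixed samples).
#' @param read_noise_sd Gaussian read-noise standard deviation (default 0.4).
#' @param cell_radius_um nominal cell radius used for ground-truth per-cell
#'   regions (default 15).
#' @param n_debris number of irregular, low-circularity debris blobs added
#'   to the BODIPY channel (default 0) to exercise the circularity
#'   criterion.
#' @param seed RNG seed; fixed seed gives bit-identical fields.
#' @return A `SimParams` list.
#' @export
sim_params <- function(width = 1024L, height = 1024L, pixel_size = 0.31,
                       bit_depth = 16L, n_cells = 150L,
                       differentiated_fraction = 0.4,
                       nucleus_radius_um_mean = 5,
                       nucleus_radius_um_sd = 0.8,
                       placement = c("lattice", "random"),
                       lattice_jitter_frac = 0.015,
                       min_center_factor = 1.0,
                       droplets_per_adipocyte_mean = 12,
                       droplets_min = 3L,
                       droplet_diam_um_median = 3,
                       droplet_diam_um_sdlog = 0.3,
                       droplet_diam_um_range = c(1, 6),
                       droplet_annulus_um = c(6, 14),
                       droplet_min_gap_px = 4,
                       dapi_background = 40, nucleus_amplitude = 160,
                       bodipy_background = 8, droplet_amplitude = 120,
                       haze_fraction = 0.15, haze_scale_px = 150,
                       shot_noise_gain = 0.008, read_noise_sd = 0.4,
                       cell_radius_um = 15, n_debris = 0L, seed = 1L) {
  placement <- match.arg(placement)
  stopifnot(width >= 64, height >= 64, pixel_size > 0,
            differentiated_fraction >= 0, differentiated_fraction <= 1,
            n_cells >= 0, nucleus_radius_um_mean > 0,
            droplets_per_adipocyte_mean > 0, droplets_min >= 0,
            droplet_diam_um_median > 0, length(droplet_annulus_um) == 2L,
            droplet_annulus_um[1] < droplet_annulus_um[2],
            droplet_min_gap_px >= 0, haze_fraction >= 0,
            shot_noise_gain >= 0, read_noise_sd >= 0, cell_radius_um > 0)
  p <- as.list(environment())
  structure(p, class = "SimParams")
}

# Predicted background intensity standard deviation (shot + read +
# quantization) and the droplet peak-to-background-sd ratio implied by a
# parameter set.
#' Predicted signal-to-noise ratio of a parameter set
#'
#' Droplet amplitude divided by the predicted background intensity standard
#' deviation (shot noise at the background level, read noise, and the
#' 1/12-variance quantization term).
#'
#' @param p a [sim_params()].
#' @return List with `background_sd` and `snr`.
#' @export
sim_snr <- function(p) {
  v <- p$shot_noise_gain * p$bodipy_background + p$read_noise_sd^2 + 1 / 12
  list(background_sd = sqrt(v), snr = p$droplet_amplitude / sqrt(v))
}

# -- placement ---------------------------------------------------------------

place_nuclei_lattice <- function(p) {
  area <- p$width * p$height
  pitch0 <- sqrt(2 * area / (sqrt(3) * p$n_cells))  # hex pitch at density n/A
  margin <- 10
  # place at the full exclusion pitch when a centred lattice yields enough
  # sites; shrink only as far as needed otherwise
  for (shrink in 0.99^(0:40)) {
    pitch <- pitch0 * shrink
    jit <- p$lattice_jitter_frac * pitch
    row_sp <- pitch * sqrt(3) / 2
    n_rows <- floor((p$height - 2 * margin) / row_sp) + 1
    r0 <- (p$height - (n_rows - 1) * row_sp) / 2
    rows <- r0 + (seq_len(n_rows) - 1) * row_sp
    c0 <- ((p$width - 2 * margin) %% pitch) / 2 + margin
    pts <- do.call(rbind, lapply(seq_along(rows), function(i) {
      off <- if (i %% 2 == 0) pitch / 2 else 0
      cols <- seq(c0 + off - pitch, p$width, by = pitch)
      cols <- cols[cols >= margin & cols <= p$width - margin]
      cbind(rows[i], cols)
    }))
    if (nrow(pts) >= p$n_cells) break
  }
  base <- pts
  pts <- base + matrix(stats::rnorm(length(base), 0, jit), nrow(base))
  # contact inhibition is a hard constraint, not a tendency: re-draw the
  # jitter of any site that lands closer than 0.95 * pitch to another
  min_sep <- 0.97 * pitch
  for (pass in 1:25) {
    d <- as.matrix(stats::dist(pts)); diag(d) <- Inf
    bad <- which(apply(d, 1, min) < min_sep)
    if (!length(bad)) break
    pts[bad, ] <- base[bad, ] +
      matrix(stats::rnorm(2L * length(bad), 0, jit), length(bad))
  }
  margin <- 2
  ok <- pts[, 1] > margin & pts[, 1] < p$height - margin &
        pts[, 2] > margin & pts[, 2] < p$width - margin
  pts <- pts[ok, , drop = FALSE]
  if (nrow(pts) < p$n_cells)
    stop("placement failure: lattice produced too few sites", call. = FALSE)
  pts[sample.int(nrow(pts), p$n_cells), , drop = FALSE]
}

place_nuclei_random <- function(p, radii_px) {
  n <- p$n_cells
  rs <- cs <- numeric(0)
  max_tries <- 2000L
  for (i in seq_len(n)) {
    placed <- FALSE
    for (k in seq_len(max_tries)) {
      rr <- stats::runif(1, radii_px[i] + 1, p$height - radii_px[i] - 1)
      cc <- stats::runif(1, radii_px[i] + 1, p$width - radii_px[i] - 1)
      if (!length(rs) ||
          all(sqrt((rs - rr)^2 + (cs - cc)^2) >=
                p$min_center_factor * (radii_px[seq_along(rs)] + radii_px[i]))) {
        rs <- c(rs, rr); cs <- c(cs, cc); placed <- TRUE; break
      }
    }
    if (!placed)
      stop(sprintf("placement failure: could not place nucleus %d of %d",
                   i, n), call. = FALSE)
  }
  cbind(rs, cs)
}

# -- rendering ---------------------------------------------------------------

# Local pixel window around (r0, c0) with half-extent `ext`.
local_window <- function(r0, c0, ext, h, w) {
  list(r = max(1L, floor(r0 - ext)):min(h, ceiling(r0 + ext)),
       c = max(1L, floor(c0 - ext)):min(w, ceiling(c0 + ext)))
}

# Irregular blob: union of several overlapping small discs along a random
# walk; low circularity by construction.
render_debris <- function(img, r0, c0, amp, n_steps = 8L, step = 4, rad = 2.5) {
  rr <- r0; cc <- c0
  for (s in seq_len(n_steps)) {
    ang <- stats::runif(1, 0, 2 * pi)
    rr <- rr + step * sin(ang); cc <- cc + step * cos(ang)
    ext <- ceiling(rad + 1)
    r <- max(1L, floor(rr - ext)):min(nrow(img), ceiling(rr + ext))
    c <- max(1L, floor(cc - ext)):min(ncol(img), ceiling(cc + ext))
    d <- sqrt(outer((r - rr)^2, (c - cc)^2, "+"))
    img[r, c] <- pmax(img[r, c], amp * pmin(pmax(rad + 0.5 - d, 0), 1))
  }
  img
}

# Smooth haze: coarse Gaussian random grid upsampled bilinearly, rescaled to
# [0, 1].
render_haze <- function(h, w, scale_px) {
  k <- max(3L, ceiling(max(h, w) / scale_px) + 2L)
  coarse <- matrix(stats::rnorm(k * k), k, k)
  f <- EBImage::resize(coarse, w = h, h = w, filter = "bilinear")
  f <- blur_matrix(f, scale_px / 6)
  (f - min(f)) / max(max(f) - min(f), .Machine$double.eps)
}

apply_noise <- function(m, p) {
  n <- length(m)
  out <- m
  if (p$shot_noise_gain > 0) {
    lam <- pmax(m, 0) / p$shot_noise_gain
    out <- stats::rpois(n, lam) * p$shot_noise_gain
  }
  if (p$read_noise_sd > 0) out <- out + stats::rnorm(n, 0, p$read_noise_sd)
  out <- round(out)
  matrix(pmin(pmax(out, 0), 2^p$bit_depth - 1), nrow(m), ncol(m))
}

#' Generate one synthetic two-channel field with ground truth
#'
#' Renders the DAPI and BODIPY channels described by `p` and returns, with
#' them, the complete ground truth: every nucleus (centre, radius,
#' adipocyte status, true per-cell lipid content computed on the true
#' droplet mask), every droplet (owner, centre, radius, rendered pixel
#' area), and the noiseless droplet mask itself. Deterministic given
#' `p$seed`.
#'
#' @param p a [sim_params()].
#' @param field_id identifier attached to the returned planes and truth.
#' @return List with `dapi` and `bodipy` ([image_plane()]s) and `truth`
#'   (class `FieldGroundTruth`): `cells`, `droplets` data frames,
#'   `droplet_mask`, counts and `true_fraction`.
#' @export
generate_field <- function(p = sim_params(), field_id = "field") {
  stopifnot(inherits(p, "SimParams"))
  with_seed(p$seed, {
    h <- p$height; w <- p$width; px <- p$pixel_size
    rad_um <- pmax(stats::rnorm(p$n_cells, p$nucleus_radius_um_mean,
                                p$nucleus_radius_um_sd), 1)
    rad_px <- rad_um / px
    centers <- if (p$n_cells == 0L) {
      matrix(numeric(0), 0, 2)
    } else if (p$placement == "lattice") {
      place_nuclei_lattice(p)
    } else {
      place_nuclei_random(p, rad_px)
    }

    n_adipo <- round(p$differentiated_fraction * p$n_cells)
    is_adipo <- rep(FALSE, p$n_cells)
    if (n_adipo > 0L) is_adipo[sample.int(p$n_cells, n_adipo)] <- TRUE

    # --- DAPI channel (rendering is done in place: no helper calls, so the
    # full-frame matrices are never copied per object) ---
    dapi <- matrix(p$dapi_background, h, w)
    for (i in seq_len(p$n_cells)) {
      sg <- rad_px[i] / 2
      win <- local_window(centers[i, 1], centers[i, 2], ceiling(3.5 * sg), h, w)
      dapi[win$r, win$c] <- dapi[win$r, win$c] + p$nucleus_amplitude *
        exp(-outer((win$r - centers[i, 1])^2, (win$c - centers[i, 2])^2, "+") /
              (2 * sg^2))
    }

    # --- BODIPY channel: droplets ---
    bodipy <- matrix(p$bodipy_background, h, w)
    if (p$haze_fraction > 0)
      bodipy <- bodipy + p$haze_fraction * p$droplet_amplitude *
        render_haze(h, w, p$haze_scale_px)
    droplet_mask <- matrix(FALSE, h, w)
    drops <- list()
    all_r <- all_c <- all_rad <- numeric(0)
    ann <- p$droplet_annulus_um / px
    for (i in which(is_adipo)) {
      n_d <- max(p$droplets_min, stats::rpois(1, p$droplets_per_adipocyte_mean))
      placed <- 0L
      for (j in seq_len(n_d)) {
        diam_um <- Inf
        while (diam_um < p$droplet_diam_um_range[1] ||
               diam_um > p$droplet_diam_um_range[2])
          diam_um <- stats::rlnorm(1, log(p$droplet_diam_um_median),
                                   p$droplet_diam_um_sdlog)
        drad <- (diam_um / 2) / px
        for (try in seq_len(200L)) {
          # uniform in radius, not in area: droplets nucleate perinuclearly,
          # so density falls off toward the annulus rim
          rr <- stats::runif(1, ann[1], ann[2])
          th <- stats::runif(1, 0, 2 * pi)
          dr <- centers[i, 1] + rr * sin(th)
          dc <- centers[i, 2] + rr * cos(th)
          if (dr - drad < 1 || dr + drad > h || dc - drad < 1 || dc + drad > w)
            next
          if (length(all_r) &&
              any(sqrt((all_r - dr)^2 + (all_c - dc)^2) <
                    all_rad + drad + p$droplet_min_gap_px))
            next
          win <- local_window(dr, dc, ceiling(drad + 1), h, w)
          d2 <- sqrt(outer((win$r - dr)^2, (win$c - dc)^2, "+"))
          bodipy[win$r, win$c] <- bodipy[win$r, win$c] +
            p$droplet_amplitude * pmin(pmax(drad + 0.5 - d2, 0), 1)
          inside <- d2 <= drad
          droplet_mask[win$r, win$c] <- droplet_mask[win$r, win$c] | inside
          all_r <- c(all_r, dr); all_c <- c(all_c, dc)
          all_rad <- c(all_rad, drad)
          drops[[length(drops) + 1L]] <-
            data.frame(cell_id = i, row = dr, col = dc, radius_px = drad,
                       radius_um = drad * px, area_px = sum(inside))
          placed <- placed + 1L
          break
        }
      }
      if (placed < p$droplets_min)
        stop(sprintf("placement failure: cell %d holds %d droplet(s), need >= %d",
                     i, placed, p$droplets_min), call. = FALSE)
    }
    if (p$n_debris > 0L)
      for (k in seq_len(p$n_debris))
        bodipy <- render_debris(bodipy, stats::runif(1, 20, h - 20),
                                stats::runif(1, 20, w - 20),
                                amp = 0.5 * p$droplet_amplitude)

    droplets <- if (length(drops)) {
      d <- do.call(rbind, drops)
      d <- cbind(droplet_id = seq_len(nrow(d)), d)
      d
    } else {
      data.frame(droplet_id = integer(), cell_id = integer(), row = numeric(),
                 col = numeric(), radius_px = numeric(), radius_um = numeric(),
                 area_px = integer())
    }

    # --- true per-cell lipid content on the noiseless droplet mask ---
    content <- rep(NA_real_, p$n_cells)
    cr_px <- p$cell_radius_um / px
    for (i in seq_len(p$n_cells)) {
      win <- local_window(centers[i, 1], centers[i, 2], ceiling(cr_px), h, w)
      disk <- outer((win$r - centers[i, 1])^2, (win$c - centers[i, 2])^2,
                    "+") <= cr_px^2
      content[i] <- 100 * sum(droplet_mask[win$r, win$c] & disk) / sum(disk)
    }

    cells <- data.frame(
      cell_id = seq_len(p$n_cells),
      row = centers[, 1], col = centers[, 2],
      nucleus_radius_um = rad_um[seq_len(p$n_cells)],
      is_adipocyte = is_adipo,
      true_lipid_content_pct = content)

    truth <- structure(list(
      cells = cells, droplets = droplets, droplet_mask = droplet_mask,
      n_cells = p$n_cells, n_adipocytes = sum(is_adipo),
      true_fraction = if (p$n_cells > 0) sum(is_adipo) / p$n_cells else NA_real_,
      field_id = field_id), class = "FieldGroundTruth")

    list(
      dapi = image_plane(apply_noise(dapi, p), pixel_size = px,
                         bit_depth = p$bit_depth),
      bodipy = image_plane(apply_noise(bodipy, p), pixel_size = px,
                           bit_depth = p$bit_depth),
      truth = truth)
  })
}

#' @export
print.FieldGroundTruth <- function(x, ...) {
  cat(sprintf("<FieldGroundTruth> field '%s': %d cells (%d adipocytes), %d droplets\n",
              x$field_id, x$n_cells, x$n_adipocytes, nrow(x$droplets)))
  invisible(x)
}

#' Write a synthetic multi-condition dataset to disk
#'
#' For each condition and field, writes `{field}_dapi.tif`,
#' `{field}_bodipy.tif`, `{field}_cells.csv` and `{field}_droplets.csv`
#' (ground truth), plus a `manifest.json` listing every field with its
#' condition and derived seed. Per-field seeds are derived deterministically
#' from `base_seed`, so the same call reproduces identical bytes.
#'
#' @param conditions named list: condition label -> [sim_params()].
#' @param fields_per_condition number of fields per condition (>= 1).
#' @param base_seed integer master seed.
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
generate_dataset <- function(conditions, fields_per_condition = 3L,
                             base_seed = 1L, out_dir) {
  stopifnot(is.list(conditions), length(names(conditions)) == length(conditions),
            fields_per_condition >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(base_seed = base_seed, fields = list())
  idx <- 0L
  for (label in names(conditions)) {
    p <- conditions[[label]]
    for (f in seq_len(fields_per_condition)) {
      idx <- idx + 1L
      field_id <- sprintf("%s_f%02d", gsub("[^A-Za-z0-9_-]", "_", label), f)
      p$seed <- (base_seed + 7919L * idx) %% 2147483647L
      fld <- generate_field(p, field_id = field_id)
      paths <- list(
        dapi = file.path(out_dir, paste0(field_id, "_dapi.tif")),
        bodipy = file.path(out_dir, paste0(field_id, "_bodipy.tif")),
        cells = file.path(out_dir, paste0(field_id, "_cells.csv")),
        droplets = file.path(out_dir, paste0(field_id, "_droplets.csv")))
      write_image_plane(fld$dapi, paths$dapi)
      write_image_plane(fld$bodipy, paths$bodipy)
      utils::write.csv(fld$truth$cells, paths$cells, row.names = FALSE)
      utils::write.csv(fld$truth$droplets, paths$droplets, row.names = FALSE)
      manifest$fields[[field_id]] <- list(
        field_id = field_id, condition = label, seed = p$seed,
        pixel_size = p$pixel_size,
        dapi = basename(paths$dapi), bodipy = basename(paths$bodipy),
        cells = basename(paths$cells), droplets = basename(paths$droplets))
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
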