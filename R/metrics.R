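#' Rule for calling a cell an adipocyte
#'
#' Automated surrogate for the manual judgment that a cell is an adipocyte
#' when distinct, circular lipid droplets surround its nucleus: a nucleus is
#' classified as an adipocyte if at least `min_droplets` segmented particles
#' have centroids within `search_radius_um` of the nucleus centroid and the
#' mean circularity of those particles is at least `min_circularity` (which
#' rejects hazy, irregular signal).
#'
#' @param search_radius_um search radius around the nucleus centroid in
#'   micrometres (default 15).
#' @param min_droplets minimum number of nearby droplets (default 3).
#' @param min_circularity minimum mean circularity of the nearby droplets,
#'   in `[0, 1]` (default 0.6).
#' @return An `AdipocyteRule` list.
#' @export
adipocyte_rule <- function(search_radius_um = 15, min_droplets = 3L,
                           min_circularity = 0.6) {
  stopifnot(search_radius_um > 0, min_droplets >= 1,
            min_circularity >= 0, min_circularity <= 1)
  structure(list(search_radius_um = search_radius_um,
                 min_droplets = as.integer(min_droplets),
                 min_circularity = min_circularity),
            class = "AdipocyteRule")
}

#' Classify each nucleus as adipocyte or not
#'
#' Applies an [adipocyte_rule()] independently to every nucleus; droplets
#' may count toward several nearby nuclei (there is no droplet-to-cell
#' assignment step).
#'
#' @param nuclei a `NucleusSet`.
#' @param seg a `DropletSegmentation` from the same field.
#' @param rule an [adipocyte_rule()].
#' @return Data frame of cell records: `nucleus_id`, `row`, `col`,
#'   `n_droplets_near`, `mean_circ_near`, `is_adipocyte`.
#' @export
classify_adipocytes <- function(nuclei, seg, rule = adipocyte_rule()) {
  stopifnot(inherits(nuclei, "NucleusSet"),
            inherits(seg, "DropletSegmentation"))
  if (!identical(nuclei$field_id, seg$field_id))
    stop(sprintf("field id mismatch: nuclei '%s' vs segmentation '%s'",
                 nuclei$field_id, seg$field_id), call. = FALSE)
  px <- seg$mask$pixel_size
  nd <- nuclei$nuclei
  p <- seg$particles
  r_px <- rule$search_radius_um / px
  n_near <- integer(nrow(nd)); mean_circ <- rep(NA_real_, nrow(nd))
  if (nrow(p) > 0L && nrow(nd) > 0L) {
    for (i in seq_len(nrow(nd))) {
      d2 <- (p$row - nd$row[i])^2 + (p$col - nd$col[i])^2
      near <- d2 <= r_px^2
      n_near[i] <- sum(near)
      if (n_near[i] > 0L) mean_circ[i] <- mean(p$circularity[near])
    }
  }
  is_adipo <- n_near >= rule$min_droplets &
    !is.na(mean_circ) & mean_circ >= rule$min_circularity
  data.frame(nucleus_id = nd$nucleus_id, row = nd$row, col = nd$col,
             n_droplets_near = n_near, mean_circ_near = mean_circ,
             is_adipocyte = is_adipo)
}

#' Differentiation efficiency of one field
#'
#' Number of cells classified as adipocytes divided by the total number of
#' cells in the field.
#'
#' @param records cell records from [classify_adipocytes()].
#' @return Fraction in `[0, 1]`; errors on an empty record list ("no cells").
#' @export
differentiation_efficiency <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("no cells: cannot compute differentiation efficiency", call. = FALSE)
  mean(records$is_adipocyte)
}

# Region index 1..5 for a centroid: 1 TL, 2 TR, 3 BL, 4 BR, 5 centre.
# The centred square claims area HW/5; the four corner quadrants share the
# rest. This is one concrete reading of "five image quadrants (top
# left/right, bottom left/right, center)".
region_of <- function(row, col, h, w) {
  side_r <- h / sqrt(5); side_c <- w / sqrt(5)   # centre square, area HW/5
  in_centre <- abs(row - (h + 1) / 2) <= side_r / 2 &
               abs(col - (w + 1) / 2) <= side_c / 2
  top <- row <= h / 2; left <- col <= w / 2
  reg <- ifelse(top & left, 1L, ifelse(top & !left, 2L,
                ifelse(!top & left, 3L, 4L)))
  ifelse(in_centre, 5L, reg)
}

region_centres <- function(h, w) {
  rbind(c(h / 4, w / 4), c(h / 4, 3 * w / 4),
        c(3 * h / 4, w / 4), c(3 * h / 4, 3 * w / 4),
        c(h / 2, w / 2))
}

#' Randomly sample cells, one per image region
#'
#' Emulates picking one nucleus from each of five image regions (top-left,
#' top-right, bottom-left, bottom-right, centre): the field is partitioned
#' into four corner quadrants plus an equal-area centred square, and one
#' uniformly random unsampled nucleus is drawn from each region in turn.
#' A region with no (remaining) nuclei falls back to the unsampled nucleus
#' nearest to that region's centre. Deterministic given `seed`.
#'
#' @param nuclei a `NucleusSet`.
#' @param shape integer `c(height, width)` of the field in pixels.
#' @param n number of cells to sample (default 5).
#' @param seed RNG seed for the draw (default 0).
#' @return Integer vector of selected `nucleus_id`s (length `min(n, count)`).
#' @export
sample_cells <- function(nuclei, shape, n = 5L, seed = 0L) {
  stopifnot(inherits(nuclei, "NucleusSet"), length(shape) == 2L)
  nd <- nuclei$nuclei
  if (nrow(nd) < n) {
    warning(sprintf("field '%s': only %d nuclei for requested n = %d; returning all",
                    nuclei$field_id, nrow(nd), n))
    return(nd$nucleus_id)
  }
  h <- shape[1]; w <- shape[2]
  reg <- region_of(nd$row, nd$col, h, w)
  centres <- region_centres(h, w)
  with_seed(seed, {
    chosen <- integer(0)
    for (i in seq_len(n)) {
      target <- ((i - 1L) %% 5L) + 1L
      avail <- which(reg == target & !(nd$nucleus_id %in% chosen))
      if (length(avail)) {
        pick <- if (length(avail) == 1L) avail else sample(avail, 1L)
      } else {
        rest <- which(!(nd$nucleus_id %in% chosen))
        d2 <- (nd$row[rest] - centres[target, 1])^2 +
              (nd$col[rest] - centres[target, 2])^2
        pick <- rest[which.min(d2)]
      }
      chosen <- c(chosen, nd$nucleus_id[pick])
    }
    chosen
  })
}

#' Per-cell lipid content
#'
#' Percent of a cell region covered by segmented droplet pixels: 100 times
#' the droplet-mask area inside the region divided by the region area.
#'
#' @param cell_region either a [binary_mask()] of the cell, or a list
#'   `list(center = c(row, col), radius_um = r)` describing a disk region.
#' @param seg a `DropletSegmentation`.
#' @return Percent in `[0, 100]`.
#' @export
cell_lipid_content <- function(cell_region, seg) {
  stopifnot(inherits(seg, "DropletSegmentation"))
  mask <- seg$mask
  region <- cell_region_mask(cell_region, dim(mask$pixels), mask$pixel_size)
  area <- sum(region)
  if (area == 0L) stop("cell region has zero area", call. = FALSE)
  100 * sum(mask$pixels & region) / area
}

# Rasterize a cell region spec (BinaryMask or disk) to a logical matrix,
# cropped to the field.
cell_region_mask <- function(cell_region, shape, pixel_size) {
  if (inherits(cell_region, "BinaryMask")) {
    if (!identical(dim(cell_region$pixels), as.integer(shape)))
      stop("cell region shape mismatch", call. = FALSE)
    return(cell_region$pixels)
  }
  if (is.list(cell_region) && !is.null(cell_region$center) &&
      !is.null(cell_region$radius_um)) {
    r_px <- cell_region$radius_um / pixel_size
    if (r_px <= 0) stop("cell region has zero area", call. = FALSE)
    rows <- seq_len(shape[1]); cols <- seq_len(shape[2])
    dr2 <- (rows - cell_region$center[1])^2
    dc2 <- (cols - cell_region$center[2])^2
    return(outer(dr2, dc2, "+") <= r_px^2)
  }
  stop("`cell_region` must be a BinaryMask or list(center=, radius_um=)",
       call. = FALSE)
}

#' Assemble per-field metrics
#'
#' Combines the nuclei count, adipocyte classification, mean droplet size
#' and mean per-cell lipid content over the sampled cells into one record.
#' When no explicit cell outlines exist, each sampled cell's region is a
#' disk of `cell_radius_um` around its nucleus.
#'
#' @param nuclei a `NucleusSet`.
#' @param seg a `DropletSegmentation` from the same field.
#' @param records cell records from [classify_adipocytes()].
#' @param sampled_ids nucleus ids from [sample_cells()].
#' @param cell_radius_um disk radius used as the cell region when no traced
#'   outline is available (default 15).
#' @return A `FieldMetrics` data frame row: `field_id`, `n_nuclei`,
#'   `n_adipocytes`, `differentiation_efficiency`, `n_particles`,
#'   `mean_droplet_area_um2`, `mean_equiv_diam_um`, `mean_lipid_content_pct`.
#' @export
field_metrics <- function(nuclei, seg, records, sampled_ids,
                          cell_radius_um = 15) {
  stopifnot(inherits(nuclei, "NucleusSet"),
            inherits(seg, "DropletSegmentation"))
  eff <- if (nrow(records)) differentiation_efficiency(records) else NA_real_
  size <- mean_droplet_area(seg)
  nd <- nuclei$nuclei
  contents <- vapply(sampled_ids, function(id) {
    i <- match(id, nd$nucleus_id)
    cell_lipid_content(list(center = c(nd$row[i], nd$col[i]),
                            radius_um = cell_radius_um), seg)
  }, numeric(1))
  data.frame(field_id = nuclei$field_id,
             n_nuclei = nuclei$count,
             n_adipocytes = sum(records$is_adipocyte),
             differentiation_efficiency = eff,
             n_particles = size$n_particles,
             mean_droplet_area_um2 = size$mean_area_um2,
             mean_equiv_diam_um = size$mean_equiv_diam_um,
             mean_lipid_content_pct = if (length(contents)) mean(contents)
                                      else NA_real_)
}

#' Aggregate field metrics for one condition
#'
#' Mean and standard error of the mean (sd/sqrt(n)) of every metric across
#' the fields of a condition. Warns when fewer than three fields are
#' provided, the conventional minimum of repeated imaging per condition.
#'
#' @param fields data frame of [field_metrics()] rows.
#' @param label condition label.
#' @return A `ConditionSummary` data frame: `condition`, `metric`, `mean`,
#'   `sem`, `n_fields`.
#' @export
summarize_condition <- function(fields, label) {
  if (!is.data.frame(fields) || nrow(fields) == 0L)
    stop("no fields to summarize", call. = FALSE)
  if (nrow(fields) < 3L)
    warning(sprintf("condition '%s': only %d field(s); at least 3 recommended",
                    label, nrow(fields)))
  metrics <- c("n_nuclei", "n_adipocytes", "differentiation_efficiency",
               "n_particles", "mean_droplet_area_um2", "mean_equiv_diam_um",
               "mean_lipid_content_pct")
  metrics <- intersect(metrics, names(fields))
  out <- do.call(rbind, lapply(metrics, function(mt) {
    x <- fields[[mt]]
    data.frame(condition = label, metric = mt,
               mean = mean(x, na.rm = TRUE), sem = sem(x),
               n_fields = sum(is.finite(x)))
  }))
  rownames(out) <- NULL
  out
}
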