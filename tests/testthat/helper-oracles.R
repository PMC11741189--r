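# Independent oracles and fixture builders used across the test files.

# Shift a matrix by (dr, dc), padding vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Brute-force flood-fill labelling by iterative minimum-label propagation:
# every foreground pixel starts with its own label (its linear index) and
# repeatedly adopts the smallest label among its neighbours until nothing
# changes. Deliberately naive and independent of the graph-based
# implementation under test.
oracle_components <- function(mask, connectivity = 8L) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- which(mask)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  repeat {
    new <- lab
    for (s in shifts) {
      nb <- shift_mat(lab, s[1], s[2])
      upd <- mask & nb > 0L
      new[upd] <- pmin(new[upd], nb[upd])
    }
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- lab[mask]
  areas <- if (length(ids)) sort(as.integer(table(ids))) else integer(0)
  list(n = length(areas), areas = areas)
}

# Brute-force grayscale opening (min filter then max filter) with a disc
# element and reflective borders — the rolling-ball background oracle.
oracle_opening <- function(m, radius) {
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  ref <- function(i, n) {                       # symmetric reflection index
    j <- (i - 1) %% (2 * n); ifelse(j < n, j + 1, 2 * n - j)
  }
  filt <- function(x, f) {
    out <- matrix(if (identical(f, pmin)) Inf else -Inf, nrow(x), ncol(x))
    for (k in seq_len(nrow(offs))) {
      ri <- ref(seq_len(nrow(x)) + offs$dr[k], nrow(x))
      ci <- ref(seq_len(ncol(x)) + offs$dc[k], ncol(x))
      out <- f(out, x[ri, ci, drop = FALSE])
    }
    out
  }
  filt(filt(m, pmin), pmax)
}

# Rasterized centred disk mask / image.
disk_mask <- function(n, r, center = c((n + 1) / 2, (n + 1) / 2)) {
  outer((seq_len(n) - center[1])^2, (seq_len(n) - center[2])^2, "+") <= r^2
}

const_plane <- function(value, n = 64, pixel_size = 0.31, bit_depth = 16L) {
  image_plane(matrix(value, n, n), pixel_size = pixel_size,
              bit_depth = bit_depth)
}

# A small DAPI-like field: Gaussian nuclei (sd = radius/2) at given centres
# on a flat background.
dapi_field <- function(n, centers, radius_px = 16, background = 40,
                       amplitude = 160, pixel_size = 0.31) {
  m <- matrix(background, n, n)
  sg <- radius_px / 2
  for (i in seq_len(nrow(centers))) {
    m <- m + amplitude * exp(-outer((seq_len(n) - centers[i, 1])^2,
                                    (seq_len(n) - centers[i, 2])^2, "+") /
                               (2 * sg^2))
  }
  image_plane(pmin(round(m), 65535), pixel_size = pixel_size, bit_depth = 16L)
}

# Small simulated field parameter sets used by several test files: density
# matched to the default study (one cell per ~6700 um^2).
small_sim <- function(..., n = 512L, n_cells = 32L) {
  sim_params(width = n, height = n, n_cells = n_cells, ...)
}
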