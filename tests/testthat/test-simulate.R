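test_that("degenerate parameter sets render correctly", {
  p0 <- small_sim(n_cells = 0L, seed = 1)
  fld <- generate_field(p0, "empty")
  expect_equal(fld$truth$n_cells, 0L)
  expect_equal(nrow(fld$truth$droplets), 0L)
  # DAPI is background + noise only
  expect_lt(abs(mean(fld$dapi$pixels) - 40), 1)
  expect_lt(sd(as.vector(fld$dapi$pixels)), 3)
  # forced full differentiation
  p1 <- small_sim(n_cells = 20L, differentiated_fraction = 1, seed = 2)
  t1 <- generate_field(p1, "all")$truth
  expect_equal(t1$n_adipocytes, 20L)
  expect_true(all(t1$cells$is_adipocyte))
  expect_equal(t1$true_fraction, 1)
})

test_that("fields are bit-identical under a fixed seed", {
  p <- small_sim(seed = 77)
  a <- generate_field(p, "f"); b <- generate_field(p, "f")
  expect_identical(a$dapi$pixels, b$dapi$pixels)
  expect_identical(a$bodipy$pixels, b$bodipy$pixels)
  expect_identical(a$truth$cells, b$truth$cells)
  p2 <- small_sim(seed = 78)
  expect_false(identical(generate_field(p2, "f")$bodipy$pixels,
                         a$bodipy$pixels))
})

test_that("ground truth is consistent with the rendered droplet mask", {
  fld <- generate_field(small_sim(seed = 12), "tc")
  truth <- fld$truth
  # droplets are pairwise separated, so labelling the noiseless mask must
  # recover exactly the recorded per-droplet areas
  pt <- connected_particles(binary_mask(truth$droplet_mask, 0.31))
  expect_equal(nrow(pt), nrow(truth$droplets))
  expect_equal(sort(pt$area_px), sort(truth$droplets$area_px))
  expect_equal(truth$n_adipocytes, sum(truth$cells$is_adipocyte))
  expect_equal(truth$true_fraction, truth$n_adipocytes / truth$n_cells)
  # per-cell truth content recomputed from the mask matches
  i <- which(truth$cells$is_adipocyte)[1]
  region <- outer((seq_len(512) - truth$cells$row[i])^2,
                  (seq_len(512) - truth$cells$col[i])^2, "+") <=
    (15 / 0.31)^2
  expect_equal(truth$cells$true_lipid_content_pct[i],
               100 * sum(truth$droplet_mask & region) / sum(region))
  # minimum edge-to-edge droplet spacing is honoured
  td <- truth$droplets
  if (nrow(td) > 1) {
    D <- as.matrix(dist(td[, c("row", "col")])); diag(D) <- Inf
    gap <- D - outer(td$radius_px, td$radius_px, "+")
    expect_gte(min(gap), 4)
  }
})

test_that("rendered droplet diameters track the configured distribution", {
  sizes <- numeric(0)
  for (s in 1:3) {
    fld <- generate_field(sim_params(n_cells = 60L, seed = 100 + s), "d")
    sizes <- c(sizes, 2 * fld$truth$droplets$radius_um)
  }
  expect_gte(length(sizes), 300)
  # lognormal(median 3, sdlog 0.3) truncated to [1, 6]: mean within 5% of
  # the median parameter
  expect_lt(abs(mean(sizes) - 3) / 3, 0.05)
})

test_that("measured background noise matches the stated SNR within 10%", {
  p <- small_sim(haze_fraction = 0, differentiated_fraction = 0, n_cells = 0L,
                 seed = 55)
  fld <- generate_field(p, "snr")
  measured_sd <- sd(as.vector(fld$bodipy$pixels))
  pred <- sim_snr(p)
  expect_lt(abs(measured_sd - pred$background_sd) / pred$background_sd, 0.10)
  expect_gte(pred$snr, 5)
})

test_that("infeasible placements raise an explicit error", {
  p <- small_sim(n = 64L, n_cells = 60L, seed = 9)
  expect_error(generate_field(p, "x"), "placement failure")
})

test_that("datasets on disk are complete and seed-reproducible", {
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  d3 <- file.path(tempdir(), "ds3")
  conds <- list(expansion = small_sim(n_cells = 10L,
                                      differentiated_fraction = 0),
                adipogenic = small_sim(n_cells = 10L,
                                       differentiated_fraction = 0.5))
  m <- generate_dataset(conds, fields_per_condition = 3L, base_seed = 4,
                        out_dir = d1)
  expect_equal(length(m$fields), 6L)
  expect_equal(length(list.files(d1, pattern = "_dapi.tif$")), 6L)
  expect_equal(length(list.files(d1, pattern = "_cells.csv$")), 6L)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  generate_dataset(conds, fields_per_condition = 3L, base_seed = 4,
                   out_dir = d2)
  f1 <- list.files(d1, full.names = TRUE); f2 <- list.files(d2, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  generate_dataset(conds, fields_per_condition = 3L, base_seed = 5,
                   out_dir = d3)
  tif1 <- file.path(d1, basename(f1)[grepl("bodipy", basename(f1))][1])
  tif3 <- file.path(d3, basename(tif1))
  expect_false(identical(unname(tools::md5sum(tif1)),
                         unname(tools::md5sum(tif3))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})
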