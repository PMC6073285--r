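# Small 3D geometry used throughout: 10 x 128 x 128 voxels at the study's
# anisotropic spacing.
small3d <- function(...) {
  do.call(synthetic_params,
          utils::modifyList(list(image_shape = c(10L, 128L, 128L),
                                 voxel_size = c(1, 0.785, 0.785),
                                 n_nmjs = 5L),
                            list(...)))
}

test_that("apposition gaps honour the configured range and far bound", {
  p <- small3d(n_nmjs = 10L, image_shape = c(10L, 256L, 256L),
               positivity_fraction = 1, apposition_gap_um = c(0.1, 0.5),
               seed = 5L)
  tr <- generate_geometry(p)
  expect_equal(nrow(tr$nmj), 10L)
  expect_true(all(tr$nmj$positive))
  expect_true(all(tr$nmj$true_gap_um >= 0.1 & tr$nmj$true_gap_um <= 0.5))

  p0 <- small3d(positivity_fraction = 0, seed = 5L)
  tr0 <- generate_geometry(p0)
  expect_true(all(!tr0$nmj$positive))
  expect_true(all(tr0$nmj$true_gap_um >= p0$far_gap_um))
})

test_that("generation and rendering are reproducible under a fixed seed", {
  p <- small3d(seed = 9L)
  t1 <- generate_geometry(p)
  t2 <- generate_geometry(p)
  expect_identical(t1$nmj, t2$nmj)
  expect_identical(t1$plaque_markers, t2$plaque_markers)
  v1 <- render_volume(t1, p)
  v2 <- render_volume(t2, p)
  expect_identical(v1$data, v2$data)
})

test_that("positive assignment uses deterministic rounding of fraction x n", {
  p <- synthetic_params(image_shape = c(1L, 512L, 512L), n_nmjs = 20L,
                        positivity_fraction = 0.40, seed = 2L)
  tr <- generate_geometry(p)
  expect_equal(sum(tr$nmj$positive), 8L)  # round(0.40 * 20)
  # monotone in the fraction (up to rounding), fixed n and seed
  counts <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    pf <- synthetic_params(image_shape = c(1L, 512L, 512L), n_nmjs = 20L,
                           positivity_fraction = f, seed = 2L)
    sum(generate_geometry(pf)$nmj$positive)
  }, numeric(1))
  expect_equal(counts, round(c(0, 0.25, 0.5, 0.75, 1) * 20))
  expect_true(all(diff(counts) >= 0))
})

test_that("noise-free, blur-free rendering places exact intensities", {
  p <- synthetic_params(image_shape = c(1L, 256L, 256L), n_nmjs = 3L,
                        positivity_fraction = 1, psf_sigma_um = 0,
                        poisson_scale = 0, gaussian_sd = 0, seed = 4L)
  tr <- generate_geometry(p)
  vol <- render_volume(tr, p)
  bgt <- get_channel(vol, "BGT")
  # voxel containing each plaque centre carries the configured intensity
  for (i in seq_len(nrow(tr$nmj))) {
    iy <- round(tr$nmj$y_um[i] / p$voxel_size[2] + 0.5)
    ix <- round(tr$nmj$x_um[i] / p$voxel_size[3] + 0.5)
    expect_equal(bgt[1, iy, ix], 200L)
  }
  expect_equal(max(bgt), 200L)
})

test_that("truth masks derive from geometry only, not from noise settings", {
  p1 <- small3d(seed = 6L, gaussian_sd = 2)
  p2 <- small3d(seed = 6L, gaussian_sd = 4)
  m1 <- truth_masks(generate_geometry(p1))
  m2 <- truth_masks(generate_geometry(p2))
  expect_identical(m1$postsynapse, m2$postsynapse)
  expect_identical(m1$marker, m2$marker)
})

test_that("rasterized masks agree with the analytic gap to within a voxel diagonal", {
  for (seed in c(1L, 8L, 21L)) {
    p <- small3d(n_nmjs = 3L, positivity_fraction = 1,
                 apposition_gap_um = c(0, 2), seed = seed)
    tr <- generate_geometry(p)
    m <- truth_masks(tr)
    post <- label_components(m$postsynapse, 26, p$voxel_size)
    mark <- label_components(m$marker, 26, p$voxel_size)
    rec <- nearest_marker(post, mark)
    diag_um <- voxel_diagonal(p$voxel_size)
    # map each detected object to the closest truth NMJ via bbox centres
    for (k in seq_len(nrow(rec))) {
      ob <- post$objects[k, ]
      cy <- (ob$y0 + ob$y1) / 2 * p$voxel_size[2]
      cx <- (ob$x0 + ob$x1) / 2 * p$voxel_size[3]
      i <- which.min((tr$nmj$y_um - cy)^2 + (tr$nmj$x_um - cx)^2)
      expect_lt(abs(rec$distance_um[k] - tr$nmj$true_gap_um[i]), diag_um)
    }
  }
})

test_that("timecourse defaults follow the configured developmental fractions", {
  expect_equal(positivity_default("TH", "P0"), 0.40)
  expect_equal(positivity_default("TH", "adult"), 0.90)
  expect_equal(positivity_default("VAChT", "P0"), 0.95)
  expect_equal(positivity_default("VAChT", "adult"), 0.95)
  expect_error(positivity_default("GFAP", "P0"),
               class = "nmjquant_config_error")
  expect_error(positivity_default("TH", "P3"),
               class = "nmjquant_config_error")

  sets <- generate_timecourse(c("P0", "adult"), "TH", seed = 3L,
                              base_params = list(n_nmjs = 20L))
  fr <- vapply(sets, function(s) mean(s$truth$nmj$positive), numeric(1))
  expect_equal(unname(fr), c(round(0.40 * 20), round(0.90 * 20)) / 20)
  expect_s3_class(sets$P0$volume, "volume_image")
  expect_equal(sets$P0$volume$channel_names, c("BGT", "TH"))
})

test_that("infeasible packing raises a placement error", {
  p <- synthetic_params(image_shape = c(10L, 48L, 48L), n_nmjs = 40L,
                        seed = 1L)
  expect_error(generate_geometry(p), class = "nmjquant_placement_error")
})
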