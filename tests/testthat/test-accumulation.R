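test_that("median filter matches window medians with edge replication", {
  m <- matrix(1:9, 3, 3, byrow = TRUE)
  expect_equal(median_filter(m, 1)[2, 2], 5)

  z <- matrix(0, 9, 9); z[5, 5] <- 255
  f <- median_filter(z, 1)
  expect_equal(f[5, 5], 0)  # median of 8 zeros and one 255

  cst <- matrix(7, 6, 6)
  expect_equal(median_filter(cst, 1), cst)
  expect_equal(median_filter(cst, 0), cst)  # radius 0 is identity

  set.seed(11)
  for (r in 1:2) {
    img <- matrix(sample(0:255, 16 * 16, replace = TRUE), 16, 16)
    expect_equal(median_filter(img, r), oracle_median(img, r))
  }
})

test_that("ROI extraction thresholds inclusively and applies the area cutoff", {
  cfg <- accumulation_config()
  z <- matrix(0, 32, 32)
  expect_length(extract_nmj_rois(z, cfg)$rois, 0L)

  one <- matrix(0, 32, 32); one[10:15, 10:15] <- 200
  rois <- extract_nmj_rois(one, cfg)
  expect_length(rois$rois, 1L)
  expect_equal(rois$rois[[1]]$area, 36L)

  # threshold lower bound is inclusive at 30
  at30 <- matrix(0, 32, 32); at30[5:10, 5:10] <- 30
  expect_length(extract_nmj_rois(at30, cfg)$rois, 1L)
  at29 <- matrix(0, 32, 32); at29[5:10, 5:10] <- 29
  expect_length(extract_nmj_rois(at29, cfg)$rois, 0L)

  # two 10-px blocks below the 20-px area cutoff
  two <- matrix(0, 32, 32)
  two[2:6, 2:3] <- 200   # 10 px
  two[20:24, 20:21] <- 200
  expect_length(extract_nmj_rois(two, cfg)$rois, 0L)

  # deterministic centroid ordering (y, then x)
  many <- matrix(0, 64, 64)
  many[40:45, 5:10] <- 200
  many[5:10, 40:45] <- 200
  rois <- extract_nmj_rois(many, cfg)
  expect_equal(vapply(rois$rois, function(r) r$centroid[["y"]], numeric(1)),
               c(7.5, 42.5))
})

test_that("fiber ring has the dilation-minus-ROI geometry and excludes other ROIs", {
  cfg <- accumulation_config(fiber_ring_radius_px = 2)
  img <- matrix(0, 40, 40); img[10:15, 10:15] <- 200
  rois <- extract_nmj_rois(img, cfg)
  ring <- fiber_region_for(1L, rois, cfg)
  expect_equal(length(ring), 10 * 10 - 6 * 6)  # square dilation ring
  expect_length(intersect(ring, rois$rois[[1]]$idx), 0L)

  # adjacent ROIs are excluded from each other's rings
  img2 <- matrix(0, 40, 40)
  img2[10:15, 10:15] <- 200
  img2[10:15, 18:23] <- 200
  rois2 <- extract_nmj_rois(img2, cfg)
  expect_length(rois2$rois, 2L)
  r1 <- fiber_region_for(1L, rois2, cfg)
  r2 <- fiber_region_for(2L, rois2, cfg)
  expect_length(intersect(r1, rois2$rois[[2]]$idx), 0L)
  expect_length(intersect(r2, rois2$rois[[1]]$idx), 0L)

  # ROI filling the whole image leaves no fiber region
  full <- matrix(200, 12, 12)
  roisf <- extract_nmj_rois(full, cfg)
  expect_length(fiber_region_for(1L, roisf, cfg), 0L)
})

test_that("positivity call is strict at the decision boundary", {
  s <- function(m, sd = 0, n = 10L) {
    structure(list(mean_grey = m, sd_grey = sd, n_pixels = n),
              class = "region_stats")
  }
  expect_true(classify_accumulation(s(100), s(50, 20)))
  expect_false(classify_accumulation(s(70), s(50, 20)))  # equality is negative
  expect_false(classify_accumulation(s(50), s(50, 0)))   # sd -> 0, equal means
  expect_error(classify_accumulation(s(100, n = 0L), s(50)),
               class = "nmjquant_validation_error")
})

test_that("classifier is invariant under positive affine intensity transforms", {
  set.seed(77)
  for (rep in seq_len(100)) {
    img <- matrix(runif(32 * 32, 0, 255), 32, 32)
    idx_nmj <- sample(length(img), 40)
    idx_fib <- sample(setdiff(seq_along(img), idx_nmj), 120)
    a <- runif(1, 0.1, 4); b <- runif(1, -20, 60)
    timg <- a * img + b
    call1 <- classify_accumulation(region_stats(img, idx_nmj),
                                   region_stats(img, idx_fib))
    call2 <- classify_accumulation(region_stats(timg, idx_nmj),
                                   region_stats(timg, idx_fib))
    expect_identical(call1, call2)
  }
})

test_that("accumulation study recovers truth exactly on clean high-contrast fields", {
  for (model in c("apposed_plaque", "filament", "diffuse_enriched")) {
    p <- synthetic_params(image_shape = c(1L, 512L, 512L), n_nmjs = 12L,
                          marker_model = model, positivity_fraction = 0.5,
                          psf_sigma_um = 0, poisson_scale = 0,
                          gaussian_sd = 0, seed = 13L)
    tr <- generate_geometry(p)
    vol <- render_volume(tr, p)
    acc <- accumulation_study(vol, p$marker_name)
    expect_equal(acc$summary$n_analyzed, 12L)
    hit <- match_rois_to_truth(acc, tr, p$voxel_size)
    expect_equal(acc$records$positive, tr$nmj$positive[hit])
    expect_equal(acc$summary$percent_positive, 50)
  }
})

test_that("uniform marker images yield no positive calls", {
  p <- synthetic_params(image_shape = c(1L, 256L, 256L), n_nmjs = 4L,
                        positivity_fraction = 0, psf_sigma_um = 0,
                        poisson_scale = 0, gaussian_sd = 0, seed = 3L)
  tr <- generate_geometry(p)
  vol <- render_volume(tr, p)
  acc <- accumulation_study(vol, "VAChT")
  expect_equal(acc$summary$n_positive, 0L)
  expect_equal(acc$summary$percent_positive, 0)
})

test_that("recovered positivity is monotone in marker intensity", {
  pct <- vapply(c(40, 120, 200), function(level) {
    p <- synthetic_params(image_shape = c(1L, 512L, 512L), n_nmjs = 10L,
                          positivity_fraction = 1,
                          intensity = list(marker = level), seed = 8L)
    tr <- generate_geometry(p)
    vol <- render_volume(tr, p)
    accumulation_study(vol, "VAChT")$summary$percent_positive
  }, numeric(1))
  expect_true(all(diff(pct) >= 0))
  expect_equal(pct[3], 100)
})

test_that("accumulation study validates channels and dimensionality", {
  p <- synthetic_params(image_shape = c(1L, 256L, 256L), n_nmjs = 3L,
                        seed = 2L)
  vol <- render_volume(generate_geometry(p), p)
  expect_error(accumulation_study(vol, "NPY"),
               class = "nmjquant_config_error")
  vol3 <- volume_image(array(0L, c(4, 16, 16, 2)), c(1, 0.785, 0.785),
                       c("BGT", "VAChT"))
  expect_error(accumulation_study(vol3, "VAChT"),
               class = "nmjquant_validation_error")
})
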