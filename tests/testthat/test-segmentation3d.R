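mkvol <- function(arr, vox = c(1, 0.785, 0.785), name = "BGT") {
  volume_image(array(arr, dim = c(dim(arr), 1L)), vox, name)
}

test_that("binarization bounds are inclusive at both ends", {
  a <- array(0L, c(1, 3, 3))
  a[1, 1, 1:3] <- c(19L, 20L, 255L)
  v <- mkvol(a)
  m <- binarize(v, "BGT")  # default BGT bounds (20, 255)
  expect_equal(m[1, 1, ], c(FALSE, TRUE, TRUE))

  th <- array(c(5L, 6L), c(1, 1, 2))
  expect_equal(binarize(mkvol(th, name = "TH"), "TH")[1, 1, ],
               c(FALSE, TRUE))
  nfl <- array(c(21L, 22L), c(1, 1, 2))
  expect_equal(binarize(mkvol(nfl, name = "NFL"), "NFL")[1, 1, ],
               c(FALSE, TRUE))
  expect_error(binarize(v, "nope"), class = "nmjquant_config_error")
})

test_that("labeling matches constructed component counts and connectivity", {
  m <- array(FALSE, c(7, 7, 7))
  m[1:3, 1:3, 1:3] <- TRUE
  m[5:7, 5:7, 5:7] <- TRUE  # corner-diagonal contact at (4,4,4)? no: gap of 1
  lo <- label_components(m, 26)
  expect_equal(nrow(lo$objects), 2L)
  expect_equal(sort(lo$objects$size), c(27L, 27L))

  # two corner-diagonal voxels: one object at 26-conn, two at 6- and 18-conn
  d <- array(FALSE, c(2, 2, 2))
  d[1, 1, 1] <- TRUE; d[2, 2, 2] <- TRUE
  expect_equal(nrow(label_components(d, 26)$objects), 1L)
  expect_equal(nrow(label_components(d, 18)$objects), 2L)
  expect_equal(nrow(label_components(d, 6)$objects), 2L)

  # edge-diagonal voxels separate 18 from 6
  e <- array(FALSE, c(2, 2, 1))
  e[1, 1, 1] <- TRUE; e[2, 2, 1] <- TRUE
  expect_equal(nrow(label_components(e, 18)$objects), 1L)
  expect_equal(nrow(label_components(e, 6)$objects), 2L)

  expect_equal(nrow(label_components(array(FALSE, c(4, 4, 4)))$objects), 0L)
})

test_that("labeling agrees with an igraph flood-fill oracle on random masks", {
  set.seed(1234)
  for (rep in seq_len(100)) {
    conn <- sample(c(6L, 18L, 26L), 1)
    mask <- array(runif(16^3) < 0.25, c(16, 16, 16))
    lo <- label_components(mask, conn)
    oracle <- oracle_label(mask, conn)
    expect_equal(max(lo$labels), max(oracle))
    expect_equal(canonical_labels(lo$labels), canonical_labels(oracle))
  }
})

test_that("voxel count is conserved before filtering", {
  set.seed(9)
  mask <- array(runif(12 * 20 * 20) < 0.3, c(12, 20, 20))
  lo <- label_components(mask, 26)
  expect_equal(sum(lo$objects$size), sum(mask))
  expect_equal(sum(lo$labels != 0), sum(mask))
})

test_that("size filtering is inclusive and re-compacts labels", {
  m <- array(FALSE, c(1, 40, 220))
  m[1, 2:8, 2:8] <- TRUE          # 49 voxels
  m[1, 12:18, 12:19] <- FALSE
  m[1, 20:26, 30:37] <- TRUE      # 56 -> trim to exactly 50
  m[1, 20, 30:35] <- FALSE        # 56 - 6 = 50 voxels
  m[1, 35, 100:102] <- TRUE       # 3 voxels
  lo <- label_components(m, 26)
  sizes <- sort(lo$objects$size)
  expect_equal(sizes, c(3L, 49L, 50L))

  f50 <- filter_by_size(lo, 50, 2e7)
  expect_equal(f50$objects$size, 50L)          # 49 removed, 50 retained
  expect_equal(attr(f50, "n_removed"), 2L)
  expect_equal(f50$objects$id, 1L)             # labels re-compacted
  expect_equal(sort(unique(as.vector(f50$labels))), c(0L, 1L))

  f3 <- filter_by_size(lo, 3, 2e9)
  expect_equal(nrow(f3$objects), 3L)           # 3-voxel object retained

  # idempotent
  expect_equal(filter_by_size(f50, 50, 2e7)$objects, f50$objects)
})

test_that("edge exclusion removes face-touching objects, sparing z for sections", {
  m <- array(FALSE, c(4, 10, 10))
  m[2:3, 1:2, 4:5] <- TRUE   # touches y = 1 face
  m[2:3, 5:6, 5:6] <- TRUE   # interior
  lo <- label_components(m, 26)
  ex <- exclude_edge_objects(lo)
  expect_equal(nrow(ex$objects), 1L)
  expect_false(any(ex$objects$touches_edge))
  expect_equal(attr(ex, "n_removed"), 1L)
  # idempotent
  expect_equal(exclude_edge_objects(ex)$objects, ex$objects)

  # z-extent-1 data: z-face contact alone never excludes
  s <- array(FALSE, c(1, 10, 10))
  s[1, 4:6, 4:6] <- TRUE
  los <- label_components(s, 26)
  expect_equal(nrow(exclude_edge_objects(los)$objects), 1L)

  # everything on an edge -> empty result with a warning, not an error
  all_edge <- array(FALSE, c(1, 10, 10))
  all_edge[1, 1, 1:5] <- TRUE
  loa <- label_components(all_edge, 26)
  expect_warning(exa <- exclude_edge_objects(loa), "edge")
  expect_equal(nrow(exa$objects), 0L)
})

test_that("noise-only negative control yields zero marker objects", {
  # primary-antibody-omitted analogue: no marker structures, default noise
  p <- synthetic_params(image_shape = c(10L, 256L, 256L), n_nmjs = 4L,
                        positivity_fraction = 0, seed = 17L)
  vol <- render_volume(generate_geometry(p), p)
  lo <- segment_channel(vol, "VAChT", "marker")
  expect_equal(nrow(lo$objects), 0L)
})

test_that("segment_channel records non-increasing stage counts", {
  p <- synthetic_params(image_shape = c(10L, 256L, 256L), n_nmjs = 6L,
                        seed = 21L)
  vol <- render_volume(generate_geometry(p), p)
  lo <- segment_channel(vol, "BGT", "postsynapse")
  sc <- attr(lo, "stage_counts")
  expect_named(sc, c("labeled", "after_size", "after_edge"))
  expect_true(all(diff(sc) <= 0))
  expect_equal(unname(sc["after_edge"]), nrow(lo$objects))
})
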