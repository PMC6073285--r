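# Independent brute-force oracles used across the suite.

# Median filter by explicit window medians with edge-replicated padding.
oracle_median <- function(img, r) {
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ii <- pmin(pmax((i - r):(i + r), 1), nr)
      jj <- pmin(pmax((j - r):(j + r), 1), nc)
      out[i, j] <- stats::median(img[ii, jj])
    }
  }
  out
}

# Connected components via igraph on the voxel adjacency graph.
oracle_label <- function(mask, connectivity) {
  d <- dim(mask)
  n <- prod(d)
  idx <- array(seq_len(n), dim = d)
  offs <- list()
  for (a in -1:1) for (b in -1:1) for (c in -1:1) {
    s <- abs(a) + abs(b) + abs(c)
    if (s == 0) next
    if (connectivity == 6 && s > 1) next
    if (connectivity == 18 && s > 2) next
    # keep one direction per axis pair (undirected edges)
    if (a > 0 || (a == 0 && b > 0) || (a == 0 && b == 0 && c > 0)) {
      offs[[length(offs) + 1L]] <- c(a, b, c)
    }
  }
  verts <- which(mask)
  vmap <- integer(n)
  vmap[verts] <- seq_along(verts)
  edges <- integer(0)
  for (o in offs) {
    z1 <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
    y1 <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
    x1 <- max(1, 1 + o[3]):min(d[3], d[3] + o[3])
    a1 <- idx[z1, y1, x1]
    a0 <- idx[z1 - o[1], y1 - o[2], x1 - o[3]]
    keep <- mask[a1] & mask[a0]
    if (any(keep)) edges <- c(edges, rbind(vmap[a0[keep]], vmap[a1[keep]]))
  }
  g <- igraph::make_graph(edges = edges, n = length(verts), directed = FALSE)
  memb <- igraph::components(g)$membership
  lab <- array(0L, dim = d)
  lab[verts] <- as.integer(memb)
  lab
}

# Canonical relabeling so two labelings can be compared as partitions.
canonical_labels <- function(lab) {
  v <- lab[lab != 0]
  match(v, unique(v))
}

# All-pairs minimum anisotropic distance between two voxel sets.
oracle_min_dist <- function(a, b, vox) {
  dz <- outer(a[, 1] * vox[1], b[, 1] * vox[1], "-")
  dy <- outer(a[, 2] * vox[2], b[, 2] * vox[2], "-")
  dx <- outer(a[, 3] * vox[3], b[, 3] * vox[3], "-")
  sqrt(min(dz^2 + dy^2 + dx^2))
}

# Random sphere mask (voxel units) added into an existing array.
add_sphere_vox <- function(mask, center, r) {
  d <- dim(mask)
  g <- expand.grid(z = seq_len(d[1]), y = seq_len(d[2]), x = seq_len(d[3]))
  sel <- (g$z - center[1])^2 + (g$y - center[2])^2 + (g$x - center[3])^2 <= r^2
  mask[cbind(g$z[sel], g$y[sel], g$x[sel])] <- TRUE
  mask
}

# Match detected accumulation ROIs to truth NMJs by centroid proximity
# (returns the truth row index for each ROI).
match_rois_to_truth <- function(acc, truth, voxel_size) {
  ty <- truth$nmj$y_um / voxel_size[2] + 0.5
  tx <- truth$nmj$x_um / voxel_size[3] + 0.5
  vapply(seq_len(nrow(acc$records)), function(k) {
    which.min((ty - acc$records$centroid_y[k])^2 +
              (tx - acc$records$centroid_x[k])^2)
  }, integer(1))
}

voxel_diagonal <- function(vox) sqrt(sum(vox^2))
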