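#' Configuration of the threshold-based 3D segmentation
#'
#' Defaults follow the published analysis settings: inclusive intensity
#' bounds BGT 20-255, TH 6-255, NFL 22-255, VAChT 20-255; inclusive object
#' sizes (in voxels) 50-20,000,000 for postsynapses and 3-2,000,000,000 for
#' markers (the filamentous stains require the higher maximum); image-edge
#' exclusion for the postsynapse (BGT) channel only.
#'
#' @param intensity_bounds Named list of inclusive `(lo, hi)` bounds per
#'   channel name.
#' @param size_bounds Named list with `(min, max)` voxel counts for roles
#'   `postsynapse` and `marker`.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param exclude_edges Named logical for roles `postsynapse` and `marker`.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(intensity_bounds = list(BGT = c(20, 255),
                                                        TH = c(6, 255),
                                                        NFL = c(22, 255),
                                                        VAChT = c(20, 255)),
                                size_bounds = list(
                                  postsynapse = c(50, 2e7),
                                  marker = c(3, 2e9)),
                                connectivity = 26L,
                                exclude_edges = c(postsynapse = TRUE,
                                                  marker = FALSE)) {
  for (b in intensity_bounds) {
    if (length(b) != 2L || b[1] > b[2])
      nmj_validation_error("each intensity bound must be (lo, hi) with lo <= hi")
  }
  for (b in size_bounds) {
    if (length(b) != 2L || b[1] > b[2])
      nmj_validation_error("each size bound must be (min, max) with min <= max")
  }
  if (!connectivity %in% c(6L, 18L, 26L))
    nmj_validation_error("connectivity must be 6, 18 or 26")
  structure(list(intensity_bounds = intensity_bounds,
                 size_bounds = size_bounds,
                 connectivity = as.integer(connectivity),
                 exclude_edges = exclude_edges),
            class = "segmentation_config")
}

#' Binarize a channel at inclusive intensity bounds
#'
#' @param volume A [volume_image].
#' @param channel Channel name.
#' @param bounds `(lo, hi)`; when `NULL`, looked up by channel name in
#'   `cfg$intensity_bounds`.
#' @param cfg A [segmentation_config].
#' @return Logical `(nz, ny, nx)` array: voxel TRUE iff
#'   `lo <= intensity <= hi`.
#' @export
binarize <- function(volume, channel, bounds = NULL,
                     cfg = segmentation_config()) {
  arr <- get_channel(volume, channel)
  if (is.null(bounds)) {
    bounds <- cfg$intensity_bounds[[channel]]
    if (is.null(bounds))
      nmj_config_error(sprintf("no intensity bounds configured for channel '%s'",
                               channel))
  }
  arr >= bounds[1] & arr <= bounds[2]
}

# Build the labeled_objects structure from a label array.
.make_labeled <- function(labels, dims, connectivity, voxel_size = NULL) {
  nlab <- if (length(labels)) max(labels) else 0L
  if (nlab > 0) {
    st <- cpp_object_stats(labels, dims, nlab)
    objects <- data.frame(id = seq_len(nlab), size = st$size,
                          z0 = st$bbox[, 1], z1 = st$bbox[, 2],
                          y0 = st$bbox[, 3], y1 = st$bbox[, 4],
                          x0 = st$bbox[, 5], x1 = st$bbox[, 6],
                          touches_z = st$touch[, 1],
                          touches_y = st$touch[, 2],
                          touches_x = st$touch[, 3])
    objects$touches_edge <- objects$touches_y | objects$touches_x |
      (dims[1] > 1L & objects$touches_z)
  } else {
    objects <- data.frame(id = integer(), size = integer(),
                          z0 = integer(), z1 = integer(), y0 = integer(),
                          y1 = integer(), x0 = integer(), x1 = integer(),
                          touches_z = logical(), touches_y = logical(),
                          touches_x = logical(), touches_edge = logical())
  }
  structure(list(labels = labels, objects = objects, dim = dims,
                 connectivity = connectivity, voxel_size = voxel_size),
            class = "labeled_objects")
}

#' Label connected components of a binary volume
#'
#' Maximal connected components under 6-, 18- or 26-connectivity. Labels are
#' consecutive positive integers assigned in order of each component's first
#' voxel in array storage order, so labeling is deterministic.
#'
#' @param mask Logical `(nz, ny, nx)` array (a matrix is treated as a
#'   z-extent-1 volume; in-plane 26-connectivity is 8-connectivity).
#' @param connectivity 6, 18 or 26.
#' @param voxel_size Optional `(dz, dy, dx)` carried along for distance
#'   analysis.
#' @return A `labeled_objects` object: integer `labels` array (0 =
#'   background) plus a per-object table of sizes, bounding boxes and edge
#'   contact flags.
#' @export
label_components <- function(mask, connectivity = 26L, voxel_size = NULL) {
  if (is.matrix(mask)) mask <- array(mask, dim = c(1L, dim(mask)))
  if (length(dim(mask)) != 3L)
    nmj_validation_error("mask must be a (nz, ny, nx) array or a matrix")
  if (!connectivity %in% c(6L, 18L, 26L))
    nmj_validation_error("connectivity must be 6, 18 or 26")
  dims <- as.integer(dim(mask))
  labels <- cpp_label_components(as.logical(mask), dims,
                                 as.integer(connectivity))
  .make_labeled(labels, dims, as.integer(connectivity), voxel_size)
}

# Drop the listed object ids and re-compact the remaining labels (order
# preserved).
.drop_objects <- function(lo, drop_ids) {
  keep <- !(lo$objects$id %in% drop_ids)
  if (all(keep)) return(lo)
  old <- lo$objects$id[keep]
  map <- integer(max(lo$objects$id, 0L))
  map[old] <- seq_along(old)
  labels <- lo$labels
  nz <- labels != 0L
  relabeled <- labels
  vals <- labels[nz]
  vals[vals %in% drop_ids] <- 0L
  vals[vals != 0L] <- map[vals[vals != 0L]]
  relabeled[nz] <- vals
  obj <- lo$objects[keep, , drop = FALSE]
  obj$id <- seq_len(nrow(obj))
  rownames(obj) <- NULL
  out <- lo
  out$labels <- relabeled
  out$objects <- obj
  out
}

#' Filter labeled objects by voxel count
#'
#' Objects with size outside the inclusive `[min_vox, max_vox]` range are
#' removed and labels are re-compacted. The number removed is recorded in
#' the `"n_removed"` attribute.
#'
#' @param objects A `labeled_objects`.
#' @param min_vox,max_vox Inclusive size bounds in voxels.
#' @return Filtered `labeled_objects`.
#' @export
filter_by_size <- function(objects, min_vox, max_vox) {
  stopifnot(inherits(objects, "labeled_objects"))
  if (min_vox > max_vox) nmj_validation_error("min_vox must be <= max_vox")
  bad <- objects$objects$id[objects$objects$size < min_vox |
                            objects$objects$size > max_vox]
  out <- .drop_objects(objects, bad)
  attr(out, "n_removed") <- length(bad)
  out
}

#' Remove objects touching the image edges
#'
#' Any object with a voxel on an x, y or z face of the grid is removed. For
#' single-slice data the z faces are ignored (otherwise every object would
#' be excluded). If every object touches an edge the result is empty and a
#' warning is raised; the pipeline continues.
#'
#' @param objects A `labeled_objects`.
#' @return Filtered `labeled_objects` with attribute `"n_removed"`.
#' @export
exclude_edge_objects <- function(objects) {
  stopifnot(inherits(objects, "labeled_objects"))
  bad <- objects$objects$id[objects$objects$touches_edge]
  if (length(bad) && length(bad) == nrow(objects$objects))
    warning("all objects touch the image edge; result is empty")
  out <- .drop_objects(objects, bad)
  attr(out, "n_removed") <- length(bad)
  out
}

#' Segment one channel with the published pipeline settings
#'
#' Binarize at the channel's intensity bounds, label connected components,
#' apply the role's size filter, and (for the postsynapse role by default)
#' exclude image-edge objects. Per-stage object counts are recorded in the
#' `"stage_counts"` attribute.
#'
#' @param volume A [volume_image].
#' @param channel Channel name.
#' @param role `"postsynapse"` or `"marker"` (selects size bounds and edge
#'   policy).
#' @param cfg A [segmentation_config].
#' @param bounds Optional explicit intensity bounds overriding the config.
#' @return A `labeled_objects` carrying the volume's voxel size.
#' @export
segment_channel <- function(volume, channel,
                            role = c("postsynapse", "marker"),
                            cfg = segmentation_config(), bounds = NULL) {
  role <- match.arg(role)
  mask <- binarize(volume, channel, bounds = bounds, cfg = cfg)
  lo <- label_components(mask, cfg$connectivity,
                         voxel_size = volume$voxel_size)
  counts <- c(labeled = nrow(lo$objects))
  sb <- cfg$size_bounds[[role]]
  lo <- filter_by_size(lo, sb[1], sb[2])
  counts <- c(counts, after_size = nrow(lo$objects))
  if (isTRUE(unname(cfg$exclude_edges[role]))) {
    lo <- exclude_edge_objects(lo)
    counts <- c(counts, after_edge = nrow(lo$objects))
  }
  attr(lo, "stage_counts") <- counts
  lo
}

#' Voxel coordinates of one labeled object
#'
#' @param objects A `labeled_objects`.
#' @param id Object id.
#' @return Integer matrix with 1-based `(z, y, x)` rows.
#' @export
object_voxels <- function(objects, id) {
  stopifnot(inherits(objects, "labeled_objects"))
  sub <- .crop_to_bbox(objects, id)
  if (is.null(sub)) nmj_validation_error(sprintf("object %d is empty", id))
  idx <- which(sub$labels == id)
  if (!length(idx)) nmj_validation_error(sprintf("object %d is empty", id))
  v <- arrayInd(idx, dim(sub$labels))
  v[, 1] <- v[, 1] + sub$offset[1]
  v[, 2] <- v[, 2] + sub$offset[2]
  v[, 3] <- v[, 3] + sub$offset[3]
  v
}

# Crop the label array to an object's bounding box (a tight bbox, so voxels
# outside the crop can never belong to the object).
.crop_to_bbox <- function(objects, id) {
  row <- objects$objects[objects$objects$id == id, ]
  if (!nrow(row)) return(NULL)
  labs <- objects$labels[row$z0:row$z1, row$y0:row$y1, row$x0:row$x1,
                         drop = FALSE]
  list(labels = labs, offset = c(row$z0, row$y0, row$x0) - 1L)
}

#' Border voxels of one labeled object
#'
#' A border voxel has at least one face-neighbour (6-connectivity) outside
#' the object; voxels on the grid boundary count as border.
#'
#' @param objects A `labeled_objects`.
#' @param id Object id.
#' @return Integer matrix with 1-based `(z, y, x)` rows.
#' @export
border_voxels <- function(objects, id) {
  stopifnot(inherits(objects, "labeled_objects"))
  sub <- .crop_to_bbox(objects, id)
  if (is.null(sub)) nmj_validation_error(sprintf("object %d is empty", id))
  out <- cpp_border_voxels(as.integer(sub$labels),
                           as.integer(dim(sub$labels)), as.integer(id))
  if (!nrow(out)) nmj_validation_error(sprintf("object %d is empty", id))
  out[, 1] <- out[, 1] + sub$offset[1]
  out[, 2] <- out[, 2] + sub$offset[2]
  out[, 3] <- out[, 3] + sub$offset[3]
  out
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat(sprintf("labeled_objects: %d object(s), grid %s, %d-connectivity\n",
              nrow(x$objects), paste(x$dim, collapse = " x "),
              x$connectivity))
  invisible(x)
}
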