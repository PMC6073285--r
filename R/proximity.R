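#' Configuration of the proximity analysis
#'
#' @param threshold_um Proximity cutoff in micrometres (default 2, the
#'   published cutoff; the comparison is strict, "less than 2 um").
#' @param bin_width_um Histogram bin width in micrometres.
#' @return A `proximity_config` list.
#' @export
proximity_config <- function(threshold_um = 2, bin_width_um = 0.5) {
  if (threshold_um <= 0) nmj_validation_error("threshold_um must be > 0")
  if (bin_width_um <= 0) nmj_validation_error("bin_width_um must be > 0")
  structure(list(threshold_um = threshold_um, bin_width_um = bin_width_um),
            class = "proximity_config")
}

#' Edge-to-edge distance between two voxel objects
#'
#' Minimum anisotropic Euclidean distance between voxel centres over all
#' pairs of voxels of the two objects (the minimum over full voxel sets is
#' attained at border voxels, so passing border voxels gives the same
#' result). Objects sharing any voxel — possible after independent
#' per-channel segmentation — have distance 0.
#'
#' @param a,b Integer matrices of 1-based `(z, y, x)` voxel rows.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @return Distance in micrometres.
#' @export
edge_to_edge_distance <- function(a, b, voxel_size) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  if (!nrow(a) || !nrow(b))
    nmj_validation_error("both objects must be non-empty")
  if (any(voxel_size <= 0))
    nmj_validation_error("voxel_size must be strictly positive")
  ka <- paste(a[, 1], a[, 2], a[, 3])
  kb <- paste(b[, 1], b[, 2], b[, 3])
  if (any(ka %in% kb)) return(0)
  cpp_min_pair_dist(a, b, as.numeric(voxel_size))
}

# Anisotropic distance between two bounding boxes (lower bound on the
# voxel-centre distance of their contents).
.bbox_lower_bound <- function(b1, b2, vox) {
  gap <- function(lo1, hi1, lo2, hi2) max(0L, lo2 - hi1, lo1 - hi2)
  gz <- gap(b1[1], b1[2], b2[1], b2[2]) * vox[1]
  gy <- gap(b1[3], b1[4], b2[3], b2[4]) * vox[2]
  gx <- gap(b1[5], b1[6], b2[5], b2[6]) * vox[3]
  sqrt(gz^2 + gy^2 + gx^2)
}

#' Nearest marker object for every postsynaptic object
#'
#' For each retained NMJ (postsynapse) object, the edge-to-edge distance to
#' the closest marker object in physical units. The search prunes marker
#' candidates with a bounding-box lower bound, in increasing-bound order
#' with early termination; the result is identical to the brute-force
#' all-pairs minimum. Ties are broken by the lower marker id. With no
#' marker objects all distances are infinite and a warning is raised.
#'
#' @param nmj_objects,marker_objects `labeled_objects` for the two channels
#'   (same grid).
#' @param voxel_size `(dz, dy, dx)` in micrometres; defaults to the voxel
#'   size carried by `nmj_objects`.
#' @return Data frame with one row per NMJ object: `nmj_id`,
#'   `nearest_marker_id` (NA if none), `distance_um` (Inf if none).
#' @export
nearest_marker <- function(nmj_objects, marker_objects,
                           voxel_size = nmj_objects$voxel_size) {
  stopifnot(inherits(nmj_objects, "labeled_objects"),
            inherits(marker_objects, "labeled_objects"))
  if (is.null(voxel_size))
    nmj_config_error("voxel_size is required (none carried by the objects)")
  nn <- nrow(nmj_objects$objects)
  nm <- nrow(marker_objects$objects)
  rec <- data.frame(nmj_id = nmj_objects$objects$id,
                    nearest_marker_id = rep(NA_integer_, nn),
                    distance_um = rep(Inf, nn))
  if (nm == 0L) {
    if (nn > 0L) warning("no marker objects: all distances are infinite")
    return(rec)
  }
  mborders <- lapply(marker_objects$objects$id,
                     function(id) border_voxels(marker_objects, id))
  mvoxkeys <- vector("list", nm)  # filled lazily: only for bbox-overlapping pairs
  marker_keys <- function(j) {
    if (is.null(mvoxkeys[[j]])) {
      v <- object_voxels(marker_objects, marker_objects$objects$id[j])
      mvoxkeys[[j]] <<- paste(v[, 1], v[, 2], v[, 3])
    }
    mvoxkeys[[j]]
  }
  mb <- as.matrix(marker_objects$objects[, c("z0", "z1", "y0", "y1",
                                             "x0", "x1")])
  nb <- as.matrix(nmj_objects$objects[, c("z0", "z1", "y0", "y1",
                                          "x0", "x1")])
  for (i in seq_len(nn)) {
    a <- border_voxels(nmj_objects, nmj_objects$objects$id[i])
    ka <- NULL
    lbs <- vapply(seq_len(nm),
                  function(j) .bbox_lower_bound(nb[i, ], mb[j, ], voxel_size),
                  numeric(1))
    ord <- order(lbs, marker_objects$objects$id)
    best <- Inf
    best_id <- NA_integer_
    for (j in ord) {
      if (lbs[j] > best) break
      if (lbs[j] == 0) {
        if (is.null(ka)) {
          v <- object_voxels(nmj_objects, nmj_objects$objects$id[i])
          ka <- paste(v[, 1], v[, 2], v[, 3])
        }
        if (any(marker_keys(j) %in% ka)) {
          d <- 0
        } else {
          d <- cpp_min_pair_dist(a, mborders[[j]], as.numeric(voxel_size))
        }
      } else {
        d <- cpp_min_pair_dist(a, mborders[[j]], as.numeric(voxel_size))
      }
      id_j <- marker_objects$objects$id[j]
      if (d < best || (d == best && !is.na(best_id) && id_j < best_id)) {
        best <- d
        best_id <- id_j
      }
    }
    rec$nearest_marker_id[i] <- best_id
    rec$distance_um[i] <- best
  }
  rec
}

#' Fraction of NMJs within a proximity cutoff
#'
#' Strict comparison, matching the published "less than 2 um" statement;
#' infinite distances (no marker object) count as not-within.
#'
#' @param records Data frame from [nearest_marker()].
#' @param threshold_um Cutoff in micrometres.
#' @return Fraction in `[0, 1]`.
#' @export
proximity_fraction <- function(records, threshold_um = 2) {
  if (!is.data.frame(records) || !nrow(records))
    nmj_validation_error("records must be a non-empty data frame")
  if (threshold_um <= 0) nmj_validation_error("threshold_um must be > 0")
  mean(records$distance_um < threshold_um)
}

#' Distance distribution of NMJ-to-marker distances
#'
#' Histogram over right-open bins `[k w, (k+1) w)` plus the empirical CDF
#' `F(x) = (number of records with distance < x) / n` (strict, so `F(2)`
#' equals [proximity_fraction()] at 2 um). Infinite distances are reported
#' as a separate overflow count and never binned.
#'
#' @param records Data frame from [nearest_marker()].
#' @param bin_width_um Bin width in micrometres.
#' @return A `distance_distribution`: `histogram` data frame
#'   (`bin_lo_um`, `bin_hi_um`, `count`), `overflow`, `n`, and `cdf`
#'   (a function of distance).
#' @export
distance_distribution <- function(records, bin_width_um = 0.5) {
  if (!is.data.frame(records) || !nrow(records))
    nmj_validation_error("records must be a non-empty data frame")
  d <- records$distance_um
  fin <- d[is.finite(d)]
  overflow <- sum(!is.finite(d))
  n <- length(d)
  if (length(fin)) {
    k <- floor(fin / bin_width_um)
    nb <- max(k) + 1
    counts <- tabulate(k + 1, nbins = nb)
  } else {
    nb <- 0L
    counts <- integer(0)
  }
  hist <- data.frame(bin_lo_um = (seq_len(nb) - 1) * bin_width_um,
                     bin_hi_um = seq_len(nb) * bin_width_um,
                     count = counts)
  cdf <- function(x) vapply(x, function(xx) sum(fin < xx) / n, numeric(1))
  structure(list(histogram = hist, overflow = overflow, n = n, cdf = cdf,
                 bin_width_um = bin_width_um),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf(
    "distance_distribution: %d records (%d with no marker), bin width %g um\n",
    x$n, x$overflow, x$bin_width_um))
  invisible(x)
}

#' Plot a distance distribution (histogram plus empirical CDF)
#'
#' @param x A `distance_distribution`.
#' @param file Optional PNG path; when given the plot is written there.
#' @param ... Passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.distance_distribution <- function(x, file = NULL, ...) {
  draw <- function() {
    h <- x$histogram
    graphics::par(mar = c(4.5, 4.5, 2, 4.5))
    mids <- graphics::barplot(h$count, names.arg = sprintf("%g", h$bin_lo_um),
                              xlab = "edge-to-edge distance (um)",
                              ylab = "NMJ count", col = "grey70",
                              border = NA, ...)
    if (nrow(h)) {
      cum <- cumsum(h$count) / x$n
      graphics::lines(mids, cum * max(h$count, 1), lwd = 2)
      graphics::axis(4, at = seq(0, max(h$count, 1), length.out = 5),
                     labels = sprintf("%.2f", seq(0, 1, length.out = 5)))
      graphics::mtext("cumulative fraction", side = 4, line = 3)
    }
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
    draw()
  } else {
    draw()
  }
  invisible(x)
}
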