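#' Parameters of the synthetic NMJ image generator
#'
#' Bundles every knob of the forward model that stands in for stained,
#' confocally imaged muscle: grid geometry, plaque/bouton/filament sizes,
#' apposition-gap sampling, structure intensities, PSF blur and noise. The
#' defaults emulate the acquisition geometry used for the distance analysis
#' (0.785 x 0.785 um lateral, 1 um axial voxels, 8-bit intensities) and the
#' stained structures: ~3 um postsynaptic plaques clustered in a central
#' synapse band, presynaptic boutons apposed at sub-micrometre surface gaps,
#' and thin axonal filaments.
#'
#' @param image_shape `(nz, ny, nx)` voxel grid; `nz = 1` gives a planar
#'   cross-section.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @param n_nmjs Number of postsynaptic plaques to place.
#' @param nmj_radius_um Plaque radius (um).
#' @param shell_thickness_um Thickness of the hollow plaque shell used by the
#'   3D renderer (um); the 2D renderer draws filled discs.
#' @param marker_radius_um Radius of apposed presynaptic marker boutons (um).
#' @param filament_radius_um Half-thickness of filamentous axons (um).
#' @param filament_halflength_um Half-length of rendered axon segments (um).
#' @param band_fraction Fraction of the y extent forming the synapse band.
#' @param marker_model `"apposed_plaque"`, `"filament"` or
#'   `"diffuse_enriched"`.
#' @param marker_name Channel name for the marker; defaults by model
#'   (VAChT / TH / B2AR).
#' @param apposition_gap_um Length-2 range; surface gaps of positive
#'   appositions are drawn uniformly from it.
#' @param far_gap_um Far-distance bound: no marker structure is allowed
#'   within this surface gap of a marker-negative NMJ.
#' @param min_separation_um Minimum surface-to-surface separation between
#'   plaques. The default (9 um) exceeds `far_gap_um` plus the largest
#'   apposition gap plus a marker diameter, so a neighbour's bouton can never
#'   fall inside the far bound of a negative NMJ.
#' @param axon_density Expected background filament length per unit area
#'   (um per um^2), for the filament model.
#' @param positivity_fraction Target fraction of NMJs given a
#'   proximal/enriched marker structure.
#' @param psf_sigma_um Isotropic Gaussian PSF sigma (um); 0 disables blur.
#' @param poisson_scale Photons per grey level for Poisson shot noise; 0
#'   disables.
#' @param gaussian_sd Additive Gaussian read-noise sd (grey levels); 0
#'   disables.
#' @param intensity Named list of structure intensities on the 0-255 scale:
#'   `plaque`, `marker`, `filament`, `enrichment`, `diffuse`, `fiber`.
#' @param seed Integer seed; all placement and noise derive from it.
#' @return A validated `synthetic_params` list.
#' @export
synthetic_params <- function(image_shape = c(12L, 1024L, 1024L),
                             voxel_size = c(1, 0.785, 0.785),
                             n_nmjs = 30L,
                             nmj_radius_um = 3,
                             shell_thickness_um = 1,
                             marker_radius_um = 1.5,
                             filament_radius_um = 0.5,
                             filament_halflength_um = 15,
                             band_fraction = 0.2,
                             marker_model = c("apposed_plaque", "filament",
                                              "diffuse_enriched"),
                             marker_name = NULL,
                             apposition_gap_um = c(0, 0.5),
                             far_gap_um = 5,
                             min_separation_um = 9,
                             axon_density = 0.001,
                             positivity_fraction = 1,
                             psf_sigma_um = 0.5,
                             poisson_scale = 4,
                             gaussian_sd = 2,
                             intensity = list(plaque = 200, marker = 200,
                                              filament = 120,
                                              enrichment = 120,
                                              diffuse = 10, fiber = 40),
                             seed = 1L) {
  marker_model <- match.arg(marker_model)
  if (is.null(marker_name)) {
    marker_name <- switch(marker_model, apposed_plaque = "VAChT",
                          filament = "TH", diffuse_enriched = "B2AR")
  }
  p <- list(image_shape = as.integer(image_shape),
            voxel_size = as.numeric(voxel_size), n_nmjs = as.integer(n_nmjs),
            nmj_radius_um = nmj_radius_um,
            shell_thickness_um = shell_thickness_um,
            marker_radius_um = marker_radius_um,
            filament_radius_um = filament_radius_um,
            filament_halflength_um = filament_halflength_um,
            band_fraction = band_fraction, marker_model = marker_model,
            marker_name = marker_name,
            apposition_gap_um = as.numeric(apposition_gap_um),
            far_gap_um = far_gap_um, min_separation_um = min_separation_um,
            axon_density = axon_density,
            positivity_fraction = positivity_fraction,
            psf_sigma_um = psf_sigma_um, poisson_scale = poisson_scale,
            gaussian_sd = gaussian_sd,
            intensity = utils::modifyList(
              list(plaque = 200, marker = 200, filament = 120,
                   enrichment = 120, diffuse = 10, fiber = 40), intensity),
            seed = as.integer(seed))
  if (length(p$image_shape) != 3L || any(p$image_shape < 1L))
    nmj_validation_error("image_shape must be three positive extents (nz, ny, nx)")
  if (any(p$voxel_size <= 0))
    nmj_validation_error("voxel_size components must be strictly positive")
  if (p$n_nmjs < 1L) nmj_validation_error("n_nmjs must be >= 1")
  if (p$positivity_fraction < 0 || p$positivity_fraction > 1)
    nmj_validation_error("positivity_fraction must lie in [0, 1]")
  if (length(p$apposition_gap_um) != 2L || any(p$apposition_gap_um < 0) ||
      diff(p$apposition_gap_um) < 0)
    nmj_validation_error("apposition_gap_um must be a non-negative (lo, hi) range")
  if (any(unlist(p$intensity) > 255) || any(unlist(p$intensity) < 0))
    nmj_validation_error("intensity levels must lie in [0, 255]")
  class(p) <- "synthetic_params"
  p
}

# Fig-3-style positivity fractions per (marker, age). End points follow the
# reported developmental time-course; intermediate ages are monotone
# interpolations (see the methods vignette).
.positivity_table <- list(
  TH    = c(P0 = 0.40, P21 = 0.70, P30 = 0.80, adult = 0.90),
  NPY   = c(P0 = 0.08, P21 = 0.30, P30 = 0.45, adult = 0.60),
  B2AR  = c(P0 = 0.85, P21 = 0.85, P30 = 0.85, adult = 0.70),
  VAChT = c(P0 = 0.95, P21 = 0.95, P30 = 0.95, adult = 0.95)
)

.marker_models <- c(TH = "filament", NPY = "filament",
                    B2AR = "diffuse_enriched", VAChT = "apposed_plaque",
                    NFL = "filament")

#' Default positivity fraction for a marker at a developmental age
#'
#' @param marker One of `"TH"`, `"NPY"`, `"B2AR"`, `"VAChT"`.
#' @param age One of `"P0"`, `"P21"`, `"P30"`, `"adult"`.
#' @return The configured fraction in `[0, 1]`.
#' @export
positivity_default <- function(marker, age) {
  tab <- .positivity_table[[marker]]
  if (is.null(tab))
    nmj_config_error(sprintf("no positivity defaults for marker '%s'", marker))
  if (!age %in% names(tab))
    nmj_config_error(sprintf("no positivity default for age '%s' (have: %s)",
                             age, paste(names(tab), collapse = ", ")))
  unname(tab[age])
}

# --- internal geometry helpers ------------------------------------------

# squared distance from point p to segment a-b (rows may be vectors)
.dist_point_seg <- function(pz, py, px, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return(sqrt((pz - a[1])^2 + (py - a[2])^2 + (px - a[3])^2))
  }
  t <- ((pz - a[1]) * ab[1] + (py - a[2]) * ab[2] + (px - a[3]) * ab[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((pz - (a[1] + t * ab[1]))^2 + (py - (a[2] + t * ab[2]))^2 +
       (px - (a[3] + t * ab[3]))^2)
}

#' Generate ground-truth geometry for a synthetic muscle field
#'
#' Places non-overlapping postsynaptic plaques inside the synapse band and,
#' for a deterministic `round(positivity_fraction * n_nmjs)` of them (chosen
#' by a seeded shuffle), a marker structure: an apposed bouton whose surface
#' gap is drawn uniformly from `apposition_gap_um` (3D), an axon filament
#' routed tangentially at that gap, or a perisynaptic enrichment footprint.
#' Marker-negative NMJs receive no proximal structure, and background
#' filaments are rejected if they would pass within `far_gap_um` of one, so
#' their true gap is at least the far bound (infinite if no structure
#' exists). True gaps are recorded analytically from the continuous
#' coordinates, before any voxelization.
#'
#' In planar (`nz = 1`) fields, positive marker structures are placed
#' overlapping the plaque footprint (a cross-section through the
#' plaque-underlying marker structure, as the accumulation readout requires)
#' and their true gap is 0; surface-gap sampling applies to the 3D geometry.
#'
#' @param params A [synthetic_params] object.
#' @return A `synthetic_truth` list: `nmj` (one row per plaque with centre,
#'   radius, positivity label and analytic `true_gap_um`), `plaque_markers`,
#'   `filaments`, `enrichments`, and the generating `params`.
#' @export
generate_geometry <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  p <- params
  with_seed(p$seed, {
    nz <- p$image_shape[1]; ny <- p$image_shape[2]; nx <- p$image_shape[3]
    vz <- p$voxel_size[1]; vy <- p$voxel_size[2]; vx <- p$voxel_size[3]
    Lz <- nz * vz; Ly <- ny * vy; Lx <- nx * vx
    is2d <- nz == 1L
    r <- p$nmj_radius_um
    # margin r + 2 um: keeps the thresholded contour of a blurred plaque off
    # the image faces at the default PSF, so edge exclusion removes nothing
    # by construction
    margin <- r + 2
    band_half <- p$band_fraction * Ly / 2
    ylo <- max(margin, Ly / 2 - band_half)
    yhi <- min(Ly - margin, Ly / 2 + band_half)
    xlo <- margin; xhi <- Lx - margin
    if (is2d) {
      zlo <- zhi <- Lz / 2
    } else {
      zlo <- min(margin, Lz / 2); zhi <- max(Lz - margin, Lz / 2)
      if (Lz < 2 * r) nmj_placement_error("z extent smaller than a plaque diameter")
    }
    if (yhi < ylo || xhi < xlo)
      nmj_placement_error("image too small for the synapse band at this plaque radius")

    min_cc <- 2 * r + p$min_separation_um
    centers <- matrix(NA_real_, p$n_nmjs, 3)  # (z, y, x) um
    for (i in seq_len(p$n_nmjs)) {
      placed <- FALSE
      for (a in seq_len(2000L)) {
        cand <- c(runif(1, zlo, zhi), runif(1, ylo, yhi), runif(1, xlo, xhi))
        if (i == 1L) { ok <- TRUE } else {
          prev <- centers[seq_len(i - 1L), , drop = FALSE]
          dd <- sqrt((prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
                     (prev[, 3] - cand[3])^2)
          ok <- all(dd >= min_cc)
        }
        if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed)
        nmj_placement_error(sprintf(
          "cannot place %d non-overlapping plaques (failed at plaque %d)",
          p$n_nmjs, i))
    }

    n_pos <- round(p$positivity_fraction * p$n_nmjs)
    positive <- logical(p$n_nmjs)
    positive[sample(p$n_nmjs)[seq_len(n_pos)]] <- TRUE

    plaque_markers <- data.frame(id = integer(), nmj_id = integer(),
                                 z_um = numeric(), y_um = numeric(),
                                 x_um = numeric(), radius_um = numeric())
    filaments <- data.frame(id = integer(), nmj_id = integer(),
                            z0 = numeric(), y0 = numeric(), x0 = numeric(),
                            z1 = numeric(), y1 = numeric(), x1 = numeric(),
                            radius_um = numeric())
    enrichments <- plaque_markers[0, ]
    assigned_gap <- rep(Inf, p$n_nmjs)

    rm_ <- p$marker_radius_um
    wf <- p$filament_radius_um
    hl <- p$filament_halflength_um

    if (p$marker_model == "apposed_plaque") {
      mid <- 0L
      for (i in which(positive)) {
        mid <- mid + 1L
        if (is2d) {
          delta <- runif(1, 0, max(0, r - rm_))
          th <- runif(1, 0, 2 * pi)
          cm <- centers[i, ] + c(0, delta * cos(th), delta * sin(th))
          assigned_gap[i] <- 0
        } else {
          gap <- runif(1, p$apposition_gap_um[1], p$apposition_gap_um[2])
          cm <- NULL
          for (a in seq_len(200L)) {
            u <- rnorm(3); u <- u / sqrt(sum(u^2))
            cand <- centers[i, ] + u * (r + rm_ + gap)
            if (cand[1] >= rm_ / 2 && cand[1] <= Lz - rm_ / 2 &&
                cand[2] >= 0.5 && cand[2] <= Ly - 0.5 &&
                cand[3] >= 0.5 && cand[3] <= Lx - 0.5) { cm <- cand; break }
          }
          if (is.null(cm))
            nmj_placement_error("cannot place an apposed marker inside the volume")
          assigned_gap[i] <- gap
        }
        plaque_markers <- rbind(plaque_markers, data.frame(
          id = mid, nmj_id = i, z_um = cm[1], y_um = cm[2], x_um = cm[3],
          radius_um = rm_))
      }
    } else if (p$marker_model == "filament") {
      fid <- 0L
      neg_set <- which(!positive)
      # a candidate axon may not come within the far bound of any
      # marker-negative NMJ (their true gap must stay >= far_gap_um)
      clears_negatives <- function(a0, a1) {
        for (i in neg_set) {
          d <- .dist_point_seg(centers[i, 1], centers[i, 2], centers[i, 3],
                               a0, a1) - r - wf
          if (d < p$far_gap_um) return(FALSE)
        }
        TRUE
      }
      for (i in which(positive)) {
        fid <- fid + 1L
        seg <- NULL
        for (a in seq_len(200L)) {
          th <- runif(1, 0, 2 * pi)
          v <- c(0, cos(th), sin(th))       # in-plane offset direction
          u <- c(0, -sin(th), cos(th))      # in-plane axon direction
          if (is2d) {
            delta <- runif(1, 0, max(0.1, r - 1))
            pm <- centers[i, ] + v * delta
            gap_i <- 0
          } else {
            gap_i <- runif(1, p$apposition_gap_um[1], p$apposition_gap_um[2])
            pm <- centers[i, ] + v * (r + wf + gap_i)
          }
          a0 <- pm - u * hl; a1 <- pm + u * hl
          if (clears_negatives(a0, a1)) { seg <- list(a0, a1); break }
        }
        if (is.null(seg))
          nmj_placement_error(
            "cannot route an axon past the marker-negative NMJs; reduce density or spacing")
        assigned_gap[i] <- gap_i
        filaments <- rbind(filaments, data.frame(
          id = fid, nmj_id = i,
          z0 = seg[[1]][1], y0 = seg[[1]][2], x0 = seg[[1]][3],
          z1 = seg[[2]][1], y1 = seg[[2]][2], x1 = seg[[2]][3],
          radius_um = wf))
        if (is2d) {
          # cross-sections of filament-marker-positive NMJs show a
          # plaque-like marker extension underlying the postsynapse, not
          # just the crossing axon; model it as a bouton-sized footprint
          delta <- runif(1, 0, max(0, r - rm_))
          th2 <- runif(1, 0, 2 * pi)
          plaque_markers <- rbind(plaque_markers, data.frame(
            id = nrow(plaque_markers) + 1L, nmj_id = i,
            z_um = centers[i, 1],
            y_um = centers[i, 2] + delta * cos(th2),
            x_um = centers[i, 3] + delta * sin(th2),
            radius_um = rm_))
        }
      }
      # background axons, routed away from marker-negative NMJs
      n_bg <- max(0L, round(p$axon_density * Lx * Ly / (2 * hl)))
      neg <- neg_set
      for (b in seq_len(n_bg)) {
        for (a in seq_len(100L)) {
          q <- c(runif(1, zlo, zhi), runif(1, 0, Ly), runif(1, 0, Lx))
          th <- runif(1, 0, 2 * pi)
          u <- c(0, -sin(th), cos(th))
          a0 <- q - u * hl; a1 <- q + u * hl
          ok <- TRUE
          for (i in neg) {
            d <- .dist_point_seg(centers[i, 1], centers[i, 2], centers[i, 3],
                                 a0, a1) - r - wf
            if (d < p$far_gap_um) { ok <- FALSE; break }
          }
          if (ok) {
            fid <- fid + 1L
            filaments <- rbind(filaments, data.frame(
              id = fid, nmj_id = NA_integer_,
              z0 = a0[1], y0 = a0[2], x0 = a0[3],
              z1 = a1[1], y1 = a1[2], x1 = a1[3], radius_um = wf))
            break
          }
        }
      }
    } else { # diffuse_enriched
      eid <- 0L
      for (i in which(positive)) {
        eid <- eid + 1L
        enrichments <- rbind(enrichments, data.frame(
          id = eid, nmj_id = i, z_um = centers[i, 1], y_um = centers[i, 2],
          x_um = centers[i, 3], radius_um = r))
        assigned_gap[i] <- 0
      }
    }

    # analytic true gap: minimum surface gap over every marker structure
    true_gap <- rep(Inf, p$n_nmjs)
    for (i in seq_len(p$n_nmjs)) {
      g <- assigned_gap[i]
      if (nrow(plaque_markers) > 0) {
        d <- sqrt((plaque_markers$z_um - centers[i, 1])^2 +
                  (plaque_markers$y_um - centers[i, 2])^2 +
                  (plaque_markers$x_um - centers[i, 3])^2) -
          r - plaque_markers$radius_um
        g <- min(g, max(0, min(d)))
      }
      if (nrow(enrichments) > 0) {
        d <- sqrt((enrichments$z_um - centers[i, 1])^2 +
                  (enrichments$y_um - centers[i, 2])^2 +
                  (enrichments$x_um - centers[i, 3])^2) -
          r - enrichments$radius_um
        g <- min(g, max(0, min(d)))
      }
      if (nrow(filaments) > 0) {
        for (f in seq_len(nrow(filaments))) {
          d <- .dist_point_seg(centers[i, 1], centers[i, 2], centers[i, 3],
                               c(filaments$z0[f], filaments$y0[f], filaments$x0[f]),
                               c(filaments$z1[f], filaments$y1[f], filaments$x1[f])) -
            r - filaments$radius_um[f]
          g <- min(g, max(0, d))
        }
      }
      true_gap[i] <- g
    }

    truth <- list(
      nmj = data.frame(id = seq_len(p$n_nmjs), z_um = centers[, 1],
                       y_um = centers[, 2], x_um = centers[, 3],
                       radius_um = r, positive = positive,
                       true_gap_um = true_gap),
      plaque_markers = plaque_markers, filaments = filaments,
      enrichments = enrichments, params = p)
    class(truth) <- "synthetic_truth"
    truth
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d NMJs (%d marker-positive), model '%s'\n",
              nrow(x$nmj), sum(x$nmj$positive), x$params$marker_model))
  invisible(x)
}

# Add a (possibly hollow) sphere/disc to a logical (nz, ny, nx) array.
.add_sphere <- function(mask, center, radius, vox, shell = NULL) {
  d <- dim(mask)
  zc <- (seq_len(d[1]) - 0.5) * vox[1]
  yc <- (seq_len(d[2]) - 0.5) * vox[2]
  xc <- (seq_len(d[3]) - 0.5) * vox[3]
  if (d[1] == 1L) center[1] <- zc[1]  # planar section through the centre
  zi <- which(abs(zc - center[1]) <= radius)
  yi <- which(abs(yc - center[2]) <= radius)
  xi <- which(abs(xc - center[3]) <= radius)
  if (!length(zi) || !length(yi) || !length(xi)) return(mask)
  d2 <- outer(outer((zc[zi] - center[1])^2, (yc[yi] - center[2])^2, "+"),
              (xc[xi] - center[3])^2, "+")
  sel <- d2 <= radius^2
  if (!is.null(shell) && shell > 0 && shell < radius) {
    sel <- sel & d2 >= (radius - shell)^2
  }
  sub <- mask[zi, yi, xi, drop = FALSE]
  sub[sel] <- TRUE
  mask[zi, yi, xi] <- sub
  mask
}

# Add a capsule (thick segment) to a logical array.
.add_segment <- function(mask, a, b, radius, vox) {
  d <- dim(mask)
  zc <- (seq_len(d[1]) - 0.5) * vox[1]
  yc <- (seq_len(d[2]) - 0.5) * vox[2]
  xc <- (seq_len(d[3]) - 0.5) * vox[3]
  if (d[1] == 1L) { a[1] <- zc[1]; b[1] <- zc[1] }
  pad <- radius + max(vox)
  zi <- which(zc >= min(a[1], b[1]) - pad & zc <= max(a[1], b[1]) + pad)
  yi <- which(yc >= min(a[2], b[2]) - pad & yc <= max(a[2], b[2]) + pad)
  xi <- which(xc >= min(a[3], b[3]) - pad & xc <= max(a[3], b[3]) + pad)
  if (!length(zi) || !length(yi) || !length(xi)) return(mask)
  g <- expand.grid(z = zc[zi], y = yc[yi], x = xc[xi])
  dd <- .dist_point_seg(g$z, g$y, g$x, a, b)
  sel <- array(dd <= radius, dim = c(length(zi), length(yi), length(xi)))
  sub <- mask[zi, yi, xi, drop = FALSE]
  sub[sel] <- TRUE
  mask[zi, yi, xi] <- sub
  mask
}

#' Rasterize ground-truth structures into per-channel boolean masks
#'
#' Voxelized truth derived from the continuous geometry (no blur, no noise):
#' a voxel belongs to a structure iff its centre lies inside the continuous
#' object. Postsynaptic plaques are hollow shells in 3D and filled discs in
#' planar sections.
#'
#' @param truth A `synthetic_truth` object.
#' @return List with logical `(nz, ny, nx)` arrays `postsynapse` and
#'   `marker`.
#' @export
truth_masks <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  p <- truth$params
  d <- p$image_shape
  vox <- p$voxel_size
  is2d <- d[1] == 1L
  post <- array(FALSE, dim = d)
  for (i in seq_len(nrow(truth$nmj))) {
    post <- .add_sphere(post, c(truth$nmj$z_um[i], truth$nmj$y_um[i],
                                truth$nmj$x_um[i]),
                        truth$nmj$radius_um[i], vox,
                        shell = if (is2d) NULL else p$shell_thickness_um)
  }
  marker <- array(FALSE, dim = d)
  if (nrow(truth$plaque_markers) > 0) {
    for (i in seq_len(nrow(truth$plaque_markers))) {
      marker <- .add_sphere(marker, c(truth$plaque_markers$z_um[i],
                                      truth$plaque_markers$y_um[i],
                                      truth$plaque_markers$x_um[i]),
                            truth$plaque_markers$radius_um[i], vox)
    }
  }
  if (nrow(truth$enrichments) > 0) {
    for (i in seq_len(nrow(truth$enrichments))) {
      marker <- .add_sphere(marker, c(truth$enrichments$z_um[i],
                                      truth$enrichments$y_um[i],
                                      truth$enrichments$x_um[i]),
                            truth$enrichments$radius_um[i], vox)
    }
  }
  if (nrow(truth$filaments) > 0) {
    for (i in seq_len(nrow(truth$filaments))) {
      marker <- .add_segment(
        marker,
        c(truth$filaments$z0[i], truth$filaments$y0[i], truth$filaments$x0[i]),
        c(truth$filaments$z1[i], truth$filaments$y1[i], truth$filaments$x1[i]),
        truth$filaments$radius_um[i], vox)
    }
  }
  list(postsynapse = post, marker = marker)
}

#' Render a ground-truth geometry into a noisy two-channel image
#'
#' Forward imaging model: structures are rasterized at their configured
#' intensities onto the voxel grid, blurred with an anisotropy-aware
#' separable Gaussian PSF, then degraded with Poisson shot noise followed by
#' additive Gaussian noise, and clipped to the 8-bit range. With
#' `psf_sigma_um = 0` and zero noise, voxels at structure centres carry the
#' configured intensities exactly. Rendering is deterministic given
#' `(truth, params$seed)`.
#'
#' @param truth A `synthetic_truth` from [generate_geometry()].
#' @param params The same [synthetic_params] (defaults to
#'   `truth$params`).
#' @return A [volume_image] with channels `BGT` and the marker name.
#' @export
render_volume <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "synthetic_truth"))
  p <- params
  d <- p$image_shape
  is2d <- d[1] == 1L
  masks <- truth_masks(truth)
  lv <- p$intensity
  post <- array(as.numeric(lv$diffuse), dim = d)
  post[masks$postsynapse] <- lv$plaque
  marker_base <- if (is2d || p$marker_model == "diffuse_enriched")
    lv$fiber else lv$diffuse
  mark <- array(as.numeric(marker_base), dim = d)
  mark_level <- switch(p$marker_model, apposed_plaque = lv$marker,
                       filament = lv$filament,
                       diffuse_enriched = lv$enrichment)
  mark[masks$marker] <- mark_level
  if (p$psf_sigma_um > 0) {
    sig <- p$psf_sigma_um / p$voxel_size
    if (is2d) sig[1] <- 0
    post <- cpp_gaussian_blur3d(post, d, sig)
    mark <- cpp_gaussian_blur3d(mark, d, sig)
  }
  n <- prod(d)
  with_seed(child_seed(p$seed, 7L), {
    degrade <- function(img) {
      x <- as.numeric(img)
      if (p$poisson_scale > 0) {
        x <- rpois(n, pmax(x, 0) * p$poisson_scale) / p$poisson_scale
      }
      if (p$gaussian_sd > 0) x <- x + rnorm(n, 0, p$gaussian_sd)
      array(as.integer(pmin(pmax(round(x), 0), 255)), dim = d)
    }
    post <- degrade(post)
    mark <- degrade(mark)
  })
  data <- array(0L, dim = c(d, 2L))
  data[, , , 1] <- post
  data[, , , 2] <- mark
  volume_image(data, voxel_size = p$voxel_size,
               channel_names = c("BGT", p$marker_name))
}

#' Generate a developmental time-course of synthetic cross-sections
#'
#' One planar two-channel field per age, with the marker's positivity
#' fraction taken from the configured developmental defaults
#' ([positivity_default()]). Seeds are derived per age from `seed`.
#'
#' @param ages Character vector of age labels (e.g. `c("P0", "adult")`).
#' @param marker Marker name with configured defaults (`TH`, `NPY`, `B2AR`,
#'   `VAChT`).
#' @param seed Integer master seed.
#' @param base_params Named list of [synthetic_params] overrides applied to
#'   every age (e.g. `image_shape`, `n_nmjs`).
#' @return Named list (one element per age) of `list(volume, truth)`.
#' @export
generate_timecourse <- function(ages, marker, seed = 1L,
                                base_params = list()) {
  model <- .marker_models[marker]
  if (is.na(model))
    nmj_config_error(sprintf("no marker model configured for '%s'", marker))
  out <- vector("list", length(ages))
  names(out) <- ages
  for (k in seq_along(ages)) {
    frac <- positivity_default(marker, ages[k])
    args <- utils::modifyList(
      list(image_shape = c(1L, 512L, 512L), n_nmjs = 20L,
           marker_model = unname(model), marker_name = marker,
           positivity_fraction = frac, seed = child_seed(seed, k)),
      base_params)
    p <- do.call(synthetic_params, args)
    truth <- generate_geometry(p)
    vol <- render_volume(truth, p)
    out[[k]] <- list(volume = vol, truth = truth)
  }
  out
}
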