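#' Multichannel intensity volume with physical voxel sizes
#'
#' The universal image container of the package: an unsigned 8-bit intensity
#' grid indexed `(z, y, x, channel)` together with the physical voxel spacing
#' `(dz, dy, dx)` in micrometres and one name per channel. Planar sections are
#' stored as volumes with z-extent 1, so every downstream operation is
#' dimension-agnostic.
#'
#' @param data An intensity array. Accepted shapes: a `(ny, nx)` matrix
#'   (single channel section), a `(nz, ny, nx)` array (single channel
#'   volume), or a `(nz, ny, nx, nc)` array. All values must lie in
#'   `[0, 255]`.
#' @param voxel_size Numeric length-3 vector `(dz, dy, dx)` in micrometres;
#'   all components strictly positive.
#' @param channel_names Character vector naming the channels; its length must
#'   equal the channel extent. Defaults to `"ch1"`, `"ch2"`, ...
#' @return An object of class `volume_image`.
#' @examples
#' img <- matrix(0L, 8, 8)
#' v <- volume_image(img, voxel_size = c(1, 0.785, 0.785))
#' dim(v$data)  # 1 8 8 1
#' @export
volume_image <- function(data, voxel_size, channel_names = NULL) {
  if (is.matrix(data)) {
    data <- array(data, dim = c(1L, dim(data), 1L))
  } else if (length(dim(data)) == 3L) {
    data <- array(data, dim = c(dim(data), 1L))
  } else if (length(dim(data)) != 4L) {
    nmj_validation_error("data must be a matrix or a 3D/4D array")
  }
  if (anyNA(data) || min(data) < 0 || max(data) > 255) {
    nmj_validation_error("intensities must be finite and within [0, 255]")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    nmj_validation_error("voxel_size must be three strictly positive values (dz, dy, dx)")
  }
  nc <- dim(data)[4]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc) {
    nmj_validation_error("length(channel_names) must equal the channel extent")
  }
  storage.mode(data) <- "integer"
  structure(
    list(data = data, voxel_size = voxel_size,
         channel_names = as.character(channel_names)),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "volume_image: %d z x %d y x %d x voxels, %d channel(s) [%s]\n",
    d[1], d[2], d[3], d[4], paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  voxel size (dz, dy, dx): %s um\n",
              paste(format(x$voxel_size), collapse = " x ")))
  invisible(x)
}

#' Extract one channel of a volume as a (z, y, x) array
#'
#' @param volume A [volume_image].
#' @param channel Channel name or index.
#' @return A 3D integer array `(nz, ny, nx)`.
#' @export
get_channel <- function(volume, channel) {
  stopifnot(inherits(volume, "volume_image"))
  if (is.character(channel)) {
    i <- match(channel, volume$channel_names)
    if (is.na(i)) {
      nmj_config_error(sprintf("unknown channel '%s' (available: %s)",
                               channel,
                               paste(volume$channel_names, collapse = ", ")))
    }
    channel <- i
  }
  arr <- volume$data[, , , channel, drop = FALSE]
  array(arr, dim = dim(volume$data)[1:3])
}

# Sidecar metadata path for a TIFF written by write_volume().
sidecar_path <- function(path) paste0(path, ".json")

#' Write a volume to TIFF with a JSON metadata sidecar
#'
#' Slices are stored as 8-bit grayscale TIFF directories, channel-fastest
#' within z. Voxel sizes, channel names and grid dimensions go to a JSON
#' sidecar (`<path>.json`), since plain TIFF has no standard slot for
#' anisotropic voxel metadata. The round trip through [read_volume()] is
#' lossless for 8-bit data.
#'
#' @param volume A [volume_image].
#' @param path Output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_image"))
  d <- dim(volume$data)
  slices <- vector("list", d[1] * d[4])
  k <- 1L
  for (z in seq_len(d[1])) {
    for (ch in seq_len(d[4])) {
      slices[[k]] <- matrix(volume$data[z, , , ch], d[2], d[3]) / 255
      k <- k + 1L
    }
  }
  ok <- tryCatch(
    tiff::writeTIFF(slices, path, bits.per.sample = 8L),
    error = function(e) nmj_io_error(paste0("cannot write TIFF: ",
                                            conditionMessage(e))))
  meta <- list(nz = d[1], ny = d[2], nx = d[3], nc = d[4],
               voxel_size = volume$voxel_size,
               channel_names = volume$channel_names)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multichannel TIFF volume
#'
#' Reads a TIFF (optionally multi-directory) into a [volume_image] with axes
#' normalized to `(z, y, x, channel)`; a plain 2D image becomes a z-extent-1
#' volume. Grid layout and voxel sizes come from the JSON sidecar written by
#' [write_volume()] when present; otherwise `voxel_size` (and `n_channels`,
#' channel-fastest slice order assumed) must be supplied, mirroring the
#' practice of specifying acquisition geometry per experiment rather than
#' trusting file metadata.
#'
#' Images deeper than 8 bits are rejected unless `rescale = TRUE`, in which
#' case they are linearly mapped onto 0-255; the pipeline's intensity
#' thresholds are only meaningful on the 8-bit scale.
#'
#' @param path TIFF file path.
#' @param voxel_size `(dz, dy, dx)` in micrometres; overrides any sidecar.
#' @param n_channels Number of channels when no sidecar is present.
#' @param channel_names Optional channel names override.
#' @param rescale Allow linear rescale of >8-bit data.
#' @return A [volume_image].
#' @export
read_volume <- function(path, voxel_size = NULL, n_channels = 1L,
                        channel_names = NULL, rescale = FALSE) {
  if (!file.exists(path)) nmj_io_error(sprintf("file not found: %s", path))
  slices <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) nmj_io_error(paste0("cannot read TIFF: ",
                                            conditionMessage(e))))
  if (!is.list(slices)) slices <- list(slices)
  slices <- lapply(slices, function(s) {
    if (length(dim(s)) == 3L) s[, , 1] else s  # collapse replicated planes
  })
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  if (!is.null(meta)) {
    nc <- as.integer(meta$nc)
    if (is.null(voxel_size)) voxel_size <- as.numeric(meta$voxel_size)
    if (is.null(channel_names)) channel_names <- meta$channel_names
  } else {
    nc <- as.integer(n_channels)
  }
  if (is.null(voxel_size)) {
    nmj_config_error("no voxel size available: supply voxel_size or a metadata sidecar")
  }
  nslice <- length(slices)
  if (nslice %% nc != 0L) {
    nmj_validation_error("slice count is not a multiple of the channel count")
  }
  nz <- nslice %/% nc
  mx <- max(vapply(slices, max, numeric(1)))
  if (mx > 255) {
    if (!rescale) {
      nmj_validation_error(
        "image is deeper than 8 bits; pass rescale = TRUE to map linearly onto 0-255")
    }
    top <- if (mx <= 65535) 65535 else mx
    slices <- lapply(slices, function(s) round(s / top * 255))
  }
  d2 <- dim(slices[[1]])
  data <- array(0L, dim = c(nz, d2[1], d2[2], nc))
  k <- 1L
  for (z in seq_len(nz)) {
    for (ch in seq_len(nc)) {
      data[z, , , ch] <- as.integer(round(slices[[k]]))
      k <- k + 1L
    }
  }
  volume_image(data, voxel_size = voxel_size, channel_names = channel_names)
}
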