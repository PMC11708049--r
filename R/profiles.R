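#' Registered multichannel image set
#'
#' Container for per-channel 2-D intensity rasters sharing one pixel grid,
#' plus the micrometre-per-pixel calibration that all downstream distance
#' measurements rely on.
#'
#' @param channels Named list of numeric matrices, all of one shape.
#' @param pixel_size Pixel edge length in micrometres (> 0).
#' @param metadata Free-form key/value list.
#' @return An object of class `image_set`.
#' @export
image_set <- function(channels, pixel_size, metadata = list()) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stopf("channels must be a named list of matrices")
  dims <- lapply(channels, dim)
  for (ch in names(channels)) {
    if (!is.matrix(channels[[ch]]))
      stopf("channel '%s' is not a 2-D raster", ch)
    if (!identical(dims[[ch]], dims[[1L]]))
      stopf("channel '%s' has shape %s, expected %s", ch,
            paste(dims[[ch]], collapse = "x"),
            paste(dims[[1L]], collapse = "x"))
  }
  if (!is_scalar_num(pixel_size) || pixel_size <= 0)
    stopf("pixel_size must be a positive number")
  structure(list(channels = channels, pixel_size = pixel_size,
                 metadata = metadata),
            class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<image_set> %d channel(s) [%s], %d x %d px, %.3g um/px\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], x$pixel_size))
  invisible(x)
}

#' Read per-channel TIFF files into an image set
#'
#' Decodes one 16-bit grayscale TIFF per channel and assembles them into a
#' registered [image_set()]. Channels listed with a missing path are simply
#' absent from the result (never zero-filled).
#'
#' @param paths Named character vector of file locations; names become
#'   channel names (e.g. `c(CFP = ..., YFP = ..., mCherry = ...)`).
#' @param pixel_size Micrometres per pixel (> 0); the TIFFs themselves carry
#'   no calibration.
#' @return An [image_set()] with intensities on the 0-65535 scale.
#' @export
read_image_set <- function(paths, pixel_size) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stopf("paths must be named by channel")
  chans <- list()
  for (ch in names(paths)) {
    p <- paths[[ch]]
    if (is.na(p) || !nzchar(p)) next
    if (!file.exists(p)) stopf("channel '%s': file not found: %s", ch, p)
    m <- tryCatch(tiff::readTIFF(p),
                  error = function(e)
                    stopf("channel '%s': cannot decode %s (%s)",
                          ch, p, conditionMessage(e)))
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    if (length(dim(m)) != 2L)
      stopf("channel '%s': %s did not decode to a 2-D raster", ch, p)
    chans[[ch]] <- round(m * 65535)
  }
  if (length(chans) == 0L) stopf("no readable channels")
  image_set(chans, pixel_size)
}

#' Intensity cross-section profile
#'
#' Ordered samples of per-channel intensity along a line, with distances in
#' micrometres and a per-sample validity mask. Masked-out samples are carried
#' but never used by downstream statistics.
#'
#' @param distance Strictly increasing numeric vector of sample positions
#'   (um); 0 marks the alignment origin once the profile is aligned.
#' @param intensity Named list of numeric vectors, one per channel, each the
#'   length of `distance`.
#' @param mask Logical validity vector (default all `TRUE`).
#' @param origin_kind `NULL` for an unaligned profile, otherwise
#'   `"yfp-peak"` or `"mcherry-edge"`.
#' @return An object of class `cross_section`.
#' @export
cross_section <- function(distance, intensity, mask = NULL,
                          origin_kind = NULL) {
  if (is.numeric(intensity)) intensity <- list(value = intensity)
  if (is.null(mask)) mask <- rep(TRUE, length(distance))
  if (any(diff(distance) <= 0))
    stopf("distances must be strictly increasing")
  lens <- vapply(intensity, length, integer(1))
  if (any(lens != length(distance)) || length(mask) != length(distance))
    stopf("all channel vectors and the mask must match length(distance)")
  if (!is.null(origin_kind))
    origin_kind <- match.arg(origin_kind, c("yfp-peak", "mcherry-edge"))
  structure(list(distance = distance, intensity = intensity,
                 mask = as.logical(mask), origin_kind = origin_kind),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> %d samples, %.4g-%.4g um, channels: %s%s\n",
              length(x$distance), min(x$distance), max(x$distance),
              paste(names(x$intensity), collapse = ", "),
              if (is.null(x$origin_kind)) " (unaligned)"
              else paste0(", origin: ", x$origin_kind)))
  invisible(x)
}

# Bilinear interpolation of matrix m at fractional pixel coordinates
# (row i, col j); coordinates are clamped to the pixel-centre hull.
bilinear <- function(m, i, j) {
  nr <- nrow(m); nc <- ncol(m)
  i <- pmin(pmax(i, 1), nr)
  j <- pmin(pmax(j, 1), nc)
  i0 <- pmin(floor(i), nr - 1L); j0 <- pmin(floor(j), nc - 1L)
  if (nr == 1L) i0 <- rep(1L, length(i))
  if (nc == 1L) j0 <- rep(1L, length(j))
  di <- i - i0; dj <- j - j0
  i1 <- pmin(i0 + 1L, nr); j1 <- pmin(j0 + 1L, nc)
  m[cbind(i0, j0)] * (1 - di) * (1 - dj) +
    m[cbind(i1, j0)] * di * (1 - dj) +
    m[cbind(i0, j1)] * (1 - di) * dj +
    m[cbind(i1, j1)] * di * dj
}

#' Extract an intensity cross-section along a line
#'
#' Samples every channel of an image set along the segment from `p0` to `p1`
#' at arithmetic spacing `step`, using bilinear interpolation for off-grid
#' positions. Distances are measured from `p0`. This reproduces the
#' user-marked measurement line from producer colony into reporter material.
#'
#' @param img An [image_set()].
#' @param p0,p1 Segment endpoints `c(x, y)` in micrometres.
#' @param step Sampling step in micrometres (> 0); defaults to one pixel
#'   equivalent. A step longer than the segment yields the two endpoints.
#' @return A [cross_section()] with all samples valid.
#' @export
extract_cross_section <- function(img, p0, p1, step = img$pixel_size) {
  stopifnot(inherits(img, "image_set"))
  if (!is_scalar_num(step) || step <= 0) stopf("step must be > 0")
  L <- sqrt(sum((p1 - p0)^2))
  if (L < .Machine$double.eps) stopf("zero-length line")
  d <- dim(img$channels[[1L]])
  lim <- c(d[2], d[1]) * img$pixel_size
  for (p in list(p0, p1)) {
    if (p[1] < 0 || p[1] > lim[1] || p[2] < 0 || p[2] > lim[2])
      stopf("line endpoint (%g, %g) um is outside the image (%g x %g um)",
            p[1], p[2], lim[1], lim[2])
  }
  s <- seq(0, L, by = step)
  if (length(s) < 2L) s <- c(0, L)
  ux <- (p1[1] - p0[1]) / L
  uy <- (p1[2] - p0[2]) / L
  x <- p0[1] + s * ux
  y <- p0[2] + s * uy
  jj <- x / img$pixel_size + 0.5
  ii <- y / img$pixel_size + 0.5
  vals <- lapply(img$channels, bilinear, i = ii, j = jj)
  cross_section(s, vals)
}

#' Locate the producer-colony edge on a profile
#'
#' Finds where the producer channel (mCherry by default) falls to the
#' half-maximum between its plateau level and its far-field level, scanning
#' outward from the channel maximum and interpolating linearly between the
#' bracketing samples. This automates the manual colony-edge marks used when
#' aligning decay profiles to the producer edge.
#'
#' @param profile A [cross_section()] containing the producer channel.
#' @param channel Channel name (default `"mCherry"`).
#' @param n_far Number of trailing samples defining the far-field level.
#' @param contrast_k Contrast floor: the plateau-to-far-field drop must exceed
#'   `contrast_k` times the far-field SD, otherwise there is no colony on the
#'   section and an error is raised.
#' @return The edge distance in micrometres.
#' @export
detect_producer_edge <- function(profile, channel = "mCherry",
                                 n_far = 20L, contrast_k = 5) {
  stopifnot(inherits(profile, "cross_section"))
  if (!channel %in% names(profile$intensity))
    stopf("profile has no channel '%s'", channel)
  y <- profile$intensity[[channel]]
  d <- profile$distance
  n <- length(y)
  far_idx <- seq.int(max(1L, n - n_far + 1L), n)
  far <- mean(y[far_idx])
  far_sd <- if (length(far_idx) > 1L) stats::sd(y[far_idx]) else 0
  contrast <- max(y) - far
  if (contrast <= 0 || contrast <= contrast_k * far_sd)
    stopf("no colony on section: '%s' contrast %.3g below floor",
          channel, contrast)
  half <- far + contrast / 2
  i0 <- which.max(y)
  for (i in seq.int(i0, n - 1L)) {
    if (y[i] >= half && y[i + 1L] < half) {
      t <- (y[i] - half) / (y[i] - y[i + 1L])
      return(d[i] + t * (d[i + 1L] - d[i]))
    }
  }
  stopf("no colony edge: '%s' never crosses its half-maximum", channel)
}

#' Align a profile to a measurement origin
#'
#' Shifts distances so `origin` maps to zero and masks out samples at
#' negative distances. The lawn assay is aligned at the YFP peak; the colony
#' assay at the producer (mCherry) colony edge.
#'
#' @param profile A [cross_section()].
#' @param origin Distance (um) within the profile's range.
#' @param origin_kind `"yfp-peak"` or `"mcherry-edge"`; recorded on the
#'   result.
#' @return The aligned [cross_section()].
#' @export
align_profile <- function(profile, origin,
                          origin_kind = c("yfp-peak", "mcherry-edge")) {
  stopifnot(inherits(profile, "cross_section"))
  origin_kind <- match.arg(origin_kind)
  d <- profile$distance
  if (origin < min(d) || origin > max(d))
    stopf("origin %g um is outside the profile range [%g, %g]",
          origin, min(d), max(d))
  profile$distance <- d - origin
  profile$mask <- profile$mask & profile$distance >= 0
  profile$origin_kind <- origin_kind
  profile
}

#' Mask the inter-colony gap of a profile
#'
#' Marks samples with distance in the closed interval
#' `[gap_start, gap_end]` invalid; intensities are untouched. Used for
#' non-contacting colony pairs, where positions between the two colonies
#' carry no reporter material and are ignored.
#'
#' @param profile A [cross_section()].
#' @param gap_start,gap_end Interval bounds in micrometres
#'   (`gap_start < gap_end`). An interval outside the profile range leaves it
#'   unchanged.
#' @return The masked [cross_section()].
#' @export
mask_gap <- function(profile, gap_start, gap_end) {
  stopifnot(inherits(profile, "cross_section"))
  if (gap_start >= gap_end)
    stopf("inverted gap interval: [%g, %g]", gap_start, gap_end)
  inside <- profile$distance >= gap_start & profile$distance <= gap_end
  profile$mask <- profile$mask & !inside
  profile
}

#' Serialize cross-section profiles as CSV
#'
#' Columns are `distance_um`, one lower-cased column per channel, and `mask`
#' (0/1).
#'
#' @param profile A [cross_section()].
#' @param path File path.
#' @return `read_profile` returns a [cross_section()]; `write_profile`
#'   returns `path` invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "cross_section"))
  df <- data.frame(distance_um = profile$distance)
  for (ch in names(profile$intensity))
    df[[tolower(ch)]] <- profile$intensity[[ch]]
  df$mask <- as.integer(profile$mask)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @param channel_case Named character vector mapping lower-cased CSV columns
#'   back to channel names (defaults restore CFP/YFP/mCherry).
#' @export
read_profile <- function(path,
                         channel_case = c(cfp = "CFP", yfp = "YFP",
                                          mcherry = "mCherry")) {
  df <- utils::read.csv(path)
  chans <- setdiff(names(df), c("distance_um", "mask"))
  ints <- list()
  for (ch in chans) {
    nm <- if (ch %in% names(channel_case)) channel_case[[ch]] else ch
    ints[[nm]] <- df[[ch]]
  }
  cross_section(df$distance_um, ints,
                mask = if ("mask" %in% names(df)) df$mask > 0 else NULL)
}
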