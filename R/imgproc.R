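# Bright-field z-stack preprocessing: inversion, rolling-ball background
# subtraction, and per-pixel focus projection into a single plane. The chain
# order is fixed (invert -> per-slice rolling ball -> focus projection) and
# recorded in the projected image's provenance.
#
# Pixels are carried in grey-level units (0 .. 2^bit_depth - 1, stored as
# numeric): that is what 8/16-bit TIFFs contain, it makes inversion a
# bit-exact involution, and it keeps the rolling-ball radius commensurable
# with intensity as in the classic plugin.

#' Construct a z-stack
#'
#' @param voxels 3D numeric array, `height x width x n_slices`, grey-level
#'   units. A 2D matrix is promoted to a single-slice stack.
#' @param slice_spacing_um Physical slice spacing in micrometers (the
#'   screen's acquisition used 18 slices at 100 um).
#' @param bit_depth Integer bit depth (grey maximum is `2^bit_depth - 1`).
#' @param focus_slices Optional per-organoid ground-truth focal slices
#'   (simulator metadata).
#' @return A `zstack` object.
#' @export
zstack <- function(voxels, slice_spacing_um = 100, bit_depth = 8L,
                   focus_slices = NULL) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (dim(voxels)[3] < 1L) stop("a z-stack needs at least one slice", call. = FALSE)
  if (!is.numeric(slice_spacing_um) || slice_spacing_um <= 0) {
    stop("slice_spacing_um must be positive", call. = FALSE)
  }
  structure(list(voxels = voxels,
                 slice_spacing_um = slice_spacing_um,
                 bit_depth = as.integer(bit_depth),
                 focus_slices = focus_slices),
            class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<zstack> %d slice(s) of %dx%d, %d-bit, %.0f um spacing\n",
              d[3], d[1], d[2], x$bit_depth, x$slice_spacing_um))
  invisible(x)
}

n_slices <- function(stack) dim(stack$voxels)[3]
grey_max <- function(stack) 2^stack$bit_depth - 1

#' Read a z-stack from a (multi-page) TIFF
#'
#' @param path TIFF file; all pages are read as slices.
#' @param slice_spacing_um,bit_depth Stack metadata (TIFF bit depth is
#'   detected from the data when `bit_depth = NULL`: 16-bit if any value
#'   exceeds the 8-bit range after scaling).
#' @return A [zstack()] in grey-level units.
#' @export
read_zstack <- function(path, slice_spacing_um = 100, bit_depth = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bps <- attr(pages[[1]], "bits.per.sample") %||% 8L
  if (is.null(bit_depth)) bit_depth <- as.integer(bps)
  scale <- 2^bit_depth - 1
  slices <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # drop extra channels
    round(p * scale)
  })
  vox <- array(unlist(slices), dim = c(dim(slices[[1]]), length(slices)))
  zstack(vox, slice_spacing_um = slice_spacing_um, bit_depth = bit_depth)
}

#' Write a z-stack to a multi-page TIFF
#' @param stack A [zstack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_zstack <- function(stack, path) {
  m <- grey_max(stack)
  pages <- lapply(seq_len(n_slices(stack)),
                  function(s) stack$voxels[, , s] / m)
  tiff::writeTIFF(pages, path, bits.per.sample = min(stack$bit_depth, 16L))
  invisible(path)
}

#' Invert a bright-field stack
#'
#' Maps every pixel `p` to `M - p`, where `M` is the grey maximum of the
#' stack's bit depth, turning dark organoids on a bright background into
#' bright signal on dark. Applying twice restores the input bit-exactly.
#'
#' @param stack A [zstack()].
#' @return Inverted [zstack()].
#' @export
invert_stack <- function(stack) {
  stopifnot(inherits(stack, "zstack"))
  stack$voxels <- grey_max(stack) - stack$voxels
  stack
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image with a
#' ball-shaped (non-flat, hemispherical) structuring element of the given
#' radius and subtracts it, clamping at zero. Smooth structure wider than
#' the ball is removed; compact features narrower than the ball footprint
#' are preserved. Flat images map to zero everywhere.
#'
#' @param image 2D numeric matrix in grey-level units.
#' @param radius_px Ball radius in pixels (default 10, the screen's
#'   preprocessing setting). Must be smaller than the smallest image side.
#' @return Background-subtracted matrix, non-negative.
#' @export
rolling_ball_subtract <- function(image, radius_px = 10L) {
  stopifnot(is.matrix(image), is.numeric(image))
  radius_px <- as.integer(radius_px)
  if (radius_px < 1L) stop("radius_px must be >= 1", call. = FALSE)
  if (radius_px >= min(dim(image))) {
    stop("radius_px must be smaller than the smallest image dimension",
         call. = FALSE)
  }
  bg <- .ball_dilate(.ball_erode(image, radius_px), radius_px)
  pmax(image - bg, 0)
}

# Windowed Laplacian energy per slice: square of the discrete 4-neighbour
# Laplacian, box-summed over a window x window neighbourhood (replicated
# borders).
laplacian_energy <- function(slice, window) {
  kern <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  lap <- EBImage::filter2(slice, kern, boundary = "replicate")
  box <- matrix(1, window, window)
  EBImage::filter2(lap^2, box, boundary = "replicate")
}

#' Project a z-stack to a single plane by local sharpness
#'
#' For every pixel, selects the value from the slice maximizing the local
#' sharpness score (sum of squared discrete Laplacian over a square window),
#' the focus-stacking strategy behind extended-depth-of-field projection.
#' Ties go to the lowest slice index, so the result is deterministic.
#'
#' @param stack A [zstack()].
#' @param sharpness_window_px Odd window side in pixels (default 11).
#' @return A `projected_image`: `pixels` (grey levels), `focus_index_map`
#'   (1-based winning slice per pixel), `bit_depth`, and `provenance` (the
#'   ordered list of operations applied so far).
#' @export
project_focus <- function(stack, sharpness_window_px = 11L) {
  stopifnot(inherits(stack, "zstack"))
  w <- as.integer(sharpness_window_px)
  if (w < 1L || w %% 2L == 0L) {
    stop("sharpness_window_px must be a positive odd integer", call. = FALSE)
  }
  ns <- n_slices(stack)
  d <- dim(stack$voxels)
  if (ns == 1L) {
    pixels <- stack$voxels[, , 1]
    fmap <- matrix(1L, d[1], d[2])
  } else {
    best <- laplacian_energy(stack$voxels[, , 1], w)
    fmap <- matrix(1L, d[1], d[2])
    for (s in 2:ns) {
      e <- laplacian_energy(stack$voxels[, , s], w)
      better <- e > best          # strict: ties keep the lower slice
      best[better] <- e[better]
      fmap[better] <- s
    }
    pixels <- matrix(0, d[1], d[2])
    for (s in seq_len(ns)) {
      sel <- fmap == s
      sl <- stack$voxels[, , s]
      pixels[sel] <- sl[sel]
    }
  }
  structure(list(pixels = pixels, focus_index_map = fmap,
                 bit_depth = stack$bit_depth,
                 provenance = list(list(op = "project_focus",
                                        sharpness_window_px = w))),
            class = "projected_image")
}

#' @export
print.projected_image <- function(x, ...) {
  cat(sprintf("<projected_image> %dx%d, %d-bit; ops: %s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              paste(vapply(x$provenance, `[[`, "", "op"), collapse = " -> ")))
  invisible(x)
}

#' Full preprocessing chain for one well
#'
#' Applies the fixed chain invert -> per-slice rolling-ball background
#' subtraction -> focus projection, and records each operation with its
#' parameters in the result's provenance.
#'
#' @param stack A [zstack()] (or an `organo_scene`, which is quantized to an
#'   8-bit single-slice stack first).
#' @param radius_px Rolling-ball radius (default 10).
#' @param sharpness_window_px Focus-projection window (default 11).
#' @return A `projected_image` ready for [to_model_input()].
#' @export
#' @examples
#' sc <- simulate_well_image(phenotype_params(n_organoids = 2), seed = 7,
#'                           size = c(96, 96))
#' pr <- preprocess_stack(sc, radius_px = 5)
#' pr
preprocess_stack <- function(stack, radius_px = 10L,
                             sharpness_window_px = 11L) {
  if (inherits(stack, "organo_scene")) {
    stack <- zstack(quantize_grey(stack$image), bit_depth = 8L)
  }
  stopifnot(inherits(stack, "zstack"))
  inv <- invert_stack(stack)
  for (s in seq_len(n_slices(inv))) {
    inv$voxels[, , s] <- rolling_ball_subtract(inv$voxels[, , s], radius_px)
  }
  proj <- project_focus(inv, sharpness_window_px)
  proj$provenance <- c(
    list(list(op = "invert"),
         list(op = "rolling_ball_subtract", radius_px = as.integer(radius_px))),
    proj$provenance)
  proj
}

# ImageNet channel statistics, the normalization convention of the standard
# natural-image pretraining corpus.
IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_SD <- c(0.229, 0.224, 0.225)

#' Convert a projected image to 3-channel model input
#'
#' Scales grey levels to \[0,1\], resizes (bilinear) to `side_px` square,
#' replicates the single channel to 3 identical channels, and applies the
#' configured intensity normalization. Deterministic.
#'
#' @param image A `projected_image`, or a plain numeric matrix in grey
#'   levels (assumed 8-bit).
#' @param side_px Output side length (default 224, the input geometry of
#'   standard image backbones).
#' @param normalization `"unit"` leaves intensities in \[0,1\];
#'   `"imagenet"` standardizes each channel by the natural-image corpus
#'   mean/sd. Embeddings are only comparable within one fixed scheme.
#' @return Numeric array `side_px x side_px x 3`.
#' @export
to_model_input <- function(image, side_px = 224L,
                           normalization = c("unit", "imagenet")) {
  normalization <- match.arg(normalization)
  if (inherits(image, "projected_image")) {
    px <- image$pixels / (2^image$bit_depth - 1)
  } else if (is.matrix(image)) {
    px <- image / 255
  } else {
    stop("image must be a projected_image or a numeric matrix", call. = FALSE)
  }
  side_px <- as.integer(side_px)
  if (side_px < 1L) stop("side_px must be positive", call. = FALSE)
  if (length(px) == 0L) stop("empty image", call. = FALSE)
  resized <- as.matrix(EBImage::resize(EBImage::as.Image(px),
                                       w = side_px, h = side_px))
  out <- array(resized, dim = c(side_px, side_px, 3L))
  if (normalization == "imagenet") {
    for (ch in 1:3) {
      out[, , ch] <- (out[, , ch] - IMAGENET_MEAN[ch]) / IMAGENET_SD[ch]
    }
  }
  out
}
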