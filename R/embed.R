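# Image embedding: turn projected well images into fixed-length descriptive
# numeric vectors. The screen's reference feature space is the 512-unit
# pooled ("flattening") layer of an 18-layer residual network pretrained on
# natural images; loading it requires a deep-learning runtime plus a weight
# file. The package additionally provides a deterministic handcrafted
# 512-dimensional morphology descriptor (intensity histogram + radial
# darkness profile + gradient-orientation histogram) that needs no weights
# and is the default: every downstream stage is dimension-agnostic and runs
# unchanged on either feature space.

HANDCRAFTED_ID <- "handcrafted-v1"
HANDCRAFTED_BINS <- c(intensity = 256L, radial = 128L, orientation = 128L)

#' Create a feature extractor
#'
#' @param kind `"handcrafted"` (default): deterministic 512-dimensional
#'   morphology descriptor, no external weights. `"resnet18"`: the pooled
#'   512-unit layer of a pretrained 18-layer residual network; requires a
#'   local weight file and a supported runtime, and errors with guidance
#'   towards the handcrafted extractor when unavailable.
#' @param weights For `"resnet18"`, path to a local weight file.
#' @return An `extractor` object: `$kind`, `$id`, `$length`, `$side_px`,
#'   `$normalization`, and `$fn(array) -> numeric`.
#' @export
#' @examples
#' ex <- make_extractor("handcrafted")
#' ex$length
make_extractor <- function(kind = c("handcrafted", "resnet18"),
                           weights = NULL) {
  kind <- match.arg(kind)
  if (kind == "resnet18") {
    if (is.null(weights) || !file.exists(weights)) {
      stop(paste("pretrained resnet18 weights not available locally;",
                 "download a weight file and pass it via 'weights',",
                 "or use make_extractor(\"handcrafted\") which needs no",
                 "weights and emits vectors of the same width (512)"),
           call. = FALSE)
    }
    id <- paste0("resnet18-", substr(unname(tools::md5sum(weights)), 1, 12))
    stop(paste("no deep-learning runtime is installed to execute resnet18",
               "weights; use make_extractor(\"handcrafted\") instead"),
         call. = FALSE)
  }
  structure(list(kind = "handcrafted", id = HANDCRAFTED_ID,
                 length = sum(HANDCRAFTED_BINS), side_px = 224L,
                 normalization = "unit",
                 fn = handcrafted_features),
            class = "extractor")
}

#' @export
print.extractor <- function(x, ...) {
  cat(sprintf("<extractor> %s (%d features, %dpx input, %s normalization)\n",
              x$id, x$length, x$side_px, x$normalization))
  invisible(x)
}

# 512-dimensional handcrafted morphology descriptor on a unit-normalized
# 3-channel model input (channels are identical; channel 1 is used):
#   f0001-f0256  intensity histogram (fractions, 256 bins over [0,1])
#   f0257-f0384  radial darkness profile about the darkness centroid
#                (128 annuli out to the half-diagonal), scaled by a fixed
#                0.1 block weight: organoid placement is random within a
#                well, so this block has intrinsically higher per-well
#                variance than the other two and would otherwise dominate
#                Euclidean distances with placement noise
#   f0385-f0512  gradient-orientation histogram (128 bins over [0, pi),
#                magnitude-weighted per pixel, x30 block weight). The block
#                deliberately keeps total edge density (it is not
#                normalized to unit mass): edge density per unit area is
#                the strongest spiky-vs-round-vs-empty cue, while the bin
#                shape captures orientation anisotropy
# Organoid foreground is dark on bright background before inversion and
# bright after; the descriptor works on whatever intensities it is given
# and only assumes a roughly unimodal background.
handcrafted_features <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) x <- x[, , 1]
  stopifnot(is.matrix(x))
  if (any(is.na(x))) stop("input image contains NA/NaN pixels", call. = FALSE)
  n <- length(x)
  xv <- clip01(x)

  # intensity histogram
  bins <- HANDCRAFTED_BINS[["intensity"]]
  idx <- pmin(bins, floor(xv * bins) + 1L)
  h_int <- tabulate(idx, nbins = bins) / n

  # radial darkness profile about the darkness-weighted centroid
  # foreground weight: deviation from the (assumed unimodal) background;
  # works both before inversion (dark organoids, bright bg) and after
  bg <- median(xv)
  w <- if (bg >= 0.5) pmax(bg - xv, 0) else pmax(xv - bg, 0)
  nr <- nrow(x); nc <- ncol(x)
  tot <- sum(w)
  if (tot > 1e-8) {
    ci <- sum(row(x) * w) / tot
    cj <- sum(col(x) * w) / tot
  } else {
    ci <- (nr + 1) / 2; cj <- (nc + 1) / 2
  }
  rho <- sqrt((row(x) - ci)^2 + (col(x) - cj)^2)
  rmax <- sqrt(nr^2 + nc^2) / 2
  rb <- HANDCRAFTED_BINS[["radial"]]
  ridx <- pmin(rb, floor(rho / rmax * rb) + 1L)
  sums <- vapply(seq_len(rb), function(b) sum(w[ridx == b]), 0)
  cnts <- tabulate(ridx, nbins = rb)
  h_rad <- ifelse(cnts > 0, sums / pmax(cnts, 1L), 0)

  # gradient-orientation histogram (central differences, axis-wrapped)
  gx <- (rbind(xv[-1, , drop = FALSE], xv[nr, , drop = FALSE]) -
         rbind(xv[1, , drop = FALSE], xv[-nr, , drop = FALSE])) / 2
  gy <- (cbind(xv[, -1, drop = FALSE], xv[, nc, drop = FALSE]) -
         cbind(xv[, 1, drop = FALSE], xv[, -nc, drop = FALSE])) / 2
  mag <- sqrt(gx^2 + gy^2)
  theta <- atan2(gy, gx) %% pi
  ob <- HANDCRAFTED_BINS[["orientation"]]
  oidx <- pmin(ob, floor(theta / pi * ob) + 1L)
  msum <- vapply(seq_len(ob), function(b) sum(mag[oidx == b]), 0)
  h_ori <- 30 * msum / n

  out <- c(h_int, 0.1 * h_rad, h_ori)
  stopifnot(length(out) == sum(HANDCRAFTED_BINS))
  out
}

#' Embed one image
#'
#' Inference-only and deterministic: identical inputs give identical
#' vectors, and no extractor state is updated.
#'
#' @param input 3-channel model input array (see [to_model_input()]), a
#'   `projected_image`, or a plain grey-level matrix (converted with the
#'   extractor's input geometry and normalization).
#' @param extractor An [make_extractor()] handle.
#' @return Numeric feature vector of length `extractor$length`, named
#'   `f0001...`.
#' @export
embed_image <- function(input, extractor = make_extractor()) {
  stopifnot(inherits(extractor, "extractor"))
  if (inherits(input, "projected_image") || is.matrix(input)) {
    input <- to_model_input(input, side_px = extractor$side_px,
                            normalization = extractor$normalization)
  }
  if (any(is.na(input))) stop("input image contains NA/NaN pixels", call. = FALSE)
  v <- extractor$fn(input)
  if (length(v) != extractor$length || any(!is.finite(v))) {
    stop("extractor produced an invalid vector", call. = FALSE)
  }
  names(v) <- sprintf("f%04d", seq_along(v))
  v
}

#' Embed all wells of a plate
#'
#' Runs the full preprocessing chain and the extractor over every well
#' image, preserving input order, and joins the vectors to well metadata.
#'
#' @param images Named list of `organo_scene` / [zstack()] objects (names =
#'   well ids), e.g. from [simulate_plate()].
#' @param records Well metadata data frame with `plate_id` and `well`
#'   columns.
#' @param extractor An [make_extractor()] handle.
#' @param radius_px,sharpness_window_px Preprocessing parameters.
#' @return Feature table: metadata columns, `extractor_id`, then one column
#'   per feature.
#' @export
embed_wells <- function(images, records, extractor = make_extractor(),
                        radius_px = 10L, sharpness_window_px = 11L) {
  stopifnot(length(images) == nrow(records))
  feats <- matrix(NA_real_, nrow = length(images), ncol = extractor$length)
  for (i in seq_along(images)) {
    proj <- preprocess_stack(images[[i]], radius_px = radius_px,
                             sharpness_window_px = sharpness_window_px)
    feats[i, ] <- embed_image(proj, extractor)
  }
  colnames(feats) <- sprintf("f%04d", seq_len(extractor$length))
  meta <- as.data.frame(records)
  meta$extractor_id <- extractor$id
  cbind(meta, as.data.frame(feats))
}

feature_cols <- function(tbl) grep("^f[0-9]{4}$", names(tbl), value = TRUE)

feature_matrix <- function(tbl) {
  as.matrix(tbl[, feature_cols(tbl), drop = FALSE])
}

#' Write a feature table to CSV
#'
#' One row per well: metadata columns first, then `f0001..fNNNN`. The
#' round-trip through [read_features()] is lossless to 15 significant
#' digits.
#'
#' @param features Feature table from [embed_wells()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  fc <- feature_cols(features)
  if (!length(fc)) stop("no feature columns (f0001..) found", call. = FALSE)
  out <- features
  for (col in fc) out[[col]] <- formatC(out[[col]], format = "g", digits = 15)
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a feature table and merge with well metadata
#'
#' Feature rows are joined to metadata by `(plate_id, well)`. Rows without
#' matching metadata are reported as orphans (attribute `"orphans"`, with a
#' warning) and excluded, so downstream models only see annotated wells.
#'
#' @param path Feature CSV from [write_features()].
#' @param records Optional metadata data frame to (re)join by
#'   `(plate_id, well)`.
#' @return Feature table; `attr(, "orphans")` holds excluded rows.
#' @export
read_features <- function(path, records = NULL) {
  tbl <- read.csv(path, stringsAsFactors = FALSE)
  fc <- feature_cols(tbl)
  if (!length(fc)) stop("no feature columns (f0001..) found", call. = FALSE)
  if (!is.null(records)) {
    key <- paste(tbl$plate_id, tbl$well)
    ref <- paste(records$plate_id, records$well)
    orphan <- !(key %in% ref)
    orphans <- tbl[orphan, , drop = FALSE]
    if (any(orphan)) {
      warning(sprintf("%d feature row(s) had no matching well metadata and were excluded",
                      sum(orphan)), call. = FALSE)
    }
    tbl <- tbl[!orphan, , drop = FALSE]
    meta_cols <- setdiff(names(records), names(tbl))
    if (length(meta_cols)) {
      idx <- match(paste(tbl$plate_id, tbl$well), ref)
      tbl <- cbind(tbl[, setdiff(names(tbl), fc), drop = FALSE],
                   records[idx, meta_cols, drop = FALSE],
                   tbl[, fc, drop = FALSE])
    }
    attr(tbl, "orphans") <- orphans
  }
  rownames(tbl) <- NULL
  tbl
}
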