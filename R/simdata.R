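# Seeded simulator of bright-field organoid well images, z-stacks and whole
# 384-well plates with known ground truth. The simulator emulates the
# screen's phenotype contrast: mesenchymal (EMT-like) organoids are spiky
# structures with radial protrusions invading the matrix, epithelial
# (MET-like) organoids are smooth round discs, and media wells are cell-free
# background. Organoids are rendered dark on a bright background, matching
# bright-field convention, so the preprocessing inversion step is meaningful.

#' Phenotype parameters for one simulated well
#'
#' @param spikiness Real in \[0,1\]: 0 = round/MET-like, 1 = spiky/EMT-like.
#'   Spike length scales with spikiness.
#' @param n_organoids Number of organoids; 0 encodes a cell-free media well.
#' @param organoid_radius_px Disc radius in pixels.
#' @param n_spikes Radial protrusions per organoid.
#' @param spike_length_px Full spike length at spikiness 1; forced to 0 when
#'   `spikiness == 0` (round organoids carry no protrusions).
#' @param noise_sd Additive Gaussian background noise (unit-intensity scale).
#' @return A `phenotype_params` list.
#' @export
phenotype_params <- function(spikiness = 1, n_organoids = 8L,
                             organoid_radius_px = 30, n_spikes = 12L,
                             spike_length_px = 36, noise_sd = 0.02) {
  for (f in c("spikiness", "n_organoids", "organoid_radius_px",
              "n_spikes", "spike_length_px", "noise_sd")) {
    stop_if_not_finite(get(f), f)
  }
  if (spikiness < 0 || spikiness > 1) stop("spikiness must lie in [0,1]", call. = FALSE)
  if (n_organoids < 0) stop("n_organoids must be >= 0", call. = FALSE)
  if (organoid_radius_px <= 0) stop("organoid_radius_px must be positive", call. = FALSE)
  if (n_spikes < 0 || spike_length_px < 0) {
    stop("n_spikes and spike_length_px must be non-negative", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (spikiness == 0) spike_length_px <- 0
  structure(list(spikiness = spikiness,
                 n_organoids = as.integer(n_organoids),
                 organoid_radius_px = organoid_radius_px,
                 n_spikes = as.integer(n_spikes),
                 spike_length_px = spike_length_px,
                 noise_sd = noise_sd),
            class = "phenotype_params")
}

#' Ground-truth dose-response parameters for a simulated drug
#'
#' Defines how a drug moves wells along the spiky-to-round axis: the
#' positive-class (MET-like) effect follows a 4PL in log10 molar
#' concentration, and doses above `tox_threshold` (if finite) kill the well,
#' rendering it media-like.
#'
#' @param drug_id Drug identifier.
#' @param top,bottom 4PL asymptotes of the reprogramming effect, in \[0,1\]
#'   with `bottom <= top`.
#' @param log10_ec50 Log10 molar EC50.
#' @param hill Hill slope (positive = effect grows with dose).
#' @param tox_threshold Log10 molar concentration above which wells become
#'   media-like, or `NA` for no toxicity.
#' @return A `ground_truth_dose` list.
#' @export
ground_truth_dose <- function(drug_id, top = 1, bottom = 0, log10_ec50 = -7,
                              hill = 1, tox_threshold = NA_real_) {
  stop_if_not_finite(top, "top"); stop_if_not_finite(bottom, "bottom")
  stop_if_not_finite(log10_ec50, "log10_ec50"); stop_if_not_finite(hill, "hill")
  if (bottom > top) stop("bottom must be <= top", call. = FALSE)
  if (top < 0 || top > 1 || bottom < 0 || bottom > 1) {
    stop("top and bottom must lie in [0,1]", call. = FALSE)
  }
  structure(list(drug_id = as.character(drug_id), top = top, bottom = bottom,
                 log10_ec50 = log10_ec50, hill = hill,
                 tox_threshold = tox_threshold),
            class = "ground_truth_dose")
}

# Render one organoid (disc + radial triangular spikes) into a darkness
# layer restricted to its bounding box. Returns list(rows, cols, coverage).
render_organoid <- function(cx, cy, params, size) {
  r <- params$organoid_radius_px
  len <- params$spikiness * params$spike_length_px
  pad <- ceiling(r + len + 3)
  rows <- max(1L, floor(cx - pad)):min(size[1], ceiling(cx + pad))
  cols <- max(1L, floor(cy - pad)):min(size[2], ceiling(cy + pad))
  dx <- rows - cx
  dy <- cols - cy
  DX <- matrix(dx, nrow = length(rows), ncol = length(cols))
  DY <- matrix(dy, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  rho <- sqrt(DX^2 + DY^2)
  cov <- clip01(r + 0.5 - rho)               # antialiased disc
  # interior cell texture (fine speckle) and a darker rim: bright-field
  # organoids are not flat plateaus, and these sub-ball-scale structures
  # are what survives rolling-ball background subtraction downstream
  speckle <- matrix(runif(length(cov), 0.55, 1.45), nrow(cov), ncol(cov))
  rim <- clip01(1 - abs(rho - (r - 2)) / 3)
  darkness <- cov * (0.75 * speckle) + 0.45 * rim
  if (len > 0 && params$n_spikes > 0) {
    phi <- atan2(DY, DX)
    theta <- runif(params$n_spikes, -pi, pi) # spike directions
    base_w <- max(4, r * 0.4)                # base width in px
    r0 <- r - 2                              # spike root just inside disc
    taper <- clip01(1 - (rho - r0) / len)    # 1 at root -> 0 at tip
    radial_ok <- rho >= r0 & rho <= r0 + len
    for (th in theta) {
      d_ang <- abs(((phi - th + pi) %% (2 * pi)) - pi)   # wrapped angle diff
      arc <- d_ang * pmax(rho, 1)                        # arc distance, px
      halfw <- (base_w / 2) * taper
      cov_spike <- clip01(halfw - arc + 0.5)
      cov_spike[!radial_ok] <- 0
      cov <- pmax(cov, cov_spike)
      darkness <- pmax(darkness, cov_spike)
    }
  }
  list(rows = rows, cols = cols, coverage = cov, darkness = clip01(darkness))
}

#' Simulate one well's projected bright-field image
#'
#' Renders `n_organoids` dark organoids (discs with `n_spikes` radial
#' protrusions scaled by `spikiness`) on a bright noisy background, placed
#' by seeded rejection sampling so organoids do not overlap. Deterministic
#' for a fixed seed.
#'
#' @param params A [phenotype_params()].
#' @param seed Integer seed (mandatory).
#' @param size Image dimensions `c(height, width)`, each >= 64.
#' @return An `organo_scene`: unit-intensity image matrix in \[0,1\], logical
#'   foreground `mask`, integer `labels` matrix (organoid index, 0 =
#'   background), per-organoid darkness `layers`, and generation metadata.
#' @export
#' @examples
#' sc <- simulate_well_image(phenotype_params(spikiness = 0, n_organoids = 3),
#'                           seed = 1, size = c(128, 128))
#' range(sc$image)
simulate_well_image <- function(params, seed, size = c(512L, 512L)) {
  stopifnot(inherits(params, "phenotype_params"))
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 64L)) {
    stop("size must be at least 64x64", call. = FALSE)
  }
  with_seed(seed, {
    bg <- 0.85
    depth <- 0.55
    noise <- matrix(rnorm(prod(size), 0, params$noise_sd), size[1], size[2])
    layers <- list()
    mask <- matrix(FALSE, size[1], size[2])
    labels <- matrix(0L, size[1], size[2])
    n <- params$n_organoids
    if (n > 0L) {
      r <- params$organoid_radius_px
      len <- params$spikiness * params$spike_length_px
      margin <- r + len + 4
      if (any(size < 2 * margin + 2)) {
        stop(sprintf(
          "size %dx%d too small for organoid geometry (radius %.0f + spikes %.0f); enlarge size or shrink organoids",
          size[1], size[2], r, len), call. = FALSE)
      }
      min_dist <- 2 * r + len + 4
      centers <- matrix(NA_real_, n, 2)
      placed <- 0L
      attempts <- 0L
      while (placed < n) {
        attempts <- attempts + 1L
        if (attempts > 20000L) {
          stop("could not place organoids; reduce n_organoids or enlarge size",
               call. = FALSE)
        }
        # relax the spacing requirement gradually so dense layouts on small
        # canvases still place; partially merged organoids are acceptable
        # (mesenchymal organoids interconnect in real plates)
        if (attempts %% 200L == 0L) min_dist <- max(min_dist * 0.85, r)
        cand <- c(runif(1, margin, size[1] - margin),
                  runif(1, margin, size[2] - margin))
        if (placed == 0L ||
            all(sqrt(rowSums((centers[seq_len(placed), , drop = FALSE] -
                              matrix(cand, placed, 2, byrow = TRUE))^2)) >= min_dist)) {
          placed <- placed + 1L
          centers[placed, ] <- cand
        }
      }
      for (i in seq_len(n)) {
        org <- render_organoid(centers[i, 1], centers[i, 2], params, size)
        # layers are kept bbox-sparse; expand_layer() rebuilds full frames
        layers[[i]] <- list(rows = org$rows, cols = org$cols,
                            darkness = org$darkness * depth)
        sel <- org$coverage > 0.5
        blk_mask <- mask[org$rows, org$cols]
        blk_lab <- labels[org$rows, org$cols]
        blk_mask[sel] <- TRUE
        blk_lab[sel] <- i
        mask[org$rows, org$cols] <- blk_mask
        labels[org$rows, org$cols] <- blk_lab
      }
    }
    img <- bg + noise
    for (layer in layers) {
      img[layer$rows, layer$cols] <- img[layer$rows, layer$cols] -
        layer$darkness
    }
    structure(list(image = clip01(img), mask = mask, labels = labels,
                   layers = layers, background = bg, noise = noise,
                   params = params, seed = as.integer(seed), size = size),
              class = "organo_scene")
  })
}

#' @export
print.organo_scene <- function(x, ...) {
  cat(sprintf("<organo_scene> %dx%d, %d organoid(s), spikiness %.2f, seed %d\n",
              x$size[1], x$size[2], x$params$n_organoids,
              x$params$spikiness, x$seed))
  invisible(x)
}

# Quantize a unit-intensity matrix to grey levels at the given bit depth.
quantize_grey <- function(img, bit_depth = 8L) {
  round(clip01(img) * (2^bit_depth - 1))
}

# Rebuild a full-frame darkness matrix from a bbox-sparse organoid layer.
expand_layer <- function(layer, size) {
  full <- matrix(0, size[1], size[2])
  full[layer$rows, layer$cols] <- layer$darkness
  full
}

#' Simulate a defocused bright-field z-stack from a scene
#'
#' Each organoid is assigned a focal slice; away from it, its darkness layer
#' is Gaussian-blurred with sigma growing linearly with slice distance
#' (`blur_scale` pixels per slice), emulating a z-stack sampled through a
#' ~1 mm Matrigel layer. Slice indices are 1-based. With `n_slices = 1` the
#' single slice reproduces the scene exactly.
#'
#' @param scene An `organo_scene` from [simulate_well_image()].
#' @param n_slices Number of slices (default 18, the acquisition depth of
#'   the screen's bright-field protocol).
#' @param focus_slices Integer vector, one focal slice per organoid, each in
#'   `1..n_slices`. Default: all organoids focused at the middle slice.
#' @param blur_scale Defocus blur growth, sigma pixels per slice of distance.
#' @param slice_spacing_um Physical slice spacing (metadata).
#' @return A [zstack()] in 8-bit grey levels.
#' @export
simulate_zstack <- function(scene, n_slices = 18L, focus_slices = NULL,
                            blur_scale = 1.5, slice_spacing_um = 100) {
  stopifnot(inherits(scene, "organo_scene"))
  n_slices <- as.integer(n_slices)
  if (length(n_slices) != 1L || n_slices < 1L) {
    stop("n_slices must be a positive integer", call. = FALSE)
  }
  n_org <- length(scene$layers)
  if (is.null(focus_slices)) {
    focus_slices <- rep(as.integer(ceiling(n_slices / 2)), n_org)
  }
  focus_slices <- as.integer(focus_slices)
  if (n_org > 0 && (length(focus_slices) != n_org ||
                    any(focus_slices < 1L | focus_slices > n_slices))) {
    stop("focus_slices must give one slice in 1..n_slices per organoid",
         call. = FALSE)
  }
  vox <- array(0, dim = c(scene$size[1], scene$size[2], n_slices))
  base <- scene$background + scene$noise
  for (s in seq_len(n_slices)) {
    slice <- base
    # Gaussian kernel must fit inside the image; beyond this the layer is
    # effectively featureless anyway
    sigma_cap <- (min(scene$size) - 3) / 7
    for (i in seq_len(n_org)) {
      sigma <- min(blur_scale * abs(s - focus_slices[i]), sigma_cap)
      layer <- expand_layer(scene$layers[[i]], scene$size)
      if (sigma > 0) {
        layer <- as.matrix(EBImage::gblur(EBImage::as.Image(layer),
                                          sigma = sigma))
      }
      slice <- slice - layer
    }
    vox[, , s] <- quantize_grey(slice)
  }
  zstack(vox, slice_spacing_um = slice_spacing_um, bit_depth = 8L,
         focus_slices = focus_slices)
}

#' Simulate a full screening plate with known ground truth
#'
#' Control wells follow the screen's reference phenotypes: negative
#' (DMSO-like) wells are fully spiky, positive (MET-induced) wells fully
#' round, media wells empty. Each treatment well's spikiness is
#' `1 - 4PL(concentration)` under that drug's ground-truth parameters, and
#' doses above the drug's toxicity threshold become media-like. A single
#' plate seed is forked per well by well index so generation is
#' order-independent and bit-reproducible.
#'
#' @param layout A [plate_map()] (e.g. [default_screen_layout()]).
#' @param doses List of [ground_truth_dose()] covering every drug in the
#'   layout.
#' @param seed Plate seed.
#' @param params Baseline [phenotype_params()] (spikiness is overridden per
#'   well).
#' @param size Image size per well.
#' @param n_slices If > 1, each well is emitted as a defocused z-stack with
#'   seeded random focal slices; otherwise as the projected scene.
#' @return List with `records` (well metadata plus ground truth columns
#'   `spikiness_truth`, `n_organoids_truth`, `well_seed`), `images` (named
#'   list of `organo_scene` or `zstack`), `doses`, and `seed`.
#' @export
simulate_plate <- function(layout, doses = list(), seed,
                           params = phenotype_params(),
                           size = c(512L, 512L), n_slices = 1L) {
  records <- plate_ground_truth(layout, doses, seed, params)
  images <- vector("list", nrow(records))
  names(images) <- records$well
  for (i in seq_len(nrow(records))) {
    images[[i]] <- render_well(records[i, ], params, size = size,
                               n_slices = n_slices)
  }
  list(records = records, images = images, doses = doses,
       seed = as.integer(seed))
}

#' Ground-truth well records for a plate, without rendering
#'
#' Computes each well's true spikiness and organoid count under the layout,
#' the drugs' ground-truth dose-response parameters, and the plate seed,
#' exactly as [simulate_plate()] would, but without producing any image.
#' Together with [render_well()] this allows memory-light streaming over
#' large plates.
#'
#' @inheritParams simulate_plate
#' @return Data frame of well records with `spikiness_truth`,
#'   `n_organoids_truth` and `well_seed` columns.
#' @export
plate_ground_truth <- function(layout, doses = list(), seed,
                               params = phenotype_params()) {
  stopifnot(inherits(layout, "plate_map"))
  dose_ids <- vapply(doses, function(d) d$drug_id, "")
  need <- unique(layout$drug_id[layout$role == "treatment"])
  missing <- setdiff(need, dose_ids)
  if (length(missing)) {
    stop("no ground-truth dose parameters for drug(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(layout)
  records$spikiness_truth <- NA_real_
  records$n_organoids_truth <- params$n_organoids
  records$well_seed <- fork_seed(seed, seq_len(nrow(records)))
  for (i in seq_len(nrow(records))) {
    role <- records$role[i]
    if (role == "negative") {
      s <- 1; n_org <- params$n_organoids
    } else if (role == "positive") {
      s <- 0; n_org <- params$n_organoids
    } else if (role == "media") {
      s <- 0; n_org <- 0L
    } else {
      d <- doses[[match(records$drug_id[i], dose_ids)]]
      lc <- log10(records$concentration_molar[i])
      if (!is.na(d$tox_threshold) && lc > d$tox_threshold) {
        s <- 0; n_org <- 0L
      } else {
        s <- clip01(1 - fourpl(lc, d$top, d$bottom, d$log10_ec50, d$hill))
        n_org <- params$n_organoids
      }
    }
    records$spikiness_truth[i] <- if (n_org == 0L) NA_real_ else s
    records$n_organoids_truth[i] <- n_org
  }
  records
}

#' Render one well from its ground-truth record
#'
#' @param record One row of [plate_ground_truth()] output.
#' @param params Baseline [phenotype_params()].
#' @param size Image size.
#' @param n_slices If > 1, a defocused z-stack with seeded random focal
#'   slices; otherwise the projected scene.
#' @return An `organo_scene` or [zstack()].
#' @export
render_well <- function(record, params = phenotype_params(),
                        size = c(512L, 512L), n_slices = 1L) {
  s <- record$spikiness_truth
  n_org <- record$n_organoids_truth
  wp <- phenotype_params(spikiness = if (is.na(s)) 0 else s,
                         n_organoids = n_org,
                         organoid_radius_px = params$organoid_radius_px,
                         n_spikes = params$n_spikes,
                         spike_length_px = params$spike_length_px,
                         noise_sd = params$noise_sd)
  scene <- simulate_well_image(wp, seed = record$well_seed, size = size)
  if (n_slices > 1L) {
    n_org_i <- length(scene$layers)
    focus <- if (n_org_i > 0) {
      with_seed(record$well_seed + 1L,
                sample.int(n_slices, n_org_i, replace = TRUE))
    } else integer()
    simulate_zstack(scene, n_slices = n_slices, focus_slices = focus)
  } else scene
}

#' Write a simulated plate to disk
#'
#' Emits one TIFF per well (multi-page for z-stacks, single-page 8-bit for
#' projected scenes), a metadata CSV, and a ground-truth JSON of the dose
#' parameters.
#'
#' @param sim Result of [simulate_plate()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_plate_images <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (w in names(sim$images)) {
    obj <- sim$images[[w]]
    path <- file.path(dir, paste0(sim$records$plate_id[1], "_", w, ".tif"))
    if (inherits(obj, "zstack")) {
      write_zstack(obj, path)
    } else {
      tiff::writeTIFF(quantize_grey(obj$image) / 255, path,
                      bits.per.sample = 8L)
    }
  }
  meta <- sim$records
  meta$seed <- sim$seed
  write.csv(meta, file.path(dir, "well_metadata.csv"), row.names = FALSE)
  jsonlite::write_json(
    lapply(sim$doses, function(d) unclass(d)),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
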