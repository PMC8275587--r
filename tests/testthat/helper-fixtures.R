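# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code from explicit seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Control-only plate (16 wells per role) at reduced canvas for unit tests;
# the acceptance suite re-runs the same layout at full simulator defaults.
fixture_control_features <- function() {
  cached("control_features_256", {
    sim <- simulate_plate(default_screen_layout(), seed = 42,
                          size = c(256L, 256L))
    embed_wells(sim$images, sim$records)
  })
}

# Control-only plate at the simulator's full default geometry (512 px,
# 16 wells per role), shared by the acceptance checks.
fixture_control_features_full <- function() {
  cached("control_features_512", {
    sim <- simulate_plate(default_screen_layout(), seed = 101)
    embed_wells(sim$images, sim$records)
  })
}

# 40 projected well images: 20 spiky (EMT-like) + 20 round (MET-like),
# embedded with the default extractor.
fixture_two_class_embeddings <- function() {
  cached("two_class_40", {
    ex <- make_extractor()
    embed_one <- function(spikiness, seed) {
      sc <- simulate_well_image(
        phenotype_params(spikiness = spikiness, n_organoids = 3L,
                         organoid_radius_px = 18, spike_length_px = 20),
        seed = seed, size = c(128L, 128L))
      embed_image(preprocess_stack(sc), ex)
    }
    spiky <- t(vapply(1:20, function(s) embed_one(1, s), numeric(ex$length)))
    round_ <- t(vapply(21:40, function(s) embed_one(0, s), numeric(ex$length)))
    list(spiky = spiky, round = round_, extractor = ex)
  })
}

# Well-separated synthetic control features (no images): three Gaussian
# clusters in 8 dimensions, 16 wells per role.
make_gaussian_controls <- function(seed, n_per_role = 16L, sep = 10,
                                   sd = 1, dims = 8L) {
  roles <- rep(c("negative", "positive", "media"), each = n_per_role)
  centers <- rbind(negative = c(rep(sep, dims / 2), rep(0, dims / 2)),
                   positive = c(rep(0, dims / 2), rep(sep, dims / 2)),
                   media = rep(-sep, dims))
  X <- with_seed(seed, {
    t(vapply(roles, function(r) centers[r, ] + rnorm(dims, 0, sd),
             numeric(dims)))
  })
  colnames(X) <- sprintf("f%04d", seq_len(dims))
  df <- data.frame(plate_id = "GP1", well = paste0("A", seq_along(roles)),
                   role = roles, batch = "GB1", stringsAsFactors = FALSE)
  df$well <- paste0(rep(LETTERS[1:3], each = n_per_role),
                    rep(seq_len(n_per_role), times = 3))
  cbind(df, as.data.frame(X))
}

# Brute-force k-NN oracle: all-pairs distances, full sort, vote fractions.
knn_oracle <- function(X, labels, query, k) {
  d <- apply(X, 1, function(row) sqrt(sum((row - query)^2)))
  ord <- order(d, seq_along(d))
  nb <- ord[seq_len(k)]
  counts <- table(factor(labels[nb], levels = c("negative", "positive",
                                                "media")))
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1) {
    md <- vapply(top, function(cl) mean(d[nb[labels[nb] == cl]]), 0)
    top <- top[md == min(md)]
    top <- top[order(match(top, c("negative", "positive", "media")))]
  }
  list(counts = as.integer(counts), label = top[1])
}

# Brute-force focus-projection oracle: per-pixel windowed Laplacian energy
# computed with explicit loops and replicated borders.
focus_oracle <- function(vox, window) {
  d <- dim(vox)
  half <- (window - 1) / 2
  pad_idx <- function(i, n) pmin(pmax(i, 1L), n)
  energy <- array(0, dim = d)
  for (s in seq_len(d[3])) {
    sl <- vox[, , s]
    lap <- matrix(0, d[1], d[2])
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        lap[i, j] <- sl[pad_idx(i - 1, d[1]), j] + sl[pad_idx(i + 1, d[1]), j] +
          sl[i, pad_idx(j - 1, d[2])] + sl[i, pad_idx(j + 1, d[2])] -
          4 * sl[i, j]
      }
    }
    l2 <- lap^2
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        ii <- pad_idx((i - half):(i + half), d[1])
        jj <- pad_idx((j - half):(j + half), d[2])
        energy[i, j, s] <- sum(l2[ii, jj])
      }
    }
  }
  fmap <- apply(energy, c(1, 2), which.max)   # which.max: lowest index on tie
  pixels <- matrix(0, d[1], d[2])
  for (s in seq_len(d[3])) {
    sel <- fmap == s
    sl <- vox[, , s]
    pixels[sel] <- sl[sel]
  }
  list(pixels = pixels, fmap = fmap)
}

# Brute-force grayscale opening with a non-flat ball structuring element
# and replicated borders (background oracle for rolling-ball subtraction).
opening_oracle <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  offs <- offs[offs$dx^2 + offs$dy^2 <= radius^2, ]
  offs$h <- sqrt(radius^2 - offs$dx^2 - offs$dy^2)
  clampi <- function(i, n) pmin(pmax(i, 1L), n)
  eroded <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- clampi(i + offs$dx, nr); jj <- clampi(j + offs$dy, nc)
    eroded[i, j] <- min(img[cbind(ii, jj)] - offs$h)
  }
  opened <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- clampi(i + offs$dx, nr); jj <- clampi(j + offs$dy, nc)
    opened[i, j] <- max(eroded[cbind(ii, jj)] + offs$h)
  }
  opened
}

# Solidity of each labelled mask component: pixel count / convex hull area
# (shoelace on the hull of pixel centers, corrected by +perimeter/2+1 to
# approximate the pixelated hull area).
component_solidity <- function(labels) {
  ids <- setdiff(unique(as.vector(labels)), 0L)
  vapply(ids, function(id) {
    px <- which(labels == id, arr.ind = TRUE)
    hull <- grDevices::chull(px)
    hp <- px[hull, , drop = FALSE]
    n <- nrow(hp)
    area <- abs(sum(hp[, 1] * hp[c(2:n, 1), 2] - hp[c(2:n, 1), 1] * hp[, 2])) / 2
    per <- sum(sqrt(rowSums((hp - hp[c(2:n, 1), , drop = FALSE])^2)))
    nrow(px) / (area + per / 2 + 1)
  }, 0)
}

# Mean Laplacian energy of a whole slice (window-free sharpness summary).
slice_sharpness <- function(slice) {
  d <- dim(slice)
  lap <- slice[c(2:d[1], d[1]), ] + slice[c(1, 1:(d[1] - 1)), ] +
    slice[, c(2:d[2], d[2])] + slice[, c(1, 1:(d[2] - 1))] - 4 * slice
  mean(lap^2)
}
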