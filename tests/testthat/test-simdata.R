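test_that("phenotype parameters are validated and spikes collapse for round organoids", {
  expect_error(phenotype_params(spikiness = NA), "spikiness")
  expect_error(phenotype_params(spikiness = 1.5), "spikiness")
  expect_error(phenotype_params(noise_sd = -1), "noise_sd")
  expect_error(phenotype_params(organoid_radius_px = 0), "organoid_radius_px")
  p <- phenotype_params(spikiness = 0, spike_length_px = 36)
  expect_identical(p$spike_length_px, 0)
  expect_equal(phenotype_params(n_organoids = 0)$n_organoids, 0L)
})

test_that("round organoids are high-solidity discs; media wells carry no foreground", {
  sc <- simulate_well_image(phenotype_params(spikiness = 0, n_organoids = 3L),
                            seed = 1, size = c(256L, 256L))
  sol <- component_solidity(sc$labels)
  expect_length(sol, 3L)
  expect_true(all(sol > 0.95))

  spiky <- simulate_well_image(phenotype_params(spikiness = 1, n_organoids = 3L),
                               seed = 1, size = c(256L, 256L))
  expect_true(all(component_solidity(spiky$labels) < min(sol)))

  media <- simulate_well_image(phenotype_params(n_organoids = 0L), seed = 2,
                               size = c(128L, 128L))
  expect_identical(sum(media$mask), 0L)
  # background + noise only: intensities concentrate near the background level
  expect_lt(diff(range(media$image)), 0.4)
})

test_that("well images are bit-identical for a fixed seed and differ across seeds", {
  p <- phenotype_params(n_organoids = 2L, organoid_radius_px = 15,
                        spike_length_px = 14)
  a <- simulate_well_image(p, seed = 7, size = c(128L, 128L))
  b <- simulate_well_image(p, seed = 7, size = c(128L, 128L))
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)
  c_ <- simulate_well_image(p, seed = 8, size = c(128L, 128L))
  expect_false(identical(a$image, c_$image))
})

test_that("rejects invalid sizes and non-finite parameters", {
  p <- phenotype_params()
  expect_error(simulate_well_image(p, seed = 1, size = c(32L, 32L)), "64x64")
  expect_error(simulate_well_image(p, seed = 1, size = c(100L, 100L)),
               "too small")
})

test_that("z-stack slices are sharpest at the assigned focal slice", {
  sc <- simulate_well_image(
    phenotype_params(n_organoids = 2L, organoid_radius_px = 16,
                     spike_length_px = 14, noise_sd = 0),
    seed = 3, size = c(128L, 128L))

  # single slice reproduces the quantized scene exactly
  st1 <- simulate_zstack(sc, n_slices = 1L, focus_slices = c(1L, 1L))
  expect_identical(st1$voxels[, , 1], round(sc$image * 255))

  expect_error(simulate_zstack(sc, n_slices = 0L), "positive")
  expect_error(simulate_zstack(sc, n_slices = 4L, focus_slices = c(1L, 9L)),
               "focus_slices")

  # all organoids focused at slice 7 of 18: global sharpness peaks there
  st <- simulate_zstack(sc, n_slices = 18L, focus_slices = c(7L, 7L))
  energy <- vapply(1:18, function(s) slice_sharpness(st$voxels[, , s]), 0)
  expect_identical(which.max(energy), 7L)

  # organoids focused at slices 2 and 15: per-organoid sharpest slice
  # matches the assignment
  st2 <- simulate_zstack(sc, n_slices = 18L, focus_slices = c(2L, 15L))
  for (org in 1:2) {
    sel <- sc$labels == org
    px <- which(sel, arr.ind = TRUE)
    rr <- range(px[, 1]); cc <- range(px[, 2])
    e_org <- vapply(1:18, function(s) {
      slice_sharpness(st2$voxels[rr[1]:rr[2], cc[1]:cc[2], s])
    }, 0)
    expect_identical(which.max(e_org), c(2L, 15L)[org])
  }
})

test_that("simulated plates honour layout roles and ground-truth dose response", {
  pm <- default_screen_layout(drugs = c("d1", "d2"),
                              concentrations = 10^seq(-6, -8.5, by = -0.5),
                              replicates = 1L)
  doses <- list(ground_truth_dose("d1", log10_ec50 = -7.5, hill = 1),
                ground_truth_dose("d2", log10_ec50 = -7.5, hill = 1,
                                  tox_threshold = -6.5))
  sim <- simulate_plate(pm, doses, seed = 9, size = c(256L, 256L),
                        params = phenotype_params(n_organoids = 2L))
  rec <- sim$records
  expect_equal(sum(rec$role == "negative"), 16L)
  expect_equal(sum(rec$role == "positive"), 16L)
  expect_equal(sum(rec$role == "media"), 16L)
  expect_true(all(rec$spikiness_truth[rec$role == "negative"] == 1))
  expect_true(all(rec$spikiness_truth[rec$role == "positive"] == 0))
  expect_true(all(is.na(rec$spikiness_truth[rec$role == "media"])))

  # monotone ground truth below the toxicity threshold
  for (d in c("d1", "d2")) {
    sub <- rec[rec$role == "treatment" & rec$drug_id == d, ]
    sub <- sub[order(sub$concentration_molar), ]
    live <- !is.na(sub$spikiness_truth)
    expect_true(all(diff(sub$spikiness_truth[live]) <= 1e-12))
  }
  # toxic drug: doses above threshold are media-like (empty wells)
  d2 <- rec[rec$role == "treatment" & rec$drug_id == "d2", ]
  hot <- log10(d2$concentration_molar) > -6.5
  expect_true(all(d2$n_organoids_truth[hot] == 0L))
  expect_true(all(d2$n_organoids_truth[!hot] > 0L))
  # media-like wells truly have empty masks
  w <- d2$well[hot][1]
  expect_identical(sum(sim$images[[w]]$mask), 0L)

  # fixed seed => bit-identical plates
  sim2 <- simulate_plate(pm, doses, seed = 9, size = c(256L, 256L),
                         params = phenotype_params(n_organoids = 2L))
  expect_identical(sim$images[[w]]$image, sim2$images[[w]]$image)
  expect_identical(sim$records, sim2$records)

  # missing dose parameters are rejected
  expect_error(simulate_plate(pm, doses[1], seed = 9, size = c(256L, 256L)),
               "d2")
})

test_that("high-dose saturation of a full reprogramming drug is positive-like", {
  pm <- default_screen_layout(drugs = "d1",
                              concentrations = c(1e-9, 1e-4),
                              replicates = 1L)
  sim <- simulate_plate(pm, list(ground_truth_dose("d1", top = 1, bottom = 0,
                                                   log10_ec50 = -7)),
                        seed = 4, size = c(256L, 256L),
                        params = phenotype_params(n_organoids = 2L))
  rec <- sim$records[sim$records$role == "treatment", ]
  hi <- rec[rec$concentration_molar == 1e-4, ]
  expect_lt(hi$spikiness_truth, 0.01)   # c >> EC50: essentially round
  lo <- rec[rec$concentration_molar == 1e-9, ]
  expect_gt(lo$spikiness_truth, 0.98)
})

test_that("plate export writes TIFFs, metadata and ground truth", {
  pm <- plate_map(data.frame(well = c("A1", "A2", "B1", "B2"),
                             role = c("negative", "positive", "media",
                                      "negative")))
  sim <- simulate_plate(pm, seed = 5, size = c(96L, 96L),
                        params = phenotype_params(
                          n_organoids = 1L, organoid_radius_px = 12,
                          spike_length_px = 10))
  dir <- withr::local_tempdir()
  write_plate_images(sim, dir)
  expect_true(file.exists(file.path(dir, "well_metadata.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  tifs <- list.files(dir, pattern = "\\.tif$")
  expect_length(tifs, 4L)
  back <- read_zstack(file.path(dir, tifs[1]))
  expect_identical(dim(back$voxels)[1:2], c(96L, 96L))
})
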