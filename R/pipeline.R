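# End-to-end orchestration: simulate (or load) -> preprocess -> embed ->
# QC/classify -> dose-response, with every stage's parameters and seeds
# captured in a run manifest so any numerical output is traceable.

#' Build a validated run configuration
#'
#' All seeds are explicit; a configuration without a seed is rejected
#' before any stage executes. Concentrations are molar.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Master seed; per-plate and per-well seeds are forked from
#'   it.
#' @param plates List of plate descriptors `list(plate_id, batch, drugs)`;
#'   each plate gets the default screen layout (16 wells per control role).
#' @param doses List of [ground_truth_dose()] covering all drugs.
#' @param concentrations Tested molar concentrations per drug (default ten
#'   half-log dilutions from 10 uM).
#' @param replicates Technical replicates per concentration (default 4).
#' @param extractor Extractor kind (see [make_extractor()]).
#' @param radius_px,sharpness_window_px Preprocessing parameters.
#' @param k,split_fraction,qc_threshold Classification parameters.
#' @param image_size,n_slices Simulation geometry.
#' @param phenotype Baseline [phenotype_params()] for simulated wells.
#' @param write_images Also write per-well TIFFs (slower; default FALSE).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed, plates, doses = list(),
                       concentrations = 10^seq(-5, by = -0.5,
                                               length.out = 10),
                       replicates = 4L, extractor = "handcrafted",
                       radius_px = 10L, sharpness_window_px = 11L,
                       k = 6L, split_fraction = 0.5, qc_threshold = 0.8,
                       image_size = c(512L, 512L), n_slices = 1L,
                       phenotype = phenotype_params(),
                       write_images = FALSE) {
  if (missing(seed) || is.null(seed)) {
    stop("run configuration must specify an explicit seed", call. = FALSE)
  }
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), plates = plates,
              doses = doses, concentrations = concentrations,
              replicates = as.integer(replicates), extractor = extractor,
              radius_px = as.integer(radius_px),
              sharpness_window_px = as.integer(sharpness_window_px),
              k = as.integer(k), split_fraction = split_fraction,
              qc_threshold = qc_threshold,
              image_size = as.integer(image_size),
              n_slices = as.integer(n_slices),
              phenotype = phenotype,
              write_images = isTRUE(write_images))
  structure(cfg, class = "run_config")
}

#' Run the full screening pipeline on simulated plates
#'
#' Stages: simulate -> preprocess+embed -> control QC (batch and
#' cumulative k-NN models) -> classification of treated wells ->
#' dose-response scoring and hit ranking. All tabular outputs are written
#' as CSV under `config$out_dir` together with `manifest.json` recording
#' the package version, the full configuration and its checksum. Reruns
#' with an identical configuration reproduce identical CSVs.
#'
#' @param config A [run_config()].
#' @return List: `features`, `qc` (from [train_levels()]), `probabilities`,
#'   `hits` (ranked, when drugs are present), `manifest`.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(out_dir = tempfile(), seed = 11,
#'                   plates = list(list(plate_id = "P1", batch = "B1",
#'                                      drugs = "drugA")),
#'                   doses = list(ground_truth_dose("drugA",
#'                                                  log10_ec50 = -7)),
#'                   concentrations = 10^seq(-5, -9.5, by = -0.5),
#'                   image_size = c(128, 128))
#' res <- run_pipeline(cfg)
#' res$qc$cumulative_qc$accuracy
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  extractor <- make_extractor(config$extractor)

  # --- simulate ---------------------------------------------------------
  feats <- NULL
  all_records <- NULL
  for (p in seq_along(config$plates)) {
    pl <- config$plates[[p]]
    layout <- default_screen_layout(
      drugs = pl$drugs %||% character(),
      concentrations = config$concentrations,
      replicates = config$replicates,
      plate_id = pl$plate_id, batch = pl$batch %||% pl$plate_id)
    records <- plate_ground_truth(layout, doses = config$doses,
                                  seed = fork_seed(config$seed, p),
                                  params = config$phenotype)
    # --- preprocess + embed, streaming one well at a time ---------------
    img_dir <- file.path(config$out_dir, pl$plate_id)
    if (config$write_images) {
      dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
    }
    fmat <- matrix(NA_real_, nrow(records), extractor$length)
    for (i in seq_len(nrow(records))) {
      well_img <- render_well(records[i, ], config$phenotype,
                              size = config$image_size,
                              n_slices = config$n_slices)
      if (config$write_images) {
        path <- file.path(img_dir, paste0(pl$plate_id, "_",
                                          records$well[i], ".tif"))
        if (inherits(well_img, "zstack")) {
          write_zstack(well_img, path)
        } else {
          tiff::writeTIFF(quantize_grey(well_img$image) / 255, path,
                          bits.per.sample = 8L)
        }
      }
      proj <- preprocess_stack(well_img, radius_px = config$radius_px,
                               sharpness_window_px = config$sharpness_window_px)
      fmat[i, ] <- embed_image(proj, extractor)
    }
    colnames(fmat) <- sprintf("f%04d", seq_len(extractor$length))
    meta <- records
    meta$extractor_id <- extractor$id
    feats <- rbind(feats, cbind(meta, as.data.frame(fmat)))
    all_records <- rbind(all_records, records)
  }
  write_features(feats, file.path(config$out_dir, "features.csv"))

  # --- control QC: batch + cumulative models ---------------------------
  qc <- train_levels(feats, k = config$k, fraction = config$split_fraction,
                     qc_threshold = config$qc_threshold,
                     seed = config$seed)
  write_qc_report(qc$cumulative_qc, config$out_dir, prefix = "qc_cumulative")
  for (b in names(qc$batch)) {
    write_qc_report(qc$batch[[b]]$qc, config$out_dir,
                    prefix = paste0("qc_batch_", b))
  }

  # --- classify treated wells ------------------------------------------
  trt <- feats[feats$role == "treatment", , drop = FALSE]
  probs <- NULL
  hits <- NULL
  if (nrow(trt)) {
    probs <- classify_wells(qc$cumulative, trt)
    write.csv(probs, file.path(config$out_dir, "probabilities.csv"),
              row.names = FALSE)
    # --- dose-response ranking -----------------------------------------
    act <- drug_activity(probs)
    if (nrow(act) >= 2L) {
      hits <- rank_hits(act)
    } else {
      hits <- act
      hits$rank <- 1L
      attr(hits, "cluster_order") <- act$drug_id
    }
    write.csv(hits, file.path(config$out_dir, "hits.csv"), row.names = FALSE)
    write.csv(data.frame(order = seq_along(attr(hits, "cluster_order")),
                         drug_id = attr(hits, "cluster_order")),
              file.path(config$out_dir, "heatmap_row_order.csv"),
              row.names = FALSE)
  }

  # --- manifest ---------------------------------------------------------
  cfg_plain <- unclass(config)
  cfg_plain$doses <- lapply(cfg_plain$doses, unclass)
  cfg_plain$phenotype <- unclass(cfg_plain$phenotype)
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE,
                               digits = NA, null = "null", na = "null")
  cfg_path <- file.path(config$out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- list(
    package = "organoscreen",
    version = as.character(utils::packageVersion("organoscreen")),
    extractor_id = extractor$id,
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = c("features.csv", "probabilities.csv", "hits.csv",
                "heatmap_row_order.csv", "qc_cumulative_confusion.csv"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(features = feats, qc = qc, probabilities = probs, hits = hits,
       manifest = manifest, records = all_records)
}
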