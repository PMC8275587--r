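# Plate-map handling for the 384-well screening geometry (rows A-P,
# columns 1-24). Control layout follows the screen design: 16 DMSO-treated
# negative wells (spiky, EMT-like), 16 dox-induced positive wells (round,
# MET-like) and 16 cell-free media wells (toxicity reference) per plate.

PLATE_ROWS <- LETTERS[1:16]
PLATE_COLS <- 1:24
WELL_ROLES <- c("negative", "positive", "media", "treatment")

#' Validate and normalize a 384-well coordinate
#'
#' Accepts row letter A-P plus 1-based column 1-24 ("A1".."P24").
#' Zero-padded columns ("A01") are normalized to the canonical form with a
#' warning; anything outside the grid is rejected.
#'
#' @param well Character vector of well ids.
#' @return Canonical well ids.
#' @export
#' @examples
#' normalize_well(c("A1", "P24"))
normalize_well <- function(well) {
  well <- toupper(trimws(as.character(well)))
  m <- regmatches(well, regexec("^([A-Z])0*([0-9]+)$", well))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed well coordinate(s): ", paste(well[bad], collapse = ", "),
         call. = FALSE)
  }
  row <- vapply(m, `[`, "", 2L)
  col <- as.integer(vapply(m, `[`, "", 3L))
  out_of_grid <- !(row %in% PLATE_ROWS) | col < 1L | col > 24L
  if (any(out_of_grid)) {
    stop("well coordinate(s) outside the 384-well grid (rows A-P, columns 1-24): ",
         paste(well[out_of_grid], collapse = ", "), call. = FALSE)
  }
  canonical <- paste0(row, col)
  padded <- canonical != well
  if (any(padded)) {
    warning("zero-padded well coordinate(s) normalized: ",
            paste(well[padded], "->", canonical[padded], collapse = ", "),
            call. = FALSE)
  }
  canonical
}

well_row <- function(well) match(substr(well, 1, 1), PLATE_ROWS)
well_col <- function(well) as.integer(substr(well, 2, nchar(well)))

#' Construct a plate map
#'
#' A plate map assigns a role (and for treatment wells a drug and molar
#' concentration) to each used well of a 384-well plate.
#'
#' @param wells Data frame with columns `well`, `role`, and for treatment
#'   wells `drug_id`, `concentration_molar`, `replicate`.
#' @param plate_id Plate identifier.
#' @param batch Batch (assay run) identifier; defaults to `plate_id`.
#' @return A `plate_map` object (data frame plus attributes).
#' @export
plate_map <- function(wells, plate_id = "plate1", batch = plate_id) {
  stopifnot(is.data.frame(wells), all(c("well", "role") %in% names(wells)))
  wells$well <- normalize_well(wells$well)
  dup <- duplicated(wells$well)
  if (any(dup)) {
    stop("well(s) assigned more than once: ",
         paste(unique(wells$well[dup]), collapse = ", "), call. = FALSE)
  }
  if (!all(wells$role %in% WELL_ROLES)) {
    stop("unknown role(s): ",
         paste(setdiff(unique(wells$role), WELL_ROLES), collapse = ", "),
         call. = FALSE)
  }
  if (!"drug_id" %in% names(wells)) wells$drug_id <- NA_character_
  if (!"concentration_molar" %in% names(wells)) wells$concentration_molar <- NA_real_
  if (!"replicate" %in% names(wells)) wells$replicate <- 1L
  trt <- wells$role == "treatment"
  if (any(trt & (is.na(wells$drug_id) | is.na(wells$concentration_molar)))) {
    stop("treatment wells must carry drug_id and concentration_molar", call. = FALSE)
  }
  if (any(trt & wells$concentration_molar <= 0)) {
    stop("concentrations must be strictly positive (molar)", call. = FALSE)
  }
  ctrl <- wells$role %in% c("negative", "positive", "media")
  wells$drug_id[ctrl] <- NA_character_
  wells$concentration_molar[ctrl] <- NA_real_
  wells$plate_id <- plate_id
  wells$batch <- batch
  ord <- order(well_row(wells$well), well_col(wells$well))
  wells <- wells[ord, c("plate_id", "well", "role", "drug_id",
                        "concentration_molar", "replicate", "batch")]
  rownames(wells) <- NULL
  structure(wells, class = c("plate_map", "data.frame"))
}

#' @export
print.plate_map <- function(x, ...) {
  counts <- table(factor(x$role, levels = WELL_ROLES))
  cat(sprintf("<plate_map> %s (batch %s): %d wells (%s)\n",
              x$plate_id[1], x$batch[1], nrow(x),
              paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")))
  invisible(x)
}

#' Default screen layout for one 384-well plate
#'
#' Places 16 wells of each control role (negative in column 1, positive in
#' column 2, media in column 23) and lays out each drug's dose series in the
#' remaining columns, row-major. Each drug occupies
#' `length(concentrations) * replicates` wells.
#'
#' @param drugs Character vector of drug ids (possibly empty).
#' @param concentrations Molar concentrations tested per drug; default ten
#'   half-log (3.3x) dilutions from 10 uM down.
#' @param replicates Technical replicates per concentration (default 4).
#' @param plate_id,batch Identifiers.
#' @return A [plate_map()].
#' @export
#' @examples
#' pm <- default_screen_layout(c("drugA", "drugB"))
#' table(pm$role)
default_screen_layout <- function(drugs = character(),
                                  concentrations = 10^seq(-5, by = -0.5,
                                                          length.out = 10),
                                  replicates = 4L,
                                  plate_id = "plate1", batch = plate_id) {
  stopifnot(all(concentrations > 0))
  ctrl <- data.frame(
    well = c(paste0(PLATE_ROWS, 1), paste0(PLATE_ROWS, 2), paste0(PLATE_ROWS, 23)),
    role = rep(c("negative", "positive", "media"), each = 16L),
    stringsAsFactors = FALSE
  )
  free <- as.vector(t(outer(PLATE_ROWS, c(3:22, 24), paste0)))
  n_per_drug <- length(concentrations) * replicates
  if (length(drugs) * n_per_drug > length(free)) {
    stop(sprintf("layout overflow: %d drugs x %d wells > %d free wells",
                 length(drugs), n_per_drug, length(free)), call. = FALSE)
  }
  trt <- NULL
  if (length(drugs)) {
    trt <- data.frame(
      well = free[seq_len(length(drugs) * n_per_drug)],
      role = "treatment",
      drug_id = rep(drugs, each = n_per_drug),
      concentration_molar = rep(rep(sort(concentrations), each = replicates),
                                times = length(drugs)),
      replicate = rep(seq_len(replicates),
                      times = length(drugs) * length(concentrations)),
      stringsAsFactors = FALSE
    )
    ctrl$drug_id <- NA_character_
    ctrl$concentration_molar <- NA_real_
    ctrl$replicate <- 1L
  }
  plate_map(rbind(ctrl, trt), plate_id = plate_id, batch = batch)
}

#' Read a plate map from CSV
#'
#' Expected columns: `well`, `role`, and optionally `drug_id`,
#' `concentration_molar`, `replicate`, `plate_id`, `batch`. Errors name the
#' offending well.
#'
#' @param path CSV file path.
#' @param plate_id,batch Defaults if the file has no such columns.
#' @return A [plate_map()].
#' @export
load_plate_map <- function(path, plate_id = NULL, batch = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("well", "role") %in% names(df))) {
    stop("plate map file must have 'well' and 'role' columns", call. = FALSE)
  }
  pid <- plate_id %||% (if ("plate_id" %in% names(df)) df$plate_id[1] else
    sub("\\.csv$", "", basename(path)))
  bat <- batch %||% (if ("batch" %in% names(df)) df$batch[1] else pid)
  plate_map(df[setdiff(names(df), c("plate_id", "batch"))],
            plate_id = pid, batch = bat)
}

#' Write a plate map to CSV
#' @param map A [plate_map()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_map <- function(map, path) {
  write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}
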