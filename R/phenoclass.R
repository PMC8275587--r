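# Control-anchored phenotype classification. Each plate carries three
# reference control classes (negative = spiky/EMT-like, positive =
# round/MET-like, media = cell-free); controls are split 50/50 per class
# into train/test halves, a k-NN model (k = 6 by default) is fit on the
# training half, and treated wells are mapped to controls via vote-fraction
# class probabilities. Assay quality is monitored from the withheld test
# half via confusion matrix and accuracy, per batch and cumulatively.

CONTROL_ROLES <- c("negative", "positive", "media")

control_rows <- function(records) records[records$role %in% CONTROL_ROLES, ,
                                          drop = FALSE]

#' Stratified 50/50 control split
#'
#' Randomly splits the control wells in half within each control class
#' (ceiling(fraction * n) to train, remainder to test), under an explicit
#' seed. A control class absent from the data (e.g. a run where media wells
#' were excluded) is recorded in `missing_roles` and the split proceeds on
#' the remaining classes.
#'
#' @param records Data frame of wells (rows with `role` in negative /
#'   positive / media are used).
#' @param fraction Training fraction per class (default 0.5).
#' @param seed Integer seed (mandatory).
#' @return A `control_split`: `train` and `test` data frames, `seed`,
#'   `missing_roles`.
#' @export
split_controls <- function(records, fraction = 0.5, seed) {
  ctrl <- control_rows(records)
  present <- intersect(CONTROL_ROLES, unique(ctrl$role))
  missing <- setdiff(CONTROL_ROLES, present)
  if (!length(present)) stop("no control wells found", call. = FALSE)
  counts <- table(factor(ctrl$role, levels = present))
  if (any(counts < 2L)) {
    stop("control class(es) with fewer than 2 wells: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  train_idx <- with_seed(seed, {
    unlist(lapply(present, function(rl) {
      rows <- which(ctrl$role == rl)
      sample(rows, ceiling(fraction * length(rows)))
    }))
  })
  split <- list(train = ctrl[sort(train_idx), , drop = FALSE],
                test = ctrl[setdiff(seq_len(nrow(ctrl)), train_idx), ,
                            drop = FALSE],
                seed = as.integer(seed),
                missing_roles = missing)
  if (length(missing)) {
    split$note <- paste("control class(es) absent; model limited to:",
                        paste(present, collapse = ", "))
  }
  structure(split, class = "control_split")
}

#' @export
print.control_split <- function(x, ...) {
  cat(sprintf("<control_split> train %d / test %d (seed %d)%s\n",
              nrow(x$train), nrow(x$test), x$seed,
              if (length(x$missing_roles))
                paste0("; missing: ", paste(x$missing_roles, collapse = ","))
              else ""))
  invisible(x)
}

#' Fit a k-NN control classifier
#'
#' A lazy learner: stores the training feature matrix and labels verbatim
#' with the neighbor count and metric. Distances are Euclidean on the raw
#' embedding values (no standardization), the default of the k-NN
#' implementation used in screening practice.
#'
#' @param split A [split_controls()] result whose `train` table carries
#'   feature columns, or a plain feature table of training wells.
#' @param k Number of neighbors (default 6).
#' @return A `knn_model`.
#' @export
fit_knn <- function(split, k = 6L) {
  train <- if (inherits(split, "control_split")) split$train else split
  fc <- feature_cols(train)
  if (!length(fc)) stop("training table has no feature columns", call. = FALSE)
  X <- feature_matrix(train)
  if (any(!is.finite(X))) {
    stop("all training wells must have finite features", call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > nrow(X)) {
    stop(sprintf("k = %d exceeds training-set size %d", k, nrow(X)),
         call. = FALSE)
  }
  structure(list(X = X,
                 labels = factor(train$role, levels = CONTROL_ROLES),
                 train_wells = if (all(c("plate_id", "well") %in% names(train)))
                   paste(train$plate_id, train$well) else NULL,
                 k = k, metric = "euclidean"),
            class = "knn_model")
}

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf("<knn_model> k=%d, %d training wells (%s), %d features, %s\n",
              x$k, nrow(x$X),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", "),
              ncol(x$X), x$metric))
  invisible(x)
}

# Vote fractions that sum to exactly 1 under left-to-right floating-point
# summation: the last component is the exact complement of the rounded
# partial sum (off from counts[3]/k by at most one ulp), so
# (p1 + p2) + p3 == 1 holds bit-exactly.
vote_probabilities <- function(counts, k) {
  p <- counts / k
  partial <- p[1] + p[2]
  p[3] <- 1 - partial
  if (p[3] < 0) {          # rounded partial sum crept above 1 by one ulp
    p[3] <- 0
    p[2] <- 1 - p[1]
  }
  p
}

#' Classify one well against the control model
#'
#' Finds the k nearest training controls (ties in distance broken by lower
#' training-row index), reports class probabilities as vote fractions over
#' k (summing to exactly 1), and a hard label. A vote tie goes to the tied
#' class with the smaller mean neighbor distance, then to the fixed class
#' order negative < positive < media. The neighbor list is returned so a
#' classification can be explained by inspecting the control wells that
#' produced it.
#'
#' @param model A [fit_knn()] model.
#' @param feature Numeric feature vector matching the model's width.
#' @return List: `probabilities` (named, negative/positive/media),
#'   `counts`, `label`, `neighbors` (data frame: training row index, well,
#'   label, distance).
#' @export
classify <- function(model, feature) {
  stopifnot(inherits(model, "knn_model"))
  feature <- as.numeric(feature)
  if (length(feature) != ncol(model$X)) {
    stop(sprintf("feature length %d does not match model width %d",
                 length(feature), ncol(model$X)), call. = FALSE)
  }
  d <- sqrt(colSums((t(model$X) - feature)^2))
  ord <- order(d, seq_along(d))       # distance, then training-row index
  nb <- ord[seq_len(model$k)]
  nb_lab <- model$labels[nb]
  counts <- table(nb_lab)             # over all three class levels
  p <- vote_probabilities(as.numeric(counts), model$k)
  names(p) <- names(counts)
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1L) {
    mean_d <- vapply(top, function(cl) mean(d[nb[nb_lab == cl]]), 0)
    top <- top[mean_d == min(mean_d)]
    top <- top[order(match(top, CONTROL_ROLES))]
  }
  list(probabilities = p,
       counts = as.integer(counts),
       label = factor(top[1L], levels = CONTROL_ROLES),
       neighbors = data.frame(index = nb,
                              well = if (is.null(model$train_wells))
                                NA_character_ else model$train_wells[nb],
                              label = nb_lab,
                              distance = d[nb]))
}

#' Classify every row of a feature table
#'
#' @param model A [fit_knn()] model.
#' @param features Feature table (metadata + `f0001..` columns).
#' @return The metadata columns plus `p_neg`, `p_pos`, `p_media`, `label`.
#' @export
classify_wells <- function(model, features) {
  X <- feature_matrix(features)
  out <- lapply(seq_len(nrow(X)), function(i) classify(model, X[i, ]))
  meta <- features[, setdiff(names(features), feature_cols(features)),
                   drop = FALSE]
  meta$p_neg <- vapply(out, function(o) o$probabilities[["negative"]], 0)
  meta$p_pos <- vapply(out, function(o) o$probabilities[["positive"]], 0)
  meta$p_media <- vapply(out, function(o) o$probabilities[["media"]], 0)
  meta$label <- factor(vapply(out, function(o) as.character(o$label), ""),
                       levels = CONTROL_ROLES)
  rownames(meta) <- NULL
  meta
}

#' Evaluate a control model on withheld test wells
#'
#' @param model A [fit_knn()] model.
#' @param test Feature table of withheld control wells (must be disjoint
#'   from the training wells).
#' @return List: `confusion` (3x3 actual x predicted counts), `accuracy`,
#'   `per_class_recall`, `n_test`.
#' @export
evaluate_knn <- function(model, test) {
  if (nrow(test) == 0L) stop("empty test set", call. = FALSE)
  if (!is.null(model$train_wells) &&
      all(c("plate_id", "well") %in% names(test))) {
    overlap <- intersect(paste(test$plate_id, test$well), model$train_wells)
    if (length(overlap)) {
      stop("test wells overlap the training set: ",
           paste(head(overlap, 3), collapse = ", "), call. = FALSE)
    }
  }
  pred <- classify_wells(model, test)$label
  actual <- factor(test$role, levels = CONTROL_ROLES)
  confusion <- table(actual = actual, predicted = pred)
  accuracy <- sum(diag(confusion)) / sum(confusion)
  recall <- diag(confusion) / pmax(rowSums(confusion), 1L)
  list(confusion = confusion, accuracy = accuracy,
       per_class_recall = recall, n_test = nrow(test))
}

#' Robustness sweep over subsampling and neighbor count
#'
#' Repeats the split-fit-evaluate cycle `n_iter` times for each K with
#' fresh stratified control splits, quantifying sensitivity of the control
#' classifier to the subsample and to K.
#'
#' @param controls Feature table of control wells.
#' @param K_values Neighbor counts to test (default 1..6).
#' @param n_iter Iterations per K (default 100).
#' @param seed Base seed; iteration i uses `seed + i`.
#' @param fraction Training fraction (default 0.5).
#' @return Data frame (K, iteration, accuracy); `attr(, "summary")` holds
#'   mean and sd per K.
#' @export
robustness_sweep <- function(controls, K_values = 1:6, n_iter = 100L,
                             seed = 1L, fraction = 0.5) {
  grid <- expand.grid(K = K_values, iteration = seq_len(n_iter))
  grid$accuracy <- NA_real_
  for (r in seq_len(nrow(grid))) {
    sp <- split_controls(controls, fraction = fraction,
                         seed = seed + grid$iteration[r])
    model <- fit_knn(sp, k = grid$K[r])
    grid$accuracy[r] <- evaluate_knn(model, sp$test)$accuracy
  }
  summ <- aggregate(accuracy ~ K, grid,
                    function(a) c(mean = mean(a), sd = sd(a)))
  summ <- data.frame(K = summ$K, mean = summ$accuracy[, "mean"],
                     sd = summ$accuracy[, "sd"])
  attr(grid, "summary") <- summ
  grid
}

#' PCA of the phenotypic landscape
#'
#' Principal components of the mean-centered (unscaled) feature matrix over
#' all wells, used to explore response patterns: in this screen the
#' negative and positive controls separate along PC1 and the media controls
#' along PC2. Constant features are dropped with a warning.
#'
#' @param features Feature table (>= 2 wells).
#' @return List: `scores` (metadata + PC columns), `rotation`,
#'   `explained_variance` (fractions, non-increasing).
#' @export
pca_landscape <- function(features) {
  X <- feature_matrix(features)
  if (nrow(X) < 2L) stop("PCA needs at least 2 wells", call. = FALSE)
  const <- apply(X, 2, function(col) max(col) - min(col) == 0)
  if (any(const)) {
    warning(sprintf("%d constant feature(s) dropped before PCA", sum(const)),
            call. = FALSE)
    X <- X[, !const, drop = FALSE]
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  meta <- features[, setdiff(names(features), feature_cols(features)),
                   drop = FALSE]
  scores <- cbind(meta, as.data.frame(pc$x))
  list(scores = scores, rotation = pc$rotation, explained_variance = ev)
}

#' Train batch-level and cumulative control models
#'
#' One model is fit per batch from that batch's control split; a batch
#' qualifies if its withheld-test accuracy reaches `qc_threshold`
#' (default 0.8). The cumulative model is retrained on the union of the
#' qualified batches' training halves and evaluated on the union of their
#' test halves; it is the model used for final classification of treated
#' wells. A batch failing the gate is excluded and logged, not fatal.
#'
#' @param features Feature table of control wells across batches (`batch`
#'   column required).
#' @param k Neighbors (default 6).
#' @param fraction Training fraction per class (default 0.5).
#' @param qc_threshold Minimum batch test accuracy for inclusion.
#' @param seed Base seed; batch b uses `seed + b`.
#' @return List: `batch` (per-batch model + qc + qualified flag),
#'   `qualified` (batch ids), `cumulative` (model), `cumulative_qc`.
#' @export
train_levels <- function(features, k = 6L, fraction = 0.5,
                         qc_threshold = 0.8, seed = 1L) {
  if (!"batch" %in% names(features)) stop("'batch' column required", call. = FALSE)
  ctrl <- control_rows(features)
  batches <- unique(ctrl$batch)
  per_batch <- list()
  train_pool <- test_pool <- NULL
  for (b in seq_along(batches)) {
    sub <- ctrl[ctrl$batch == batches[b], , drop = FALSE]
    sp <- split_controls(sub, fraction = fraction, seed = seed + b)
    model <- fit_knn(sp, k = min(k, nrow(sp$train)))
    qc <- evaluate_knn(model, sp$test)
    ok <- qc$accuracy >= qc_threshold
    per_batch[[as.character(batches[b])]] <-
      list(model = model, qc = qc, qualified = ok, split = sp)
    if (ok) {
      train_pool <- rbind(train_pool, sp$train)
      test_pool <- rbind(test_pool, sp$test)
    } else {
      message(sprintf("batch '%s' failed QC (accuracy %.2f < %.2f); excluded",
                      batches[b], qc$accuracy, qc_threshold))
    }
  }
  qualified <- names(per_batch)[vapply(per_batch, `[[`, TRUE, "qualified")]
  if (!length(qualified)) stop("no batch passed the QC gate", call. = FALSE)
  cumulative <- fit_knn(train_pool, k = k)
  list(batch = per_batch, qualified = qualified,
       cumulative = cumulative,
       cumulative_qc = evaluate_knn(cumulative, test_pool))
}

#' Write a QC report for a control model
#'
#' Emits the confusion matrix and summary metrics as CSV plus a short
#' human-readable text file.
#'
#' @param qc Result of [evaluate_knn()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return `dir`, invisibly.
#' @export
write_qc_report <- function(qc, dir, prefix = "qc") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame.matrix(qc$confusion),
            file.path(dir, paste0(prefix, "_confusion.csv")))
  write.csv(data.frame(metric = c("accuracy",
                                  paste0("recall_", names(qc$per_class_recall))),
                       value = c(qc$accuracy, qc$per_class_recall)),
            file.path(dir, paste0(prefix, "_metrics.csv")), row.names = FALSE)
  txt <- c(sprintf("Control QC: accuracy %.3f on %d withheld wells",
                   qc$accuracy, qc$n_test),
           "", "Confusion (actual x predicted):",
           capture.output(print(qc$confusion)))
  writeLines(txt, file.path(dir, paste0(prefix, "_report.txt")))
  invisible(dir)
}
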