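test_that("control splits are stratified, seeded, and tolerate a missing class", {
  ctrl <- make_gaussian_controls(seed = 1)
  sp <- split_controls(ctrl, seed = 10)
  expect_identical(as.vector(table(sp$train$role)[c("negative", "positive",
                                                    "media")]),
                   rep(8L, 3))
  expect_identical(as.vector(table(sp$test$role)[c("negative", "positive",
                                                   "media")]),
                   rep(8L, 3))
  expect_length(intersect(sp$train$well, sp$test$well), 0L)
  expect_identical(split_controls(ctrl, seed = 10)$train$well, sp$train$well)
  expect_false(identical(split_controls(ctrl, seed = 11)$train$well,
                         sp$train$well))

  # media excluded (as in a run where that plate region was seeded):
  # split proceeds on the remaining classes and records the flag
  no_media <- ctrl[ctrl$role != "media", ]
  sp2 <- split_controls(no_media, seed = 10)
  expect_identical(sp2$missing_roles, "media")
  model <- fit_knn(sp2, k = 6)
  expect_identical(sort(unique(as.character(model$labels))),
                   c("negative", "positive"))

  expect_error(split_controls(ctrl[c(1, 17, 33), ], seed = 1), "fewer than 2")
})

test_that("k-NN fitting validates k and stores the training set verbatim", {
  ctrl <- make_gaussian_controls(seed = 2)
  sp <- split_controls(ctrl, seed = 3)
  model <- fit_knn(sp, k = 6)
  expect_identical(nrow(model$X), 24L)
  expect_identical(model$metric, "euclidean")
  expect_error(fit_knn(sp, k = 0), "k")
  expect_error(fit_knn(sp, k = 25), "exceeds")

  # duplicated training vectors and zero-distance neighbors are legal
  dup <- sp$train[c(seq_len(24), 1), ]
  dup$well[25] <- "Z9"
  m2 <- fit_knn(dup, k = 1)
  res <- classify(m2, as.numeric(sp$train[1, grep("^f", names(sp$train))]))
  expect_identical(res$neighbors$distance[1], 0)
  expect_identical(as.character(res$label), sp$train$role[1])
})

test_that("class probabilities are vote fractions with deterministic tie-breaks", {
  # constructed geometry in 2 dimensions: query at origin, 4 positive
  # neighbors closer than 2 negative, media far away
  mk <- function(X, roles) {
    df <- data.frame(plate_id = "P", well = paste0("A", seq_len(nrow(X))),
                     role = roles, stringsAsFactors = FALSE)
    colnames(X) <- sprintf("f%04d", 1:2)
    cbind(df, as.data.frame(X))
  }
  X <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1),   # positive, d = 1
             c(2, 0), c(0, 2),                       # negative, d = 2
             c(50, 50), c(60, 60))                   # media, far
  tr <- mk(X, c(rep("positive", 4), rep("negative", 2), rep("media", 2)))
  model <- fit_knn(tr, k = 6)
  res <- classify(model, c(0, 0))
  expect_identical(unname(res$probabilities),
                   c(2 / 6, 4 / 6, 0))
  expect_identical(sum(res$probabilities), 1)
  expect_identical(as.character(res$label), "positive")
  expect_identical(nrow(res$neighbors), 6L)

  # all six nearest positive
  res2 <- classify(fit_knn(tr[1:4, ], k = 4), c(0, 0))
  expect_identical(unname(res2$probabilities), c(0, 1, 0))

  # 3-3 vote tie: label goes to the class with smaller mean neighbor distance
  Xt <- rbind(c(1, 0), c(0, 1), c(-1, 0),            # positive, mean d = 1
              c(1.5, 0), c(0, 1.5), c(-1.5, 0),      # negative, mean d = 1.5
              c(90, 90))                             # media
  tt <- mk(Xt, c(rep("positive", 3), rep("negative", 3), "media"))
  res3 <- classify(fit_knn(tt, k = 6), c(0, 0))
  expect_identical(unname(res3$probabilities), c(0.5, 0.5, 0))
  expect_identical(as.character(res3$label), "positive")

  # exact tie in distance too: fixed class order (negative first) decides
  Xe <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  te <- mk(Xe, c("positive", "negative", "positive", "negative"))
  res4 <- classify(fit_knn(te, k = 4), c(0, 0))
  expect_identical(as.character(res4$label), "negative")

  expect_error(classify(model, c(1, 2, 3)), "length")
})

test_that("classification matches the brute-force all-pairs oracle", {
  roles <- c("negative", "positive", "media")
  for (case in 1:25) {
    n <- with_seed(300 + case, sample(10:200, 1))
    d <- with_seed(400 + case, sample(2:32, 1))
    X <- with_seed(500 + case, matrix(rnorm(n * d), n, d))
    labs <- with_seed(600 + case, sample(roles, n, replace = TRUE))
    colnames(X) <- sprintf("f%04d", seq_len(d))
    tr <- cbind(data.frame(plate_id = "P", well = paste0("W", seq_len(n)),
                           role = labs, stringsAsFactors = FALSE),
                as.data.frame(X))
    k <- with_seed(700 + case, sample(1:6, 1))
    model <- fit_knn(tr, k = k)
    for (q in 1:4) {
      query <- with_seed(800 + 10 * case + q, rnorm(d))
      got <- classify(model, query)
      want <- knn_oracle(X, labs, query, k)
      expect_identical(got$counts, want$counts)
      expect_equal(unname(got$probabilities), want$counts / k,
                   tolerance = 1e-15)
      expect_identical(as.character(got$label), want$label)
    }
  }
})

test_that("vote fractions agree with the reference knn implementation", {
  ctrl <- make_gaussian_controls(seed = 7, sep = 3, sd = 2)
  sp <- split_controls(ctrl, seed = 8)
  model <- fit_knn(sp, k = 6)
  fc <- grep("^f", names(ctrl), value = TRUE)
  ref <- caret::knn3(x = as.matrix(sp$train[, fc]),
                     y = factor(sp$train$role,
                                levels = c("negative", "positive", "media")),
                     k = 6)
  got <- classify_wells(model, sp$test)
  want <- predict(ref, as.matrix(sp$test[, fc]), type = "prob")
  expect_equal(cbind(got$p_neg, got$p_pos, got$p_media), unname(want),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("well-separated controls are classified perfectly; noise is at chance", {
  ctrl <- make_gaussian_controls(seed = 4)
  sp <- split_controls(ctrl, seed = 5)
  model <- fit_knn(sp, k = 6)
  ev <- evaluate_knn(model, sp$test)
  expect_identical(ev$accuracy, 1)
  expect_true(all(ev$confusion[upper.tri(ev$confusion)] == 0))
  expect_true(all(ev$confusion[lower.tri(ev$confusion)] == 0))
  expect_identical(unname(ev$per_class_recall), rep(1, 3))
  expect_error(evaluate_knn(model, sp$test[0, ]), "empty")
  expect_error(evaluate_knn(model, sp$train), "overlap")

  # pure-noise features: accuracy concentrates at chance (1/3)
  accs <- vapply(1:100, function(s) {
    noise <- make_gaussian_controls(seed = 1000 + s, sep = 0, sd = 1)
    nsp <- split_controls(noise, seed = 2000 + s)
    evaluate_knn(fit_knn(nsp, k = 6), nsp$test)$accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 1 / 3), 0.1)
})

test_that("accuracy is invariant to global feature scaling", {
  ctrl <- make_gaussian_controls(seed = 6)
  fc <- grep("^f", names(ctrl), value = TRUE)
  scaled <- ctrl
  scaled[, fc] <- scaled[, fc] * 1000
  for (src in list(ctrl, scaled)) {
    sp <- split_controls(src, seed = 9)
    ev <- evaluate_knn(fit_knn(sp, k = 6), sp$test)
    expect_identical(ev$accuracy, 1)
  }
})

test_that("robustness sweep is stable across subsamples and K on separated controls", {
  ctrl <- make_gaussian_controls(seed = 11)
  sweep <- robustness_sweep(ctrl, K_values = 1:6, n_iter = 30, seed = 12)
  summ <- attr(sweep, "summary")
  expect_identical(nrow(summ), 6L)
  expect_true(all(summ$sd < 0.05))
  expect_lt(max(summ$mean) - min(summ$mean), 0.05)
  one <- robustness_sweep(ctrl, K_values = 1:6, n_iter = 1, seed = 12)
  expect_identical(nrow(one), 6L)
})

test_that("PCA landscape orders components and separates control centroids", {
  ft <- fixture_control_features()
  pca <- suppressWarnings(pca_landscape(ft))
  ev <- pca$explained_variance
  expect_true(all(diff(ev) <= 1e-12))
  expect_lte(sum(ev), 1 + 1e-9)

  # control-role centroids in PC1-PC2 separate beyond within-role spread
  sc <- pca$scores
  cent <- vapply(c("negative", "positive", "media"), function(r) {
    colMeans(sc[sc$role == r, c("PC1", "PC2")])
  }, numeric(2))
  spread <- mean(vapply(c("negative", "positive", "media"), function(r) {
    pts <- as.matrix(sc[sc$role == r, c("PC1", "PC2")])
    mean(sqrt(rowSums(sweep(pts, 2, colMeans(pts))^2)))
  }, 0))
  pair_d <- dist(t(cent))
  expect_true(all(pair_d > 2 * spread))

  # duplicating every well leaves explained-variance fractions unchanged
  pca2 <- suppressWarnings(pca_landscape(rbind(ft, ft)))
  expect_equal(pca2$explained_variance[1:5], ev[1:5], tolerance = 1e-8)

  # constant features are dropped with a warning
  ft2 <- ft
  ft2$f0001 <- 1
  expect_warning(pca_landscape(ft2), "constant")
})

test_that("batch models gate inclusion and feed the cumulative model", {
  b1 <- make_gaussian_controls(seed = 21)
  b2 <- make_gaussian_controls(seed = 22)
  b2$batch <- "GB2"; b2$plate_id <- "GP2"
  both <- rbind(b1, b2)
  lv <- train_levels(both, k = 6, seed = 30)
  expect_identical(sort(lv$qualified), c("GB1", "GB2"))
  # cumulative training set = union of the two batches' control halves:
  # 8 per role per batch -> 16 per role, as in cumulative-level models
  expect_identical(nrow(lv$cumulative$X), 48L)
  expect_identical(as.vector(table(lv$cumulative$labels)), rep(16L, 3))
  expect_identical(lv$cumulative_qc$accuracy, 1)

  # a label-shuffled batch fails the QC gate and is excluded
  b3 <- make_gaussian_controls(seed = 23)
  b3$batch <- "GB3"; b3$plate_id <- "GP3"
  b3$role <- with_seed(99, sample(b3$role))
  lv2 <- suppressMessages(train_levels(rbind(b1, b3), k = 6, seed = 30))
  expect_identical(lv2$qualified, "GB1")
  expect_false(lv2$batch$GB3$qualified)

  # single batch: cumulative model is the batch model
  lv3 <- train_levels(b1, k = 6, seed = 30)
  expect_identical(lv3$cumulative$X, lv3$batch$GB1$model$X)
  expect_identical(lv3$cumulative$labels, lv3$batch$GB1$model$labels)
})

test_that("every emitted probability triple sums to exactly one", {
  ctrl <- make_gaussian_controls(seed = 31, sep = 2, sd = 2)
  sp <- split_controls(ctrl, seed = 32)
  model <- fit_knn(sp, k = 6)
  probs <- classify_wells(model, sp$test)
  expect_identical(probs$p_neg + probs$p_pos + probs$p_media,
                   rep(1, nrow(probs)))
})
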