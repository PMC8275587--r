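# Dose-response analytics: per-well class probabilities are converted into
# per-drug activity scores. A radial-kernel support-vector regression is fit
# per control class ("class probability ~ concentration"), making no
# assumption about curve shape, so saturated, sigmoidal and multi-stage
# responses (reprogramming switching to toxicity) are all accommodated. The
# normalized area under each fitted curve over the tested log10 range gives
# the continuous activity ranking (AUC per class); potency is summarized by
# a constrained four-parameter logistic fit of the positive-class
# probabilities and its PR50, the concentration at which the fitted
# positive-class probability reaches 0.5.

#' Fit a shape-free probability curve by support-vector regression
#'
#' Radial-kernel eps-regression with library-default cost, gamma and
#' epsilon, trained on `probability ~ log10(concentration)` with two-fold
#' cross-validated error recorded. Replicates enter as separate points.
#' Predictions are clipped to \[0,1\] so downstream AUCs stay bounded.
#'
#' @param series Data frame with columns `concentration_molar` and
#'   `probability` (>= 2 distinct concentrations).
#' @return A `prob_curve`: `$predict(log10_conc)`, `$range` (tested log10
#'   range), `$cv_rmse`.
#' @export
fit_probability_curve <- function(series) {
  stopifnot(all(c("concentration_molar", "probability") %in% names(series)))
  if (any(series$concentration_molar <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  if (any(series$probability < 0 | series$probability > 1)) {
    stop("probabilities must lie in [0,1]", call. = FALSE)
  }
  x <- log10(series$concentration_molar)
  y <- series$probability
  if (length(unique(x)) < 2L) {
    stop("need at least 2 distinct concentrations to fit a curve",
         call. = FALSE)
  }
  rng <- range(x)
  if (sd(y) < 1e-9) {
    # degenerate flat series: SVR's response scaling is undefined, and the
    # constant is the exact least-squares curve
    const <- mean(y)
    return(structure(list(predict = function(lx) rep(clip01(const),
                                                     length(lx)),
                          range = rng, cv_rmse = 0, constant = const),
                     class = "prob_curve"))
  }
  # cross-validation fold assignment draws from the RNG; a fixed internal
  # fold seed keeps the reported CV error reproducible without touching
  # the caller's RNG state (the fitted curve itself is deterministic)
  fit <- withCallingHandlers(
    with_seed(20201L,
      e1071::svm(x = matrix(x, ncol = 1), y = y, type = "eps-regression",
                 kernel = "radial", cross = 2)),
    # e1071's cross-validation path triggers a base-R recycling deprecation
    # notice on R >= 4.3; it does not affect the fit
    warning = function(w) {
      if (grepl("Recycling array", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  pred <- function(lx) {
    clip01(as.numeric(predict(fit, matrix(lx, ncol = 1))))
  }
  structure(list(predict = pred, range = rng,
                 cv_rmse = sqrt(mean(fit$MSE)), model = fit),
            class = "prob_curve")
}

#' @export
print.prob_curve <- function(x, ...) {
  cat(sprintf("<prob_curve> log10 range [%.2f, %.2f], 2-fold CV RMSE %.3f\n",
              x$range[1], x$range[2], x$cv_rmse))
  invisible(x)
}

#' Normalized area under a fitted probability curve
#'
#' Trapezoidal integral of the curve over the log10 concentration range on
#' an evenly spaced grid, divided by the width of the range; lies in
#' \[0,1\] for clipped curves. A curve identically 1 scores 1, identically
#' 0 scores 0.
#'
#' @param curve A `prob_curve`, or any function of log10 concentration.
#' @param conc_range Molar range `c(min, max)` to integrate over; defaults
#'   to the curve's tested range.
#' @param n_grid Grid points (default 101).
#' @return Normalized AUC.
#' @export
compute_auc <- function(curve, conc_range = NULL, n_grid = 101L) {
  f <- if (inherits(curve, "prob_curve")) curve$predict else match.fun(curve)
  if (is.null(conc_range)) {
    if (!inherits(curve, "prob_curve")) {
      stop("conc_range required for a bare function", call. = FALSE)
    }
    lr <- curve$range
  } else {
    if (any(conc_range <= 0)) stop("conc_range must be positive molar",
                                   call. = FALSE)
    lr <- log10(sort(conc_range))
  }
  if (diff(lr) <= 0) stop("degenerate concentration range", call. = FALSE)
  grid <- seq(lr[1], lr[2], length.out = n_grid)
  trapz(grid, f(grid)) / diff(lr)
}

#' Raw per-class AUCs from a probability table
#'
#' Trapezoid of the mean observed vote fractions per concentration (no
#' curve fitting), normalized by the log10 range. Because the three class
#' probabilities of every well sum to 1, the three raw AUCs of a drug sum
#' to 1 as well.
#'
#' @param probs Probability table rows for one drug (`concentration_molar`,
#'   `p_neg`, `p_pos`, `p_media`).
#' @return Named numeric: `auc_neg`, `auc_pos`, `auc_media`.
#' @export
compute_raw_aucs <- function(probs) {
  lx <- log10(probs$concentration_molar)
  ux <- sort(unique(lx))
  if (length(ux) < 2L) stop("need >= 2 distinct concentrations", call. = FALSE)
  mean_at <- function(p) vapply(ux, function(v) mean(p[lx == v]), 0)
  vapply(c(auc_neg = "p_neg", auc_pos = "p_pos", auc_media = "p_media"),
         function(col) trapz(ux, mean_at(probs[[col]])) / diff(range(ux)),
         0)
}

#' Constrained four-parameter logistic fit
#'
#' Bounded nonlinear least squares of the 4PL (see [fourpl()]) with box
#' constraints `0 <= bottom, top <= 1`, multi-started from four fixed
#' initializations (hill +1/-1 crossed with EC50 at the first and third
#' quartile of the tested log10 range). `bottom <= top` is enforced by the
#' hill-sign equivalence of the 4PL (a fit with inverted asymptotes is
#' reported with swapped asymptotes and negated hill). An atypical series
#' that the optimizer cannot fit is a recorded outcome (`converged =
#' FALSE`), not an error, as are series with fewer than 4 distinct
#' concentrations.
#'
#' @param series Data frame with `concentration_molar` and `probability`
#'   (the positive-class probabilities of one drug; replicates as rows).
#' @return A `fourpl_fit`: `top`, `bottom`, `hill`, `log10_ec50`,
#'   `converged`, `pr50` (molar, `NA` = not reached), `pr50_reached`,
#'   `range`, `rss`.
#' @export
fit_4pl <- function(series) {
  stopifnot(all(c("concentration_molar", "probability") %in% names(series)))
  if (nrow(series) == 0L) stop("empty dose series", call. = FALSE)
  x <- log10(series$concentration_molar)
  y <- series$probability
  lr <- range(x)
  n_conc <- length(unique(x))
  resid_fn <- function(par) y - fourpl(x, par[["top"]], par[["bottom"]],
                                       par[["ec50"]], par[["hill"]])
  lower <- c(top = 0, bottom = 0, ec50 = lr[1] - 3, hill = -20)
  upper <- c(top = 1, bottom = 1, ec50 = lr[2] + 3, hill = 20)
  starts <- expand.grid(hill = c(1, -1),
                        ec50 = quantile(x, c(0.25, 0.75), names = FALSE))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    par0 <- c(top = min(1, max(y)), bottom = max(0, min(y)),
              ec50 = starts$ec50[s], hill = starts$hill[s])
    # under-determined series (< 4 points) make lmdif warn and bail out;
    # that is the recorded converged = FALSE outcome, not an error
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                           fn = resid_fn,
                           control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(par = fit$par, rss = rss, info = fit$info)
    }
  }
  if (is.null(best)) {
    out <- list(top = NA_real_, bottom = NA_real_, hill = NA_real_,
                log10_ec50 = NA_real_, converged = FALSE, pr50 = NA_real_,
                pr50_reached = FALSE, range = lr, rss = NA_real_)
    return(structure(out, class = "fourpl_fit"))
  }
  par <- best$par
  top <- par[["top"]]; bottom <- par[["bottom"]]
  hill <- par[["hill"]]; ec50 <- par[["ec50"]]
  if (bottom > top) {   # equivalent curve with ordered asymptotes
    tmp <- top; top <- bottom; bottom <- tmp
    hill <- -hill
  }
  converged <- best$info %in% 1:3 && n_conc >= 4L
  out <- structure(list(top = top, bottom = bottom, hill = hill,
                        log10_ec50 = ec50, converged = converged,
                        pr50 = NA_real_, pr50_reached = FALSE,
                        range = lr, rss = best$rss),
                   class = "fourpl_fit")
  p50 <- pr50(out)
  out$pr50 <- p50
  out$pr50_reached <- !is.na(p50)
  out
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "<fourpl_fit> top=%.3f bottom=%.3f hill=%.2f log10EC50=%.2f (%s)\n",
    x$top, x$bottom, x$hill, x$log10_ec50,
    if (x$converged) "converged" else "did not converge"))
  cat("  PR50:", if (x$pr50_reached) sprintf("%.3g M", x$pr50)
      else "not reached", "\n")
  invisible(x)
}

#' PR50 potency from a 4PL fit
#'
#' The smallest concentration within the tested range at which the fitted
#' positive-class probability curve reaches 0.5, located by monotone
#' bisection on the log10 axis. `NA` means the curve never attains 0.5 in
#' range ("not reached").
#'
#' @param fit A [fit_4pl()] result.
#' @param conc_range Optional molar range overriding the fit's tested
#'   range.
#' @return Molar concentration, or `NA_real_` if not reached.
#' @export
pr50 <- function(fit, conc_range = NULL) {
  stopifnot(inherits(fit, "fourpl_fit"))
  if (any(is.na(c(fit$top, fit$bottom, fit$hill, fit$log10_ec50)))) {
    return(NA_real_)
  }
  lr <- if (is.null(conc_range)) fit$range else log10(sort(conc_range))
  f <- function(lx) fourpl(lx, fit$top, fit$bottom, fit$log10_ec50, fit$hill)
  flo <- f(lr[1]); fhi <- f(lr[2])
  if (flo == 0.5) return(10^lr[1])
  if ((flo - 0.5) * (fhi - 0.5) > 0) return(NA_real_)  # no crossing in range
  lo <- lr[1]; hi <- lr[2]
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if ((f(mid) - 0.5) * (flo - 0.5) > 0) lo <- mid else hi <- mid
  }
  10^((lo + hi) / 2)
}

#' Per-drug activity scores from classified wells
#'
#' For each drug: fits the three per-class SVR probability curves over the
#' drug's tested range, computes the three normalized AUCs, and fits the
#' constrained 4PL with PR50 on the positive-class probabilities.
#'
#' @param probs Probability table from [classify_wells()] for treatment
#'   wells (`drug_id`, `concentration_molar`, `p_neg`, `p_pos`,
#'   `p_media`).
#' @return Data frame: one row per drug with `auc_neg`, `auc_pos`,
#'   `auc_media`, 4PL parameters, `converged`, `pr50_molar`,
#'   `pr50_reached`.
#' @export
drug_activity <- function(probs) {
  stopifnot(all(c("drug_id", "concentration_molar", "p_neg", "p_pos",
                  "p_media") %in% names(probs)))
  drugs <- unique(probs$drug_id)
  rows <- lapply(drugs, function(d) {
    sub <- probs[probs$drug_id == d, , drop = FALSE]
    aucs <- vapply(c(auc_neg = "p_neg", auc_pos = "p_pos",
                     auc_media = "p_media"), function(col) {
      curve <- fit_probability_curve(
        data.frame(concentration_molar = sub$concentration_molar,
                   probability = sub[[col]]))
      compute_auc(curve)
    }, 0)
    fit <- fit_4pl(data.frame(concentration_molar = sub$concentration_molar,
                              probability = sub$p_pos))
    data.frame(drug_id = d, auc_neg = aucs[["auc_neg"]],
               auc_pos = aucs[["auc_pos"]], auc_media = aucs[["auc_media"]],
               top = fit$top, bottom = fit$bottom, hill = fit$hill,
               log10_ec50 = fit$log10_ec50, converged = fit$converged,
               pr50_molar = fit$pr50, pr50_reached = fit$pr50_reached,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank drug hits and derive the clustered heatmap order
#'
#' Orders drugs by decreasing positive-class AUC (the screen's activity
#' ranking) and hierarchically clusters the (auc_neg, auc_pos, auc_media)
#' triplets (Euclidean distance, average linkage by default) to give the
#' heatmap row order; drugs with identical triplets end up adjacent. Drugs
#' with missing AUCs are excluded with a warning.
#'
#' @param scores Hit table from [drug_activity()] (>= 2 drugs).
#' @param annotations Optional data frame with `drug_id` plus annotation
#'   columns (e.g. target category), joined onto the output.
#' @param method Linkage for [stats::hclust()] (default "average").
#' @return Ranked data frame with a `rank` column; `attr(, "cluster_order")`
#'   gives drug ids in heatmap order and `attr(, "clustering")` the
#'   `hclust` object (with the scheme recorded in its `method`).
#' @export
rank_hits <- function(scores, annotations = NULL, method = "average") {
  auc_cols <- c("auc_neg", "auc_pos", "auc_media")
  stopifnot(all(auc_cols %in% names(scores)))
  bad <- !stats::complete.cases(scores[, auc_cols])
  if (any(bad)) {
    warning("drug(s) with missing AUCs excluded: ",
            paste(scores$drug_id[bad], collapse = ", "), call. = FALSE)
    scores <- scores[!bad, , drop = FALSE]
  }
  if (nrow(scores) < 2L) stop("ranking needs at least 2 drugs", call. = FALSE)
  ranked <- scores[order(-scores$auc_pos, scores$drug_id), , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  if (!is.null(annotations)) {
    ranked <- merge(ranked, annotations, by = "drug_id", all.x = TRUE,
                    sort = FALSE)
    ranked <- ranked[order(ranked$rank), , drop = FALSE]
  }
  hc <- hclust(dist(as.matrix(scores[, auc_cols])), method = method)
  hc$labels <- scores$drug_id
  rownames(ranked) <- NULL
  attr(ranked, "cluster_order") <- scores$drug_id[hc$order]
  attr(ranked, "clustering") <- hc
  ranked
}

#' Clustered AUC heatmap of the hit table
#'
#' @param ranked Result of [rank_hits()].
#' @param path Optional PNG path; when given, the plot is written there.
#' @return The heatmap object (pheatmap) or `NULL`, invisibly.
#' @export
plot_hit_heatmap <- function(ranked, path = NULL) {
  auc_cols <- c("auc_neg", "auc_pos", "auc_media")
  m <- as.matrix(ranked[, auc_cols])
  rownames(m) <- ranked$drug_id
  ord <- attr(ranked, "cluster_order")
  m <- m[match(ord, rownames(m)), , drop = FALSE]
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    if (!is.null(path)) grDevices::png(path, width = 600, height = 120 + 24 * nrow(m))
    p <- pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                            main = "Per-class dose-response AUC")
    if (!is.null(path)) grDevices::dev.off()
    return(invisible(p))
  }
  if (!is.null(path)) grDevices::png(path)
  graphics::image(t(m), axes = FALSE, main = "Per-class dose-response AUC")
  if (!is.null(path)) grDevices::dev.off()
  invisible(NULL)
}

#' Plot one drug's dose-response
#'
#' Positive-class probabilities by concentration with the SVR curve and,
#' when converged, the 4PL fit and PR50 marker.
#'
#' @param probs Probability table rows for one drug.
#' @param drug_id Drug to plot.
#' @param path Optional PNG path.
#' @return Invisibly, the fitted `fourpl_fit`.
#' @export
plot_dose_response <- function(probs, drug_id, path = NULL) {
  sub <- probs[probs$drug_id == drug_id, , drop = FALSE]
  if (!nrow(sub)) stop("no wells for drug ", drug_id, call. = FALSE)
  curve <- fit_probability_curve(
    data.frame(concentration_molar = sub$concentration_molar,
               probability = sub$p_pos))
  fit <- fit_4pl(data.frame(concentration_molar = sub$concentration_molar,
                            probability = sub$p_pos))
  if (!is.null(path)) grDevices::png(path)
  lx <- log10(sub$concentration_molar)
  grid <- seq(min(lx), max(lx), length.out = 101)
  plot(lx, sub$p_pos, xlab = "log10 concentration (M)",
       ylab = "P(positive-like)", ylim = c(0, 1), main = drug_id)
  graphics::lines(grid, curve$predict(grid), col = "steelblue", lwd = 2)
  if (fit$converged) {
    graphics::lines(grid, fourpl(grid, fit$top, fit$bottom, fit$log10_ec50,
                                 fit$hill), col = "firebrick", lty = 2)
    if (fit$pr50_reached) graphics::abline(v = log10(fit$pr50), lty = 3)
  }
  if (!is.null(path)) grDevices::dev.off()
  invisible(fit)
}
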