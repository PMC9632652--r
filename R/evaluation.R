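#' Confusion-matrix metrics for a binary classifier
#'
#' Counts TP/TN/FP/FN against the declared positive class and derives
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy, precision
#' `TP/(TP+FP)` and `F1 = 2 Pre Sen / (Pre + Sen)`. A ratio with a zero
#' denominator is reported as 0 and flagged in `undefined` rather than
#' erroring, so small batches never crash an evaluation.
#'
#' An optional `group` key averages per-group before counting is *not*
#' applied here; see [roc_auc()]'s `group` argument for grouped scoring.
#'
#' @param truth,predicted binary label vectors of equal length.
#' @param positive the label counted as positive (default 1).
#' @return object of class `evaluation_report` with the counts, the five
#'   metrics, and `undefined` (names of zero-denominator metrics).
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_metrics <- function(truth, predicted, positive = 1L) {
  if (length(truth) != length(predicted))
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  if (length(unique(c(truth, predicted))) > 2L)
    stop("labels must be binary", call. = FALSE)
  pos_t <- truth == positive
  pos_p <- predicted == positive
  tp <- sum(pos_t & pos_p); tn <- sum(!pos_t & !pos_p)
  fp <- sum(!pos_t & pos_p); fn <- sum(pos_t & !pos_p)
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(0) }
    num / den
  }
  sen <- ratio(tp, tp + fn, "sen")
  spe <- ratio(tn, tn + fp, "spe")
  acc <- ratio(tp + tn, tp + tn + fp + fn, "acc")
  pre <- ratio(tp, tp + fp, "pre")
  f1 <- ratio(2 * pre * sen, pre + sen, "f1")
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 sen = sen, spe = spe, acc = acc, pre = pre, f1 = f1,
                 undefined = undefined),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Confusion: TP %d  FN %d  TN %d  FP %d\n", x$tp, x$fn, x$tn, x$fp))
  cat(sprintf("Sen %.3f  Spe %.3f  Acc %.3f  Pre %.3f  F1 %.3f\n",
              x$sen, x$spe, x$acc, x$pre, x$f1))
  if (!is.null(x$auc)) cat(sprintf("AUC %.3f\n", x$auc))
  if (length(x$undefined))
    cat("  (zero-denominator, reported as 0:",
        paste(x$undefined, collapse = ", "), ")\n")
  invisible(x)
}

#' F1 score from precision and sensitivity
#'
#' The harmonic mean `2 Pre Sen / (Pre + Sen)`; returns 0 when both are 0.
#'
#' @param precision,sensitivity values in \[0, 1\].
#' @return F1 value in \[0, 1\].
#' @export
f1_score <- function(precision, sensitivity) {
  ifelse(precision + sensitivity == 0, 0,
         2 * precision * sensitivity / (precision + sensitivity))
}

#' ROC curve and AUC
#'
#' Sweeps all score thresholds to build the ROC curve and integrates it by
#' the trapezoidal rule. Tied scores are handled by grouping, which makes
#' the AUC exactly the normalized Mann-Whitney U statistic (ties count 1/2).
#' An optional `group` key averages scores per group first (e.g. per
#' patient) with the group's majority truth label.
#'
#' @param truth binary truth labels; both classes must be present.
#' @param scores finite numeric scores, ranked as given (higher score is
#'   called more positive). The `positive` argument only relabels which
#'   samples count as positive, so on the same scores
#'   `AUC(positive = 0) = 1 - AUC(positive = 1)` exactly; pass scores
#'   oriented for the declared positive class.
#' @param positive label treated as positive.
#' @param group optional grouping key for score averaging.
#' @return list with `auc` and `roc_points` (data frame of fpr, tpr,
#'   monotone non-decreasing in both columns).
#' @export
roc_auc <- function(truth, scores, positive = 1L, group = NULL) {
  if (length(truth) != length(scores))
    stop("`truth` and `scores` must have equal length", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (!is.null(group)) {
    agg_s <- tapply(scores, group, mean)
    agg_t <- tapply(truth, group, function(v) {
      as.numeric(names(which.max(table(v))))
    })
    scores <- as.numeric(agg_s)
    truth <- as.numeric(agg_t[names(agg_s)])
  }
  is_pos <- truth == positive
  if (all(is_pos) || all(!is_pos))
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  s <- scores

  np <- sum(is_pos); nn <- sum(!is_pos)
  ord <- order(s, decreasing = TRUE)
  s_ord <- s[ord]; pos_ord <- is_pos[ord]
  # group tied scores: each distinct threshold adds one ROC vertex
  grp <- cumsum(!duplicated(s_ord))
  tp_cum <- cumsum(pos_ord); fp_cum <- cumsum(!pos_ord)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp_cum[last] / np)
  fpr <- c(0, fp_cum[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc, roc_points = data.frame(fpr = fpr, tpr = tpr))
}

#' Kernel-density comparison of two feature sets
#'
#' Projects both sets onto a single axis (a named feature, or the first
#' principal direction of the pooled data), fits Gaussian kernel density
#' estimates with Silverman bandwidths on a shared grid, and summarizes
#' their disagreement as the L1 distance between the two curves
#' (0 for identical distributions, approaching 2 for disjoint supports).
#' Used to compare source/target feature distributions before and after
#' adaptation.
#'
#' @param features_a,features_b `feature_set`s or matrices with equal column
#'   count and at least 5 rows each.
#' @param projection `"pc1"` or the name (or index) of a feature column.
#' @param grid_n number of grid points.
#' @return object of class `kde_comparison`: `grid`, `density_a`,
#'   `density_b`, `l1_distance`, `projection`.
#' @export
kde_compare <- function(features_a, features_b, projection = "pc1",
                        grid_n = 512L) {
  A <- as_feature_matrix(features_a)
  B <- as_feature_matrix(features_b)
  if (ncol(A) != ncol(B))
    stop("the two sets must have the same feature dimension", call. = FALSE)
  if (nrow(A) < 5L || nrow(B) < 5L)
    stop("at least 5 samples per set are required", call. = FALSE)
  if (identical(projection, "pc1")) {
    pooled <- rbind(A, B)
    ctr <- colMeans(pooled)
    v <- svd(sweep(pooled, 2, ctr), nu = 0, nv = 1)$v[, 1]
    xa <- as.numeric(sweep(A, 2, ctr) %*% v)
    xb <- as.numeric(sweep(B, 2, ctr) %*% v)
  } else {
    xa <- A[, projection]
    xb <- B[, projection]
  }
  bwa <- stats::bw.nrd0(xa)
  bwb <- stats::bw.nrd0(xb)
  pad <- 3 * max(bwa, bwb)
  grid <- seq(min(xa, xb) - pad, max(xa, xb) + pad, length.out = grid_n)
  fa <- gaussian_kde(xa, grid, bwa)
  fb <- gaussian_kde(xb, grid, bwb)
  dg <- grid[2] - grid[1]
  structure(list(grid = grid, density_a = fa, density_b = fb,
                 l1_distance = sum(abs(fa - fb)) * dg,
                 projection = projection),
            class = "kde_comparison")
}

gaussian_kde <- function(x, grid, bw) {
  rowMeans(vapply(x, function(xi) stats::dnorm(grid, xi, bw),
                  numeric(length(grid))))
}

#' @export
print.kde_comparison <- function(x, ...) {
  cat(sprintf("KDE comparison on projection '%s': L1 distance %.4f\n",
              as.character(x$projection), x$l1_distance))
  invisible(x)
}

#' @export
plot.kde_comparison <- function(x, ...) {
  graphics::matplot(x$grid, cbind(x$density_a, x$density_b), type = "l",
                    lty = 1, col = c("#1b6ca8", "#c1403d"),
                    xlab = "projection", ylab = "density", ...)
  graphics::legend("topright", legend = c("set A", "set B"), lty = 1,
                   col = c("#1b6ca8", "#c1403d"), bty = "n")
  invisible(x)
}

#' Full evaluation of scored predictions
#'
#' Combines [confusion_metrics()] (labels from thresholding the class-1
#' score at `threshold`, or explicit predictions) with [roc_auc()].
#'
#' @param truth binary truth labels.
#' @param scores class-1 scores.
#' @param predicted optional explicit hard labels; defaults to
#'   `scores > threshold`.
#' @param threshold score cut for hard labels.
#' @param positive positive label.
#' @param group optional grouping key.
#' @return `evaluation_report` including `auc` and `roc_points`.
#' @export
evaluate_predictions <- function(truth, scores, predicted = NULL,
                                 threshold = 0.5, positive = 1L,
                                 group = NULL) {
  if (is.null(predicted)) predicted <- as.integer(scores > threshold)
  rep <- confusion_metrics(truth, predicted, positive = positive)
  roc <- roc_auc(truth, scores, positive = positive, group = group)
  rep$auc <- roc$auc
  rep$roc_points <- roc$roc_points
  rep
}
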