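# Evaluation metrics for affinity regression and its binarized variants.

check_pairs <- function(y_true, y_pred) {
  stopifnot(is.numeric(y_true), is.numeric(y_pred),
            length(y_true) == length(y_pred), length(y_true) >= 2L)
  if (!all(is.finite(y_true)) || !all(is.finite(y_pred))) {
    stop("non-finite values in y_true/y_pred", call. = FALSE)
  }
  invisible(TRUE)
}

#' Concordance index
#'
#' The fraction of strictly ordered pairs of true affinities whose
#' predictions preserve the order:
#' `CI = (1/Z) * sum over (x, y) with d_x > d_y of h(b_x - b_y)` where `h`
#' is 1 for a positive argument, 0.5 for zero and 0 for negative, and `Z`
#' counts the strictly ordered true pairs.  Ties in the true affinities
#' contribute nothing; prediction ties score 0.5.  CI is invariant under
#' strictly increasing transforms of the predictions.
#'
#' @param y_true Numeric vector of measured affinities.
#' @param y_pred Numeric vector of predicted affinities (same length).
#' @return The concordance index in `[0, 1]`.
#' @export
concordance_index <- function(y_true, y_pred) {
  check_pairs(y_true, y_pred)
  dt <- outer(y_true, y_true, `>`)
  if (!any(dt)) stop("all y_true equal: no strictly ordered pairs",
                     call. = FALSE)
  h <- (sign(outer(y_pred, y_pred, `-`)) + 1) / 2
  sum(h[dt]) / sum(dt)
}

#' Mean squared error
#'
#' @inheritParams concordance_index
#' @return Mean of squared residuals.
#' @export
mse <- function(y_true, y_pred) {
  check_pairs(y_true, y_pred)
  mean((y_true - y_pred)^2)
}

#' Pearson correlation of predictions and labels
#'
#' @inheritParams concordance_index
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(y_true, y_pred) {
  check_pairs(y_true, y_pred)
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) {
    stop("zero variance in y_true or y_pred", call. = FALSE)
  }
  stats::cor(y_true, y_pred)
}

#' The r_m^2 external-validation index
#'
#' `r_m^2 = r^2 * (1 - sqrt(r^2 - r_0^2))`, where `r^2` is the squared
#' Pearson correlation (regression with intercept) and `r_0^2` the squared
#' correlation of the least-squares fit through the origin.  A model with
#' `r_m^2 > 0.5` on a test set is conventionally considered acceptable.
#'
#' With the default `orientation = "obs_on_pred"`, the through-origin fit
#' regresses observations on predictions: `k = sum(y * yhat) / sum(yhat^2)`
#' and `r_0^2 = 1 - sum((y - k * yhat)^2) / sum((y - mean(y))^2)`.  The
#' alternative orientation swaps the roles of the two vectors.  If `r^2`
#' falls below `r_0^2` numerically the difference is clamped at zero, so
#' `r_m^2 <= r^2` always.
#'
#' @inheritParams concordance_index
#' @param orientation `"obs_on_pred"` (default) or `"pred_on_obs"`; which
#'   vector is regressed on which in the through-origin fit.
#' @return A list with `rm2`, `r2` and `r02`.
#' @export
rm2_index <- function(y_true, y_pred,
                      orientation = c("obs_on_pred", "pred_on_obs")) {
  orientation <- match.arg(orientation)
  check_pairs(y_true, y_pred)
  if (length(y_true) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) {
    stop("zero variance in y_true or y_pred", call. = FALSE)
  }
  r2 <- stats::cor(y_true, y_pred)^2
  if (orientation == "obs_on_pred") {
    obs <- y_true; fit <- y_pred
  } else {
    obs <- y_pred; fit <- y_true
  }
  k <- sum(obs * fit) / sum(fit^2)
  r02 <- 1 - sum((obs - k * fit)^2) / sum((obs - mean(obs))^2)
  diff <- max(r2 - r02, 0)
  list(rm2 = r2 * (1 - sqrt(diff)), r2 = r2, r02 = r02)
}

#' Area under the precision-recall curve after affinity thresholding
#'
#' Binarizes the true affinities at `threshold` (positive class:
#' `y_true >= threshold`), ranks by predicted affinity and accumulates the
#' step-wise area `sum (R_k - R_(k-1)) * P_k` over cut points taken after
#' every group of tied predictions.  Common thresholds in the field are a
#' pKd of 7 (Davis-style data) and a KIBA score of 12.1.
#'
#' @inheritParams concordance_index
#' @param threshold Affinity cut point defining the positive class.
#' @return The area under the precision-recall curve in `[0, 1]`.
#' @export
aupr_by_threshold <- function(y_true, y_pred, threshold) {
  check_pairs(y_true, y_pred)
  labels <- y_true >= threshold
  if (all(labels) || !any(labels)) {
    stop(sprintf("thresholding at %g leaves a single class", threshold),
         call. = FALSE)
  }
  pr_area(labels, y_pred)
}

# Step-wise PR area over descending-score cut points, ties grouped.
pr_area <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]
  scores <- scores[ord]
  P <- sum(labels)
  tp <- cumsum(labels)
  k <- seq_along(labels)
  # cut only after the last element of each tied-score group
  last_of_group <- c(scores[-1L] != scores[-length(scores)], TRUE)
  prec <- (tp / k)[last_of_group]
  rec <- (tp / P)[last_of_group]
  sum(diff(c(0, rec)) * prec)
}

#' Classification metrics for the binary (active/inactive) task variant
#'
#' Confusion-matrix metrics at a probability cutoff plus the rank-statistic
#' AUC (Mann-Whitney formulation, prediction ties counted half).
#'
#' @param labels Binary vector (0/1 or logical); both classes must be
#'   present for the AUC.
#' @param probabilities Numeric vector of predicted probabilities/scores.
#' @param cutoff Probability cutoff for the confusion matrix.
#' @return A list with `sen`, `acc`, `f1`, `prec`, `auc`.
#' @export
classification_metrics <- function(labels, probabilities, cutoff = 0.5) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(labels) == length(probabilities))
  if (all(labels == 1L) || all(labels == 0L)) {
    stop("single-class labels: AUC undefined", call. = FALSE)
  }
  pred <- as.integer(probabilities >= cutoff)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  sen <- tp / (tp + fn)
  acc <- (tp + tn) / length(labels)
  f1 <- if (prec + sen > 0) 2 * prec * sen / (prec + sen) else 0
  # AUC via the rank statistic: ties get average ranks, hence count half
  r <- rank(probabilities, ties.method = "average")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(sen = sen, acc = acc, f1 = f1, prec = prec, auc = auc)
}

#' Full regression evaluation panel
#'
#' Computes the standard DTA evaluation panel: concordance index, MSE,
#' Pearson R, the r_m^2 index, and (when `threshold` is given and both
#' classes occur) AUPR by affinity thresholding.
#'
#' @inheritParams concordance_index
#' @param threshold Optional affinity threshold for AUPR.
#' @return A `dta_metrics` object (list with `ci`, `mse`, `pearson_r`,
#'   `rm2`, `r2`, `r02`, and optionally `aupr`, `threshold`).
#' @export
evaluate_predictions <- function(y_true, y_pred, threshold = NULL) {
  rm2 <- rm2_index(y_true, y_pred)
  out <- list(ci = concordance_index(y_true, y_pred),
              mse = mse(y_true, y_pred),
              pearson_r = pearson(y_true, y_pred),
              rm2 = rm2$rm2, r2 = rm2$r2, r02 = rm2$r02)
  if (!is.null(threshold)) {
    out$aupr <- aupr_by_threshold(y_true, y_pred, threshold)
    out$threshold <- threshold
  }
  structure(out, class = "dta_metrics")
}

#' @export
print.dta_metrics <- function(x, digits = 4, ...) {
  cat("DTA evaluation metrics\n")
  cat(sprintf("  CI      : %.*f\n", digits, x$ci))
  cat(sprintf("  MSE     : %.*f\n", digits, x$mse))
  cat(sprintf("  R       : %.*f\n", digits, x$pearson_r))
  cat(sprintf("  r_m^2   : %.*f  (r^2 = %.*f, r_0^2 = %.*f)\n",
              digits, x$rm2, digits, x$r2, digits, x$r02))
  if (!is.null(x$aupr)) {
    cat(sprintf("  AUPR    : %.*f  (threshold %g)\n", digits, x$aupr,
                x$threshold))
  }
  invisible(x)
}
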