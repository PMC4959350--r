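#' ROC curve over a score sweep
#'
#' Builds the receiver operating characteristic by sweeping the decision
#' threshold over every distinct score (ties grouped), with higher scores
#' meaning "more pain-like". The curve starts at (0, 0) (threshold `Inf`,
#' nothing called positive) and ends at (1, 1); the trapezoidal area under it
#' equals the Mann-Whitney U statistic normalized by `n1 * n0` with ties
#' counted 1/2.
#'
#' @param data Data frame holding scores and reference labels.
#' @param truth Unquoted column of 0/1 reference labels (1 = pain).
#' @param score Unquoted column of numeric scores.
#' @return An object of class `roc_result`: list with `points` (tibble of
#'   `threshold`, `fpr`, `tpr`), `auc`, and `optimal` (one-row tibble from
#'   [optimal_operating_point()]).
#' @export
#' @examples
#' d <- tibble::tibble(pain = c(0, 0, 1, 1), p1 = c(0.1, 0.4, 0.35, 0.8))
#' roc <- roc_curve(d, pain, p1)
#' roc$auc
roc_curve <- function(data, truth, score) {
  labels <- dplyr::pull(data, {{ truth }})
  scores <- dplyr::pull(data, {{ score }})
  if (length(labels) != length(scores)) {
    stop("`truth` and `score` must have equal length", call. = FALSE)
  }
  assert_binary(labels, "truth")
  if (anyNA(scores)) stop("`score` contains missing values", call. = FALSE)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("ROC needs both classes present in `truth`; got a single class",
         call. = FALSE)
  }

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp_last <- cumsum(rle(s)$lengths) # last index of each tie group
  tp <- cumsum(l == 1)[grp_last]
  fp <- cumsum(l == 0)[grp_last]
  points <- tibble::tibble(
    threshold = c(Inf, s[grp_last]),
    fpr = c(0, fp / n0),
    tpr = c(0, tp / n1)
  )

  auc_val <- sum(diff(points$fpr) * (head(points$tpr, -1) + points$tpr[-1]) / 2)
  res <- structure(list(points = points, auc = auc_val, optimal = NULL,
                        n_pos = n1, n_neg = n0),
                   class = "roc_result")
  res$optimal <- optimal_operating_point(res)
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: %d points, AUC %.4f; optimal (FPR %.3f, TPR %.3f) at threshold %.4g>\n",
              nrow(x$points), x$auc, x$optimal$fpr, x$optimal$tpr,
              x$optimal$threshold))
  invisible(x)
}

#' Area under an ROC curve
#'
#' @param roc An object from [roc_curve()].
#' @return The trapezoidal AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  roc$auc
}

#' Optimal ROC operating point
#'
#' Selects the curve point minimizing the Euclidean distance to the ideal
#' corner (0, 1), \eqn{\sqrt{FPR^2 + (1 - TPR)^2}}: jointly high sensitivity
#' and specificity. Ties are broken toward higher TPR, then toward the lower
#' threshold.
#'
#' @param roc An object from [roc_curve()].
#' @return One-row tibble with `threshold`, `fpr`, `tpr`, `distance`.
#' @export
optimal_operating_point <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  pts <- roc$points
  d <- sqrt(pts$fpr^2 + (1 - pts$tpr)^2)
  cand <- which(d == min(d))
  cand <- cand[pts$tpr[cand] == max(pts$tpr[cand])]
  best <- cand[which.min(pts$threshold[cand])]
  tibble::tibble(threshold = pts$threshold[best], fpr = pts$fpr[best],
                 tpr = pts$tpr[best], distance = d[best])
}

#' Confusion-matrix rates
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and accuracy
#' `(TP+TN)/total` of hard 0/1 predictions. When a reference class is absent
#' the corresponding rate is undefined and reported as `NA` (never silently
#' 0).
#'
#' @param data Data frame holding reference labels and predictions.
#' @param truth Unquoted column of 0/1 reference labels.
#' @param estimate Unquoted column of 0/1 predictions.
#' @return One-row tibble with `sensitivity`, `specificity`, `accuracy`.
#' @export
#' @examples
#' d <- tibble::tibble(pain = c(1, 1, 1, 0, 0, 0, 0), pred = c(1, 1, 0, 0, 0, 0, 1))
#' confusion_metrics(d, pain, pred)
confusion_metrics <- function(data, truth, estimate) {
  labels <- dplyr::pull(data, {{ truth }})
  preds <- dplyr::pull(data, {{ estimate }})
  if (length(labels) != length(preds)) {
    stop("`truth` and `estimate` must have equal length", call. = FALSE)
  }
  assert_binary(labels, "truth")
  assert_binary(preds, "estimate")
  tp <- sum(labels == 1 & preds == 1)
  fn <- sum(labels == 1 & preds == 0)
  tn <- sum(labels == 0 & preds == 0)
  fp <- sum(labels == 0 & preds == 1)
  tibble::tibble(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(labels)
  )
}

#' @export
tidy.roc_result <- function(x, ...) x$points

#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(
    auc = x$auc,
    n_pos = x$n_pos,
    n_neg = x$n_neg,
    optimal_threshold = x$optimal$threshold,
    optimal_fpr = x$optimal$fpr,
    optimal_tpr = x$optimal$tpr
  )
}

#' Plot an ROC curve
#'
#' @param object An object from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot: the ROC step curve, the chance diagonal, and the optimal
#'   operating point.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = object$optimal, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Write ROC points and summary to disk
#'
#' @param roc An object from [roc_curve()].
#' @param points_path CSV path for the (threshold, FPR, TPR) sweep.
#' @param summary_path Optional JSON path for AUC and the optimal point.
#' @return `roc`, invisibly.
#' @export
write_roc <- function(roc, points_path, summary_path = NULL) {
  stopifnot(inherits(roc, "roc_result"))
  readr::write_csv(roc$points, points_path)
  if (!is.null(summary_path)) {
    jsonlite::write_json(
      list(auc = roc$auc, optimal = as.list(roc$optimal)),
      summary_path, auto_unbox = TRUE, digits = I(17)
    )
  }
  invisible(roc)
}
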