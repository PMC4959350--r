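#' Pooled-covariance linear discriminant scorer
#'
#' Fits the two-class linear discriminant by class-conditional Gaussians with
#' a shared covariance: the scoring direction is
#' \eqn{w = \Sigma^{-1}(\mu_1 - \mu_0)} with \eqn{\Sigma} the pooled
#' within-class covariance, and the score of an instance is \eqn{w^\top x}
#' (monotone in the estimated class-1 posterior). With two classes only one
#' discriminant dimension exists, so no dimensionality parameter arises.
#' Binary feature matrices frequently make \eqn{\Sigma} singular; pass
#' `ridge` to add `ridge * I` before inversion.
#'
#' @param x Numeric (typically 0/1) feature matrix, instances in rows.
#' @param labels 0/1 class labels, both classes present.
#' @param ridge Optional non-negative ridge added to the pooled covariance
#'   diagonal; `NULL` (default) errors on a singular covariance instead.
#' @return An object of class `painrbm_scorer`; use [predict()] to obtain
#'   numeric scores (higher = more class-1-like) on new data.
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40, 2), 20, 2))
#' s <- fit_linear_discriminant(x, rep(c(0, 1), each = 20))
#' head(predict(s, x))
fit_linear_discriminant <- function(x, labels, ridge = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  assert_binary(labels, "labels")
  check_two_classes(labels)
  x0 <- x[labels == 0, , drop = FALSE]
  x1 <- x[labels == 1, , drop = FALSE]
  mu0 <- colMeans(x0)
  mu1 <- colMeans(x1)
  pooled <- (crossprod(sweep(x0, 2, mu0)) + crossprod(sweep(x1, 2, mu1))) /
    (nrow(x) - 2)
  if (!is.null(ridge)) {
    stopifnot(is.numeric(ridge), ridge >= 0)
    pooled <- pooled + diag(ridge, ncol(x))
  }
  w <- tryCatch(
    solve(pooled, mu1 - mu0),
    error = function(e) {
      stop("pooled within-class covariance is singular; refit with a small ",
           "`ridge` (e.g. 1e-6)", call. = FALSE)
    }
  )
  structure(
    list(kind = "linear_discriminant", direction = w,
         center = (mu0 + mu1) / 2, n_features = ncol(x)),
    class = "painrbm_scorer"
  )
}

#' Principal-component projection feeding a linear max-margin classifier
#'
#' The second comparator: center the features, project onto the top
#' `n_components` variance directions (principal components), and fit a
#' linear support vector machine on the projection. The returned scorer emits
#' the SVM decision value, oriented so higher means more class-1-like.
#' Because the projection ignores class labels, class signal living in a
#' low-variance (discarded) direction is lost — the known failure mode that
#' motivates comparing against the discriminant approaches.
#'
#' @inheritParams fit_linear_discriminant
#' @param n_components Number of principal components kept (default 4). If it
#'   exceeds the rank of the centered matrix it is reduced with a warning.
#' @param cost Soft-margin cost parameter `C` of the linear SVM (default 1).
#' @return An object of class `painrbm_scorer`.
#' @export
fit_pca_margin_classifier <- function(x, labels, n_components = 4, cost = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  assert_binary(labels, "labels")
  check_two_classes(labels)
  stopifnot(n_components >= 1, cost > 0)

  pca <- prcomp(x, center = TRUE, scale. = FALSE)
  tol <- max(dim(x)) * .Machine$double.eps * max(pca$sdev, 0)
  rank <- sum(pca$sdev > tol)
  if (rank == 0) stop("centered feature matrix has rank 0", call. = FALSE)
  if (n_components > rank) {
    warning("n_components = ", n_components, " exceeds the rank (", rank,
            ") of the centered data; reduced to ", rank, call. = FALSE)
    n_components <- rank
  }
  proj <- pca$x[, seq_len(n_components), drop = FALSE]

  fit <- e1071::svm(x = proj, y = factor(labels, levels = c(0, 1)),
                    kernel = "linear", cost = cost, scale = FALSE)
  dv <- drop(attr(predict(fit, proj, decision.values = TRUE), "decision.values"))
  # orient decision values so higher = class 1
  flip <- if (mean(dv[labels == 1]) < mean(dv[labels == 0])) -1 else 1

  structure(
    list(kind = "pca_margin", center = pca$center,
         rotation = pca$rotation[, seq_len(n_components), drop = FALSE],
         svm = fit, flip = flip, n_features = ncol(x),
         n_components = n_components),
    class = "painrbm_scorer"
  )
}

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2) {
    stop("both classes must be present in `labels`", call. = FALSE)
  }
  invisible(labels)
}

#' @export
predict.painrbm_scorer <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (ncol(x) != object$n_features) {
    stop("`newdata` has ", ncol(x), " features; the scorer expects ",
         object$n_features, call. = FALSE)
  }
  if (object$kind == "linear_discriminant") {
    drop(sweep(x, 2, object$center) %*% object$direction)
  } else {
    proj <- sweep(x, 2, object$center) %*% object$rotation
    dv <- drop(attr(predict(object$svm, proj, decision.values = TRUE),
                    "decision.values"))
    object$flip * dv
  }
}

#' @export
print.painrbm_scorer <- function(x, ...) {
  cat(sprintf("<painrbm_scorer: %s over %d feature(s)%s>\n", x$kind,
              x$n_features,
              if (x$kind == "pca_margin")
                sprintf(", %d component(s)", x$n_components) else ""))
  invisible(x)
}
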