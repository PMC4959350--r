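#' Class posterior of the discriminant RBM
#'
#' A discriminant RBM is trained on visible vectors that concatenate the
#' binary feature vector `x` with the binary pain label `c` as the *last*
#' visible unit. The posterior odds of the two label completions follow from
#' the chain rule, which cancels the intractable partition function:
#' \deqn{\frac{p(c=0 \mid x)}{p(c=1 \mid x)} =
#'       \frac{p(x, c=0)}{p(x, c=1)} = e^{f(x \oplus 1) - f(x \oplus 0)},}
#' so \eqn{p(c=1 \mid x) = \sigma(f(x \oplus 0) - f(x \oplus 1))}. The
#' complement is formed as `1 - p1`, so the two columns sum to 1 exactly.
#'
#' @param x Binary feature matrix (instances in rows; a single vector is
#'   accepted). Must have one column fewer than the model's visible layer.
#' @param model A trained [rbm_train()] model (or [rbm_parameters()]) over the
#'   `(n_features + 1)`-dimensional visible layer, label last.
#' @return A tibble with one row per instance and columns `f0`, `f1` (free
#'   energies of the label-0 and label-1 completions), `p0`, `p1`.
#' @export
#' @examples
#' p <- rbm_parameters(matrix(0, 3, 2), b = c(0, 0, 2), c = c(0, 0))
#' rbm_class_posterior(c(1, 0), p) # label bias +2 -> p1 = plogis(2)
rbm_class_posterior <- function(x, model) {
  params <- as_rbm_parameters(model)
  m <- n_visible(params)
  if (m < 2) {
    stop("a discriminant RBM needs at least 2 visible units (features + label)",
         call. = FALSE)
  }
  X <- as_binary_matrix(x, m - 1, arg = "x")
  f0 <- rbm_free_energy(cbind(X, 0), params)
  f1 <- rbm_free_energy(cbind(X, 1), params)
  p1 <- plogis(f0 - f1)
  tibble::tibble(f0 = f0, f1 = f1, p0 = 1 - p1, p1 = p1)
}

#' Threshold the discriminant posterior into a hard label
#'
#' Predicts pain (`1`) when `p(c=1 | x) >= threshold`. The tie at exact
#' equality classifies as positive — the conservative direction for pain
#' detection. The threshold is typically chosen on an ROC curve with
#' [optimal_operating_point()].
#'
#' @inheritParams rbm_class_posterior
#' @param threshold Posterior cutoff, strictly inside (0, 1); default 0.5.
#' @return Integer vector of 0/1 predictions, one per instance.
#' @export
rbm_predict_label <- function(x, model, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    stop("`threshold` must be a single number strictly inside (0, 1)",
         call. = FALSE)
  }
  as.integer(rbm_class_posterior(x, model)$p1 >= threshold)
}

#' Hidden-unit representation of feature vectors
#'
#' The alternative classification route: expose the hidden-unit activation
#' probabilities as learned features for a downstream classifier. The label
#' unit is unknown at feature-extraction time and is set to 0 (the documented
#' convention) before computing the hidden conditional.
#'
#' @inheritParams rbm_class_posterior
#' @return Numeric matrix of hidden probabilities, one row per instance.
#' @export
rbm_hidden_features <- function(x, model) {
  params <- as_rbm_parameters(model)
  X <- as_binary_matrix(x, n_visible(params) - 1, arg = "x")
  p <- rbm_hidden_conditional(cbind(X, 0), params)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  p
}

#' Predict method for trained RBMs
#'
#' @param object A trained [rbm_train()] model used discriminatively
#'   (label as last visible unit).
#' @param newdata Binary feature matrix or data frame, instances in rows.
#' @param type `"prob"` for the posterior tibble, `"class"` for hard 0/1
#'   labels, `"score"` for the free-energy difference `f0 - f1` (monotone in
#'   the posterior, convenient for ROC sweeps).
#' @param threshold Cutoff used when `type = "class"`.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.rbm <- function(object, newdata, type = c("prob", "class", "score"),
                        threshold = 0.5, ...) {
  type <- match.arg(type)
  post <- rbm_class_posterior(newdata, object)
  switch(type,
    prob = post[c("p0", "p1")],
    class = {
      if (threshold <= 0 || threshold >= 1) {
        stop("`threshold` must be strictly inside (0, 1)", call. = FALSE)
      }
      as.integer(post$p1 >= threshold)
    },
    score = post$f0 - post$f1
  )
}

#' Write per-instance posteriors as CSV
#'
#' Emits the two-column posterior table (plus instance id and the thresholded
#' prediction) in the shape the evaluation module consumes.
#'
#' @inheritParams rbm_class_posterior
#' @param path Output CSV path.
#' @param threshold Cutoff for the `predicted` column.
#' @return The written tibble, invisibly.
#' @export
write_posteriors <- function(x, model, path, threshold = 0.5) {
  post <- rbm_class_posterior(x, model)
  out <- tibble::tibble(
    instance = seq_len(nrow(post)),
    p0 = post$p0,
    p1 = post$p1,
    predicted = as.integer(post$p1 >= threshold)
  )
  readr::write_csv(out, path)
  invisible(out)
}
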