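#' Fit a personalized feature normalizer
#'
#' Baseline physiology differs between individuals, so the "normal" regime of
#' every data item is fitted per patient: for each feature column the mean and
#' the sample standard deviation (denominator `n - 1`) are computed over that
#' patient's non-missing readings. Features with fewer than two observations
#' or zero variance cannot define a baseline and are dropped with a warning
#' (the drop list is kept on the object).
#'
#' @param data Data frame of one patient's numeric readings (rows are
#'   timestamps); missing cells are `NA`.
#' @param features Character vector of feature columns to fit; default every
#'   numeric column of `data`.
#' @param threshold Abnormality-probability cutoff used later by
#'   [binarize()]; default 0.5.
#' @return An object of class `feature_normalizer` with elements `stats`
#'   (tibble: `feature`, `mu`, `sigma`, `n_obs`), `dropped` (tibble:
#'   `feature`, `reason`) and `threshold`.
#' @export
#' @examples
#' fit_normalizer(data.frame(hr = c(61, 65, 70), spo2 = c(97, 97, 97)))
fit_normalizer <- function(data, features = NULL, threshold = 0.5) {
  stopifnot(is.data.frame(data) || is.matrix(data))
  data <- tibble::as_tibble(as.data.frame(data))
  if (is.null(features)) {
    features <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols) > 0) {
    stop("features not present in `data`: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly inside (0, 1)", call. = FALSE)
  }

  stats <- purrr::map_dfr(features, function(f) {
    x <- data[[f]]
    x <- x[!is.na(x)]
    tibble::tibble(
      feature = f,
      mu = if (length(x) >= 2) mean(x) else NA_real_,
      sigma = if (length(x) >= 2) sd(x) else NA_real_,
      n_obs = length(x)
    )
  })
  dropped <- dplyr::bind_rows(
    dplyr::transmute(dplyr::filter(stats, .data$n_obs < 2),
                     feature = .data$feature, reason = "fewer than 2 observations"),
    dplyr::transmute(dplyr::filter(stats, .data$n_obs >= 2 & .data$sigma == 0),
                     feature = .data$feature, reason = "zero variance")
  )
  stats <- dplyr::filter(stats, .data$n_obs >= 2, .data$sigma > 0)
  if (nrow(dropped) > 0) {
    warning("dropped ", nrow(dropped), " feature(s) without a usable baseline: ",
            paste(dropped$feature, collapse = ", "), call. = FALSE)
  }
  if (nrow(stats) == 0) {
    stop("no feature retains a usable Gaussian baseline; cannot preprocess",
         call. = FALSE)
  }
  structure(list(stats = stats, dropped = dropped, threshold = threshold),
            class = "feature_normalizer")
}

#' @export
print.feature_normalizer <- function(x, ...) {
  cat(sprintf("<feature_normalizer: %d feature(s), %d dropped, threshold %.2f>\n",
              nrow(x$stats), nrow(x$dropped), x$threshold))
  invisible(x)
}

#' @export
tidy.feature_normalizer <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$stats, dropped = FALSE, reason = NA_character_),
    tibble::tibble(feature = x$dropped$feature, mu = NA_real_, sigma = NA_real_,
                   n_obs = NA_integer_, dropped = TRUE, reason = x$dropped$reason)
  )
}

#' Probability that a reading is abnormal
#'
#' Maps a numeric reading `t` against a Gaussian baseline `Normal(mu, sigma)`
#' to the central-coverage probability
#' \deqn{p(x = 1) = 2\,\Phi(|t - \mu| / \sigma) - 1,}
#' i.e. the probability that a draw from the baseline lies closer to the mean
#' than `t`. It is 0 at the mean, tends to 1 in the tails, is symmetric in
#' `t - mu`, and is invariant under affine rescaling of the measurement. This
#' is the package's concrete reading of "fit the reading into the patient's
#' Gaussian": it is the unique symmetric choice that is monotone in the
#' z-score magnitude with a meaningful 0.5 cutoff.
#'
#' @param t Numeric reading(s).
#' @param mu Baseline mean (same units as `t`).
#' @param sigma Baseline standard deviation; must be positive.
#' @return Probabilities in `[0, 1)`, same length as `t`.
#' @export
#' @examples
#' abnormality_probability(c(0, 1, 3), mu = 0, sigma = 1)
abnormality_probability <- function(t, mu, sigma) {
  if (any(sigma <= 0)) stop("`sigma` must be positive", call. = FALSE)
  2 * pnorm(abs(t - mu) / sigma) - 1
}

#' Binarize a patient table against its fitted baseline
#'
#' Converts each numeric reading into a binary abnormality indicator:
#' `1` when `abnormality_probability(t) > threshold`, which for the default
#' `threshold = 0.5` is equivalent to `|t - mu| > z0 * sigma` with
#' `z0 = qnorm(0.75) ~ 0.6745`. Missing cells are imputed as 0 ("normal") and
#' flagged in the `missing_mask` attribute so downstream code can tell imputed
#' zeros from observed ones.
#'
#' @param data Data frame with the patient's readings; must contain every
#'   feature retained by the normalizer.
#' @param normalizer A [fit_normalizer()] object fitted on the same patient.
#' @return A tibble of 0/1 integer columns (one per retained feature, in
#'   normalizer order) with attribute `missing_mask`, a logical matrix marking
#'   imputed cells.
#' @export
binarize <- function(data, normalizer) {
  stopifnot(inherits(normalizer, "feature_normalizer"))
  data <- tibble::as_tibble(as.data.frame(data))
  feats <- normalizer$stats$feature
  missing_cols <- setdiff(feats, names(data))
  if (length(missing_cols) > 0) {
    stop("`data` lacks feature(s) the normalizer was fitted on: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- as.matrix(data[feats])
  mask <- is.na(raw)
  p <- abnormality_probability(
    raw,
    mu = matrix(normalizer$stats$mu, nrow(raw), length(feats), byrow = TRUE),
    sigma = matrix(normalizer$stats$sigma, nrow(raw), length(feats), byrow = TRUE)
  )
  x <- (p > normalizer$threshold) * 1L
  x[mask] <- 0L
  out <- tibble::as_tibble(as.data.frame(x))
  names(out) <- feats
  attr(out, "missing_mask") <- mask
  out
}

#' Write or read a normalizer sidecar file
#'
#' The per-feature baselines, the drop list and the threshold are stored as a
#' small JSON document next to the binarized data so a preprocessing run is
#' fully reconstructable.
#'
#' @param normalizer A [fit_normalizer()] object.
#' @param path JSON file path.
#' @return `write_normalizer()` returns `path` invisibly; `read_normalizer()`
#'   returns a `feature_normalizer`.
#' @export
write_normalizer <- function(normalizer, path) {
  stopifnot(inherits(normalizer, "feature_normalizer"))
  jsonlite::write_json(
    list(format = "painrbm/normalizer",
         threshold = normalizer$threshold,
         stats = normalizer$stats,
         dropped = normalizer$dropped),
    path, auto_unbox = TRUE, digits = I(17)
  )
  invisible(path)
}

#' @rdname write_normalizer
#' @export
read_normalizer <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "painrbm/normalizer")) {
    stop("`", path, "` is not a painrbm normalizer file", call. = FALSE)
  }
  dropped <- tibble::as_tibble(doc$dropped)
  if (nrow(dropped) == 0) {
    dropped <- tibble::tibble(feature = character(), reason = character())
  }
  structure(list(stats = tibble::as_tibble(doc$stats), dropped = dropped,
                 threshold = doc$threshold),
            class = "feature_normalizer")
}
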