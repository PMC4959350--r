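#' Configuration for a synthetic flowsheet cohort
#'
#' Describes a cohort of flowsheet-like patients with known ground truth.
#' Each patient gets a personal Gaussian baseline `Normal(mu_i, sigma_i)` per
#' data item; at each timestamp a latent abnormality bit
#' `z_i ~ Bernoulli(abnormality_rate)` decides whether the reading is drawn
#' from the baseline or from the baseline displaced by `shift` standard
#' deviations in a per-feature fixed direction (some items run high when
#' abnormal, others low — the direction information a binary abnormality code
#' cannot carry). The pain label is a function of the latent abnormality
#' pattern, optionally flipped with probability `label_noise`, and cells go
#' missing at `missing_rate`. Defaults mirror a realistic charting scale: 25
#' items and 1200 labelled rows per patient.
#'
#' @param n_patients Number of patients in the cohort.
#' @param n_features Data items per patient (default 25).
#' @param n_rows Labelled timestamps per patient (default 1200).
#' @param abnormality_rate Per-feature probability of the abnormal regime at
#'   any timestamp, in [0, 1) (default 0.25; 0 gives a purely in-regime
#'   patient).
#' @param shift Abnormal-state mean displacement in units of the baseline
#'   standard deviation (default 2).
#' @param label_rule One of `"linear"` (weighted abnormality count over
#'   designated items passes a cut), `"xor_pair"` (exclusive-or of two
#'   designated items — linearly inseparable in the latent bits), or
#'   `"count_threshold"` (total abnormal items reaches a threshold).
#' @param rule_params Optional list overriding the rule's defaults: `linear`
#'   uses `features` (default `1:10`), `weights` (default all 1) and `cut`
#'   (default 2.5); `xor_pair` uses `features` (default `c(1, 2)`);
#'   `count_threshold` uses `threshold` (default 7).
#' @param label_noise Probability of flipping the rule's label, in [0, 0.5)
#'   (default 0.05).
#' @param missing_rate Probability a cell is missing, in [0, 1) (default
#'   0.02).
#' @param seed Integer root seed; fully determines the cohort.
#' @return An object of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(n_patients = 1, n_features = 25,
                                    n_rows = 1200, abnormality_rate = 0.25,
                                    shift = 2, label_rule = c("linear", "xor_pair", "count_threshold"),
                                    rule_params = NULL, label_noise = 0.05,
                                    missing_rate = 0.02, seed = 1) {
  label_rule <- match.arg(label_rule)
  stopifnot(n_patients >= 1, n_features >= 1, n_rows >= 1,
            abnormality_rate >= 0, abnormality_rate < 1, shift > 0,
            label_noise >= 0, label_noise < 0.5,
            missing_rate >= 0, missing_rate < 1)
  defaults <- switch(label_rule,
    linear = list(features = seq_len(min(10, n_features)),
                  weights = rep(1, min(10, n_features)), cut = 2.5),
    xor_pair = list(features = c(1, 2)),
    count_threshold = list(threshold = 7)
  )
  rule_params <- modifyList(defaults, as.list(rule_params %||% list()))
  if (label_rule %in% c("linear", "xor_pair")) {
    if (max(rule_params$features) > n_features) {
      stop("label rule references feature ", max(rule_params$features),
           " but the cohort has only ", n_features, call. = FALSE)
    }
  }
  if (label_rule == "xor_pair" && length(rule_params$features) != 2) {
    stop("xor_pair needs exactly two designated features", call. = FALSE)
  }
  if (label_rule == "linear" &&
      length(rule_params$weights) != length(rule_params$features)) {
    stop("`weights` and `features` must have equal length", call. = FALSE)
  }
  structure(
    list(n_patients = n_patients, n_features = n_features, n_rows = n_rows,
         abnormality_rate = abnormality_rate, shift = shift,
         label_rule = label_rule, rule_params = rule_params,
         label_noise = label_noise, missing_rate = missing_rate, seed = seed),
    class = "synthetic_cohort_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a latent label rule to abnormality bits
#'
#' @param z Binary matrix of latent abnormality bits (rows are timestamps), or
#'   a single row vector.
#' @param rule Rule name as in [synthetic_cohort_config()].
#' @param params Rule parameter list (see [synthetic_cohort_config()]).
#' @return Integer 0/1 label vector, one per row of `z`.
#' @export
#' @examples
#' apply_label_rule(rbind(c(1, 0), c(1, 1)), "xor_pair", list(features = c(1, 2)))
apply_label_rule <- function(z, rule, params) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  assert_binary(z, "z")
  switch(rule,
    linear = {
      zz <- z[, params$features, drop = FALSE]
      as.integer(drop(zz %*% params$weights) > params$cut)
    },
    xor_pair = {
      as.integer(z[, params$features[1]] != z[, params$features[2]])
    },
    count_threshold = as.integer(rowSums(z) >= params$threshold),
    stop("unknown label rule: ", rule, call. = FALSE)
  )
}

#' Generate one synthetic patient
#'
#' Draws a full flowsheet-like table for one patient according to the cohort
#' configuration, together with the ground truth a real dataset never
#' provides: the latent abnormality matrix `z`, the generating baselines, the
#' per-feature shift direction and the noise-free labels.
#'
#' @param config A [synthetic_cohort_config()].
#' @param patient_seed Integer seed for this patient (default the config
#'   seed). The same `(config, patient_seed)` always yields the same patient.
#' @return An object of class `synthetic_patient`: list with `data` (tibble:
#'   `timestamp`, `item_*` readings with `NA` for missing cells, `pain`
#'   label) and `truth` (list: `z`, `mu`, `sigma`, `direction`,
#'   `clean_labels`, `patient_seed`).
#' @export
#' @examples
#' cfg <- synthetic_cohort_config(n_rows = 50, n_features = 4, seed = 7)
#' pat <- generate_patient(cfg)
#' head(pat$data)
generate_patient <- function(config, patient_seed = config$seed) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  nf <- config$n_features
  nr <- config$n_rows
  withr::with_seed(patient_seed, {
    mu <- runif(nf, 40, 160)       # vital-sign-like baselines
    sigma <- runif(nf, 2, 25)
    direction <- sample(c(-1, 1), nf, replace = TRUE)
    z <- matrix(rbinom(nr * nf, 1, config$abnormality_rate), nr, nf)
    noise <- matrix(rnorm(nr * nf), nr, nf)
    readings <- sweep(z * config$shift, 2, direction, "*")
    readings <- sweep(sweep(readings + noise, 2, sigma, "*"), 2, mu, "+")
    clean <- apply_label_rule(z, config$label_rule, config$rule_params)
    flips <- rbinom(nr, 1, config$label_noise)
    labels <- as.integer(xor(clean, flips))
    if (config$missing_rate > 0) {
      readings[matrix(runif(nr * nf) < config$missing_rate, nr, nf)] <- NA_real_
    }
    colnames(readings) <- sprintf("item_%02d", seq_len(nf))
    data <- dplyr::bind_cols(
      tibble::tibble(timestamp = seq_len(nr)),
      tibble::as_tibble(as.data.frame(readings)),
      tibble::tibble(pain = labels)
    )
    structure(
      list(data = data,
           truth = list(z = z, mu = mu, sigma = sigma, direction = direction,
                        clean_labels = clean, patient_seed = patient_seed)),
      class = "synthetic_patient"
    )
  })
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("<synthetic_patient: %d rows x %d items, %.1f%% pain labels, seed %d>\n",
              nrow(x$data), ncol(x$data) - 2, 100 * mean(x$data$pain),
              x$truth$patient_seed))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' @param config A [synthetic_cohort_config()].
#' @return List of [generate_patient()] results, one per patient; patient `i`
#'   uses the sub-seed `derive_seed(config$seed, i)`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  lapply(seq_len(config$n_patients), function(i) {
    generate_patient(config, patient_seed = derive_seed(config$seed, i))
  })
}

#' Write a synthetic patient to disk
#'
#' Emits the flowsheet CSV in the dialect [fit_normalizer()]/[binarize()]
#' read (empty cells for missing readings) plus a ground-truth sidecar: the
#' latent abnormality matrix as CSV and the generating parameters as JSON.
#'
#' @param patient A [generate_patient()] result.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem (default `"patient"`).
#' @return Named character vector of written paths, invisibly.
#' @export
write_patient <- function(patient, dir, stem = "patient") {
  stopifnot(inherits(patient, "synthetic_patient"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data_path <- file.path(dir, paste0(stem, ".csv"))
  z_path <- file.path(dir, paste0(stem, "_truth_z.csv"))
  meta_path <- file.path(dir, paste0(stem, "_truth.json"))
  readr::write_csv(patient$data, data_path, na = "")
  z <- tibble::as_tibble(as.data.frame(patient$truth$z))
  names(z) <- sprintf("item_%02d", seq_len(ncol(z)))
  readr::write_csv(z, z_path)
  jsonlite::write_json(
    list(format = "painrbm/synthetic_truth",
         mu = patient$truth$mu, sigma = patient$truth$sigma,
         direction = patient$truth$direction,
         clean_labels = patient$truth$clean_labels,
         patient_seed = patient$truth$patient_seed),
    meta_path, auto_unbox = TRUE, digits = I(17)
  )
  invisible(c(data = data_path, truth_z = z_path, truth_meta = meta_path))
}

#' Read a flowsheet CSV
#'
#' Reads the CSV dialect written by [write_patient()] (and expected from real
#' exports): one `timestamp` column, numeric item columns, and a 0/1 label
#' column; empty cells are missing readings.
#'
#' @param path CSV path.
#' @param label_col Name of the label column (default `"pain"`).
#' @return A tibble.
#' @export
read_flowsheet <- function(path, label_col = "pain") {
  data <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
  if (!label_col %in% names(data)) {
    stop("label column `", label_col, "` not found in ", path, call. = FALSE)
  }
  assert_binary(data[[label_col]], label_col)
  data
}
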