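#' Configuration for a full pain-classification experiment
#'
#' Bundles everything one experiment needs: the input (a flowsheet CSV path or
#' a synthetic-cohort configuration), the random test split, the RBM training
#' settings and the baseline settings. All randomness — split, weight
#' initialization, Gibbs noise — derives from the single `seed` via
#' [derive_seed()], so the whole report is a pure function of the inputs and
#' this configuration.
#'
#' @param input Path to a flowsheet CSV (see [read_flowsheet()]), or `NULL`
#'   to generate data from `cohort`.
#' @param cohort A [synthetic_cohort_config()] used when `input` is `NULL`.
#' @param label_col Name of the 0/1 pain-label column (default `"pain"`).
#' @param timestamp_col Name of the timestamp column to exclude from features
#'   (default `"timestamp"`).
#' @param test_fraction Fraction of rows held out for testing, in (0, 1)
#'   (default 0.20).
#' @param seed Root seed for the experiment (default 42).
#' @param stratify Stratify the split by label (default `FALSE`: plain uniform
#'   sampling).
#' @param threshold_selection Where the operating threshold is chosen:
#'   `"test"` picks the minimum-distance point on the *test* ROC (the
#'   conventional but optimistic protocol reported here), `"train"` picks it
#'   on a training ROC and applies it to the test set.
#' @param rbm List of [rbm_train()] settings (`n_hidden`, `k`,
#'   `learning_rate`, `epochs`, `batch_size`, `init_scale`).
#' @param pca_components Principal components kept by the PCA+SVM baseline
#'   (default 4).
#' @param svm_cost Linear-SVM cost (default 1).
#' @param lda_ridge Ridge added to the pooled covariance of the linear
#'   discriminant (default 1e-6; binary features are often collinear).
#' @param max_split_retries Resampling attempts when a split leaves a single
#'   class in either part (default 20).
#' @param out_dir Optional directory; when given, the report, ROC sweeps,
#'   posteriors, normalizer and trained model are written there.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(input = NULL, cohort = synthetic_cohort_config(),
                              label_col = "pain", timestamp_col = "timestamp",
                              test_fraction = 0.2, seed = 42, stratify = FALSE,
                              threshold_selection = c("test", "train"),
                              rbm = list(), pca_components = 4, svm_cost = 1,
                              lda_ridge = 1e-6, max_split_retries = 20,
                              out_dir = NULL) {
  threshold_selection <- match.arg(threshold_selection)
  stopifnot(test_fraction > 0, test_fraction < 1, max_split_retries >= 1)
  rbm_defaults <- list(n_hidden = 20, k = 1, learning_rate = 0.05, epochs = 200,
                       batch_size = 32, init_scale = 0.01)
  structure(
    list(input = input, cohort = cohort, label_col = label_col,
         timestamp_col = timestamp_col, test_fraction = test_fraction,
         seed = seed, stratify = stratify,
         threshold_selection = threshold_selection,
         rbm = modifyList(rbm_defaults, rbm), pca_components = pca_components,
         svm_cost = svm_cost, lda_ridge = lda_ridge,
         max_split_retries = max_split_retries, out_dir = out_dir),
    class = "experiment_config"
  )
}

split_indices <- function(labels, test_fraction, seed, stratify, max_retries) {
  n <- length(labels)
  n_test <- max(1L, round(n * test_fraction))
  for (try in seq_len(max_retries)) {
    test <- withr::with_seed(derive_seed(seed, 1000 + try), {
      if (stratify) {
        idx1 <- which(labels == 1)
        idx0 <- which(labels == 0)
        sort(c(sample(idx1, max(1L, round(length(idx1) * test_fraction))),
               sample(idx0, max(1L, round(length(idx0) * test_fraction)))))
      } else {
        sort(sample.int(n, n_test))
      }
    })
    train <- setdiff(seq_len(n), test)
    if (length(unique(labels[test])) == 2 && length(unique(labels[train])) == 2) {
      if (try > 1) message("split resampled ", try - 1, " time(s) to keep both classes")
      return(list(train = train, test = test))
    }
  }
  stop("could not obtain a two-class train/test split after ", max_retries,
       " attempts", call. = FALSE)
}

#' Run the full per-patient experiment
#'
#' Orchestrates the complete protocol on one patient: personalized
#' binarization, a random held-out test split (default 20%), training the
#' discriminant RBM on the feature-plus-label visible vectors, fitting the
#' two linear comparators on the same binarized training data, and evaluating
#' all three by ROC/AUC with sensitivity, specificity and accuracy at the
#' minimum-distance operating point.
#'
#' @param config An [experiment_config()].
#' @return An object of class `pain_experiment`: list with `report` (tibble:
#'   one row per model with `auc`, `sensitivity`, `specificity`, `accuracy`,
#'   `threshold`), `rocs` (named list of [roc_curve()] results), `models`
#'   (the trained RBM and baseline scorers), `normalizer`, `split`, and
#'   `config`.
#' @export
#' @examples
#' cfg <- experiment_config(
#'   cohort = synthetic_cohort_config(n_rows = 200, n_features = 6, seed = 3),
#'   rbm = list(epochs = 20), seed = 3
#' )
#' ex <- run_experiment(cfg)
#' ex$report
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  data <- if (!is.null(config$input)) {
    read_flowsheet(config$input, label_col = config$label_col)
  } else {
    generate_patient(config$cohort,
                     patient_seed = derive_seed(config$seed, 1))$data
  }
  labels <- as.integer(data[[config$label_col]])
  feature_cols <- setdiff(names(data), c(config$label_col, config$timestamp_col))

  normalizer <- fit_normalizer(data, features = feature_cols)
  xb <- binarize(data, normalizer)
  x <- as.matrix(xb)

  split <- split_indices(labels, config$test_fraction, config$seed,
                         config$stratify, config$max_split_retries)
  x_train <- x[split$train, , drop = FALSE]
  x_test <- x[split$test, , drop = FALSE]
  y_train <- labels[split$train]
  y_test <- labels[split$test]

  rbm_fit <- rbm_train(
    cbind(x_train, pain = y_train),
    n_hidden = config$rbm$n_hidden, k = config$rbm$k,
    learning_rate = config$rbm$learning_rate, epochs = config$rbm$epochs,
    batch_size = config$rbm$batch_size, init_scale = config$rbm$init_scale,
    seed = derive_seed(config$seed, 2)
  )
  lda_fit <- fit_linear_discriminant(x_train, y_train, ridge = config$lda_ridge)
  pca_fit <- fit_pca_margin_classifier(x_train, y_train,
                                       n_components = config$pca_components,
                                       cost = config$svm_cost)

  scores <- list(
    rbm = rbm_class_posterior(x_test, rbm_fit)$p1,
    pca_svm = predict(pca_fit, x_test),
    lda = predict(lda_fit, x_test)
  )
  train_scores <- list(
    rbm = rbm_class_posterior(x_train, rbm_fit)$p1,
    pca_svm = predict(pca_fit, x_train),
    lda = predict(lda_fit, x_train)
  )

  rocs <- purrr::map(scores, function(s) {
    roc_curve(tibble::tibble(truth = y_test, score = s), truth, score)
  })
  report <- purrr::imap_dfr(rocs, function(roc, model) {
    thr <- if (config$threshold_selection == "test") {
      roc$optimal$threshold
    } else {
      tr <- roc_curve(tibble::tibble(truth = y_train,
                                     score = train_scores[[model]]),
                      truth, score)
      tr$optimal$threshold
    }
    preds <- as.integer(scores[[model]] >= thr)
    cm <- confusion_metrics(tibble::tibble(truth = y_test, pred = preds),
                            truth, pred)
    tibble::tibble(model = model, auc = roc$auc, sensitivity = cm$sensitivity,
                   specificity = cm$specificity, accuracy = cm$accuracy,
                   threshold = thr)
  })

  result <- structure(
    list(report = report, rocs = rocs,
         models = list(rbm = rbm_fit, pca_svm = pca_fit, lda = lda_fit),
         normalizer = normalizer, split = split, config = config,
         test_scores = scores, test_labels = y_test),
    class = "pain_experiment"
  )
  if (!is.null(config$out_dir)) write_experiment(result, config$out_dir)
  result
}

#' Write every experiment artefact to a directory
#'
#' @param experiment A [run_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `experiment`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "pain_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(experiment$report, file.path(dir, "report.csv"))
  purrr::iwalk(experiment$rocs, function(roc, model) {
    write_roc(roc, file.path(dir, sprintf("roc_%s.csv", model)))
  })
  scores <- tibble::as_tibble(experiment$test_scores)
  scores$truth <- experiment$test_labels
  readr::write_csv(scores, file.path(dir, "test_scores.csv"))
  write_rbm(experiment$models$rbm, file.path(dir, "rbm_model.json"))
  write_normalizer(experiment$normalizer, file.path(dir, "normalizer.json"))
  invisible(experiment)
}

#' @export
print.pain_experiment <- function(x, ...) {
  cat("<pain_experiment>\n")
  print(as.data.frame(x$report), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
tidy.pain_experiment <- function(x, ...) x$report

#' @export
glance.pain_experiment <- function(x, ...) {
  tibble::tibble(
    n_train = length(x$split$train),
    n_test = length(x$split$test),
    n_features = nrow(x$normalizer$stats),
    n_dropped = nrow(x$normalizer$dropped),
    best_model = x$report$model[which.max(x$report$auc)],
    best_auc = max(x$report$auc),
    seed = x$config$seed
  )
}

#' Plot the test ROC curves of all models in an experiment
#'
#' @param object A [run_experiment()] result.
#' @param ... Unused.
#' @return A ggplot overlaying the per-model ROC curves.
#' @export
autoplot.pain_experiment <- function(object, ...) {
  pts <- purrr::imap_dfr(object$rocs, function(roc, model) {
    dplyr::mutate(roc$points,
                  model = sprintf("%s (AUC %.3f)", model, roc$auc))
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL, title = "Test ROC by model") +
    ggplot2::theme_minimal()
}
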