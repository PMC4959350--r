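#' Read and write trained RBM models as plain JSON
#'
#' Trained models are stored as a flat, diffable JSON document: the shapes,
#' the row-major weight array, both bias vectors, and an echo of the training
#' configuration including the seed. `read_rbm()` reconstructs an identical
#' `rbm` object (round-trips are exact because numbers are written at full
#' precision).
#'
#' @param model An `rbm` model from [rbm_train()], or bare [rbm_parameters()].
#' @param path File path for the JSON document.
#' @return `write_rbm()` returns `path` invisibly; `read_rbm()` returns an
#'   `rbm` object.
#' @export
write_rbm <- function(model, path) {
  params <- as_rbm_parameters(model)
  config <- if (inherits(model, "rbm")) model$config else NULL
  doc <- list(
    format = "painrbm/rbm",
    n_visible = nrow(params$W),
    n_hidden = ncol(params$W),
    W = as.numeric(t(params$W)), # row-major
    b = params$b,
    c = params$c,
    config = config
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_rbm
#' @export
read_rbm <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "painrbm/rbm")) {
    stop("`", path, "` is not a painrbm model file", call. = FALSE)
  }
  params <- rbm_parameters(
    W = matrix(doc$W, doc$n_visible, doc$n_hidden, byrow = TRUE),
    b = doc$b,
    c = doc$c
  )
  config <- doc$config
  if (is.null(config)) {
    params
  } else {
    structure(list(params = params, config = as.list(config)), class = "rbm")
  }
}
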