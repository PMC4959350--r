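#' Construct binary RBM parameters
#'
#' Bundles the weight matrix and bias vectors that define the energy surface
#' of a binary restricted Boltzmann machine (RBM) over `m` visible and `n`
#' hidden units,
#' \deqn{E(v, h) = -\sum_i b_i v_i - \sum_j c_j h_j - \sum_{i,j} v_i h_j w_{ij}.}
#'
#' @param W Numeric `m x n` weight matrix (visible by hidden), in
#'   dimensionless energy units.
#' @param b Numeric visible-bias vector of length `m`.
#' @param c Numeric hidden-bias vector of length `n`.
#' @return An object of class `rbm_parameters` with elements `W`, `b`, `c`.
#' @export
#' @examples
#' p <- rbm_parameters(W = matrix(0, 3, 2), b = rep(0, 3), c = rep(0, 2))
#' rbm_free_energy(c(1, 0, 1), p)
rbm_parameters <- function(W, b, c) {
  W <- as.matrix(W)
  storage.mode(W) <- "double"
  dimnames(W) <- NULL
  b <- unname(as.numeric(b))
  c <- unname(as.numeric(c))
  if (nrow(W) != length(b) || ncol(W) != length(c)) {
    stop("dimension mismatch: W must be length(b) x length(c)", call. = FALSE)
  }
  if (nrow(W) < 1 || ncol(W) < 1) {
    stop("an RBM needs at least one visible and one hidden unit", call. = FALSE)
  }
  if (!all(is.finite(W)) || !all(is.finite(b)) || !all(is.finite(c))) {
    stop("RBM parameters must be finite", call. = FALSE)
  }
  structure(list(W = W, b = b, c = c), class = "rbm_parameters")
}

#' @export
print.rbm_parameters <- function(x, ...) {
  cat(sprintf("<rbm_parameters: %d visible x %d hidden units>\n",
              nrow(x$W), ncol(x$W)))
  invisible(x)
}

# Accept either bare parameters or a trained `rbm` model everywhere.
as_rbm_parameters <- function(model) {
  if (inherits(model, "rbm_parameters")) return(model)
  if (inherits(model, "rbm")) return(model$params)
  stop("expected an `rbm` model or `rbm_parameters` object", call. = FALSE)
}

n_visible <- function(params) nrow(as_rbm_parameters(params)$W)
n_hidden <- function(params) ncol(as_rbm_parameters(params)$W)

#' Energy of a joint visible/hidden configuration
#'
#' Evaluates the RBM energy
#' \eqn{E(v,h) = -b^\top v - c^\top h - v^\top W h} for one binary visible
#' vector and one binary hidden vector. Lower energy means higher probability
#' under the Boltzmann distribution \eqn{p(v,h) = e^{-E(v,h)}/Z}.
#'
#' @param v Binary visible vector of length `m`.
#' @param h Binary hidden vector of length `n`.
#' @param params An [rbm_parameters()] object (or trained [rbm_train()] model).
#' @return A single numeric energy value.
#' @export
rbm_energy <- function(v, h, params) {
  params <- as_rbm_parameters(params)
  v <- as.numeric(v)
  h <- as.numeric(h)
  assert_binary(v, "v")
  assert_binary(h, "h")
  if (length(v) != n_visible(params) || length(h) != n_hidden(params)) {
    stop("dimension mismatch between (v, h) and the parameters", call. = FALSE)
  }
  -sum(params$b * v) - sum(params$c * h) - drop(v %*% params$W %*% h)
}

#' Free energy of visible configurations
#'
#' The free energy \eqn{f(v) = -\log \sum_h e^{-E(v,h)}} determines the
#' marginal probability of a visible vector, \eqn{p(v) = e^{-f(v)}/Z}. For
#' binary hidden units the sum over the \eqn{2^n} hidden states collapses to
#' the closed form
#' \deqn{f(v) = -b^\top v - \sum_j \log(1 + e^{c_j + W_{\cdot j}^\top v}),}
#' evaluated here with a numerically stable softplus so that large activations
#' do not overflow.
#'
#' @param v Binary visible vector of length `m`, or a matrix with one such
#'   vector per row.
#' @param params An [rbm_parameters()] object (or trained [rbm_train()] model).
#' @return Numeric vector of free energies, one per row of `v`.
#' @export
rbm_free_energy <- function(v, params) {
  params <- as_rbm_parameters(params)
  V <- as_binary_matrix(v, n_visible(params))
  act <- sweep(V %*% params$W, 2, params$c, "+")
  drop(-(V %*% params$b) - rowSums(softplus(act)))
}

#' Exact log partition function by enumeration (oracle)
#'
#' Computes \eqn{\log Z = \log \sum_v e^{-f(v)}} by enumerating all \eqn{2^m}
#' visible configurations with a log-sum-exp reduction. \eqn{Z} normalizes the
#' Boltzmann distribution; it is intractable in general and this routine is an
#' enumeration oracle for testing and small-model diagnostics only, refused
#' above 20 visible or 20 hidden units.
#'
#' @inheritParams rbm_free_energy
#' @return The scalar \eqn{\log Z}.
#' @export
rbm_log_partition <- function(params) {
  params <- as_rbm_parameters(params)
  m <- n_visible(params)
  n <- n_hidden(params)
  if (m > 20 || n > 20) {
    stop("rbm_log_partition is an enumeration oracle only; it requires at most ",
         "20 visible and 20 hidden units", call. = FALSE)
  }
  logsumexp(-rbm_free_energy(all_binary_states(m), params))
}

#' Factorized conditional distributions of an RBM
#'
#' Because the RBM graph is bipartite (no within-layer connections), the
#' conditional of each layer given the other factorizes into independent
#' logistic units: \eqn{p(h_j = 1 \mid v) = \sigma(c_j + W_{\cdot j}^\top v)}
#' and \eqn{p(v_i = 1 \mid h) = \sigma(b_i + W_{i \cdot} h)}.
#'
#' @param v,h Binary vector (or matrix of row vectors) for the conditioning
#'   layer.
#' @inheritParams rbm_free_energy
#' @return Numeric vector (or matrix) of Bernoulli probabilities in (0, 1).
#' @export
rbm_hidden_conditional <- function(v, params) {
  params <- as_rbm_parameters(params)
  V <- as_binary_matrix(v, n_visible(params))
  p <- plogis(sweep(V %*% params$W, 2, params$c, "+"))
  if (nrow(p) == 1) drop(p) else p
}

#' @rdname rbm_hidden_conditional
#' @export
rbm_visible_conditional <- function(h, params) {
  params <- as_rbm_parameters(params)
  H <- as_binary_matrix(h, n_hidden(params), arg = "h")
  p <- plogis(sweep(H %*% t(params$W), 2, params$b, "+"))
  if (nrow(p) == 1) drop(p) else p
}

#' One step of alternating Gibbs sampling
#'
#' Samples `h ~ Bernoulli(p(h | v))` then `v' ~ Bernoulli(p(v | h))`, the
#' transition underlying contrastive-divergence training. Uses (and advances)
#' R's global RNG stream, so results are deterministic after `set.seed()` or
#' inside [withr::with_seed()].
#'
#' @param v Binary visible vector (or matrix of row vectors).
#' @inheritParams rbm_free_energy
#' @return A list with binary `h` and `v_next` of the same row count as `v`.
#' @export
rbm_gibbs_step <- function(v, params) {
  params <- as_rbm_parameters(params)
  V <- as_binary_matrix(v, n_visible(params))
  ph <- plogis(sweep(V %*% params$W, 2, params$c, "+"))
  H <- (matrix(runif(length(ph)), nrow(ph), ncol(ph)) < ph) * 1
  pv <- plogis(sweep(H %*% t(params$W), 2, params$b, "+"))
  Vn <- (matrix(runif(length(pv)), nrow(pv), ncol(pv)) < pv) * 1
  if (nrow(V) == 1) list(h = drop(H), v_next = drop(Vn)) else list(h = H, v_next = Vn)
}

#' Contrastive-divergence gradient estimate (CD-k)
#'
#' Estimates the log-likelihood gradient as the difference between data-clamped
#' statistics and statistics after `k` steps of Gibbs sampling started at the
#' data. The chain uses sampled hidden (and intermediate visible) states, but
#' the final visible reconstruction and final hidden statistics use
#' probabilities rather than samples — a standard variance-reduction choice.
#' Consumes the global RNG stream (seed it for reproducibility).
#'
#' @param batch Binary matrix, one training vector per row (a single vector is
#'   accepted).
#' @inheritParams rbm_free_energy
#' @param k Number of Gibbs steps (`k >= 1`); `k = 1` is the classic CD-1.
#' @return A list with `dW` (`m x n`), `db` (`m`), `dc` (`n`): the estimated
#'   ascent direction on the mean training log-likelihood.
#' @export
rbm_cd_gradient <- function(batch, params, k = 1) {
  params <- as_rbm_parameters(params)
  if (length(batch) == 0) stop("`batch` must be non-empty", call. = FALSE)
  V0 <- as_binary_matrix(batch, n_visible(params), arg = "batch")
  stopifnot(k >= 1)
  B <- nrow(V0)

  ph0 <- plogis(sweep(V0 %*% params$W, 2, params$c, "+"))
  Vk <- V0
  for (step in seq_len(k)) {
    ph <- plogis(sweep(Vk %*% params$W, 2, params$c, "+"))
    H <- (matrix(runif(length(ph)), nrow(ph), ncol(ph)) < ph) * 1
    pv <- plogis(sweep(H %*% t(params$W), 2, params$b, "+"))
    if (step < k) {
      Vk <- (matrix(runif(length(pv)), nrow(pv), ncol(pv)) < pv) * 1
    } else {
      Vk <- pv # final reconstruction uses probabilities
    }
  }
  phk <- plogis(sweep(Vk %*% params$W, 2, params$c, "+"))

  list(
    dW = (t(V0) %*% ph0 - t(Vk) %*% phk) / B,
    db = colMeans(V0) - colMeans(Vk),
    dc = colMeans(ph0) - colMeans(phk)
  )
}

#' Train a binary RBM by minibatch contrastive divergence
#'
#' Performs stochastic gradient ascent on the training log-likelihood using
#' the CD-k estimate of [rbm_cd_gradient()]. Weights are initialized
#' `Normal(0, init_scale^2)` and biases at zero. The whole trajectory —
#' initialization, epoch shuffles and Gibbs noise — is a deterministic
#' function of `seed`, so identical calls return bit-identical parameters.
#'
#' @param data Binary matrix (or data frame) of training vectors, one per row.
#' @param n_hidden Number of hidden units; in pain-state experiments values
#'   between 15 and 30 are typical (default 20).
#' @param k Gibbs chain length for CD-k (default 1).
#' @param learning_rate Step size for the gradient ascent (default 0.05).
#' @param epochs Number of passes over the data (default 200).
#' @param batch_size Minibatch size (default 32).
#' @param seed Integer seed controlling the full training trajectory.
#' @param init_scale Standard deviation of the Normal weight initialization
#'   (default 0.01); 0 gives a deterministic all-zero start.
#' @return An object of class `rbm`: a list with `params`
#'   ([rbm_parameters()]) and `config` (the training settings, seed included).
#' @export
#' @examples
#' x <- matrix(rbinom(200, 1, 0.4), 50, 4)
#' fit <- rbm_train(x, n_hidden = 3, epochs = 5, seed = 1)
#' rbm_free_energy(c(1, 0, 0, 1), fit)
rbm_train <- function(data, n_hidden = 20, k = 1, learning_rate = 0.05,
                      epochs = 200, batch_size = 32, seed = 1,
                      init_scale = 0.01) {
  if (is.data.frame(data)) data <- as.matrix(data)
  if (is.null(dim(data))) data <- matrix(data, nrow = 1)
  if (nrow(data) == 0) stop("`data` must contain at least one vector", call. = FALSE)
  assert_binary(data, "data")
  storage.mode(data) <- "double"
  stopifnot(n_hidden >= 1, k >= 1, learning_rate >= 0, epochs >= 1,
            batch_size >= 1, init_scale >= 0)
  m <- ncol(data)
  N <- nrow(data)

  params <- withr::with_seed(seed, {
    params <- rbm_parameters(
      W = matrix(rnorm(m * n_hidden, sd = init_scale), m, n_hidden),
      b = rep(0, m),
      c = rep(0, n_hidden)
    )
    for (epoch in seq_len(epochs)) {
      idx <- sample.int(N)
      starts <- seq(1, N, by = batch_size)
      for (s in starts) {
        rows <- idx[s:min(s + batch_size - 1, N)]
        g <- rbm_cd_gradient(data[rows, , drop = FALSE], params, k = k)
        params$W <- params$W + learning_rate * g$dW
        params$b <- params$b + learning_rate * g$db
        params$c <- params$c + learning_rate * g$dc
      }
    }
    if (!all(is.finite(params$W)) || !all(is.finite(params$b)) ||
        !all(is.finite(params$c))) {
      stop("training produced non-finite parameters; lower the learning rate",
           call. = FALSE)
    }
    params
  })

  structure(
    list(
      params = params,
      config = list(n_hidden = n_hidden, k = k, learning_rate = learning_rate,
                    epochs = epochs, batch_size = batch_size, seed = seed,
                    init_scale = init_scale)
    ),
    class = "rbm"
  )
}

#' @export
print.rbm <- function(x, ...) {
  cat(sprintf("<rbm: %d visible x %d hidden units; CD-%d, %d epochs, seed %d>\n",
              n_visible(x$params), n_hidden(x$params), x$config$k,
              x$config$epochs, x$config$seed))
  invisible(x)
}

#' @export
tidy.rbm <- function(x, ...) {
  p <- x$params
  w <- tibble::tibble(
    term = sprintf("w[%d,%d]", row(p$W), col(p$W)),
    unit = "weight",
    visible = as.integer(row(p$W)),
    hidden = as.integer(col(p$W)),
    estimate = as.numeric(p$W)
  )
  b <- tibble::tibble(term = sprintf("b[%d]", seq_along(p$b)),
                      unit = "visible_bias", visible = seq_along(p$b),
                      hidden = NA_integer_, estimate = p$b)
  c_ <- tibble::tibble(term = sprintf("c[%d]", seq_along(p$c)),
                       unit = "hidden_bias", visible = NA_integer_,
                       hidden = seq_along(p$c), estimate = p$c)
  dplyr::bind_rows(w, b, c_)
}

#' @export
glance.rbm <- function(x, ...) {
  tibble::tibble(
    n_visible = n_visible(x$params),
    n_hidden = n_hidden(x$params),
    k = x$config$k,
    learning_rate = x$config$learning_rate,
    epochs = x$config$epochs,
    batch_size = x$config$batch_size,
    seed = x$config$seed
  )
}

#' Exact training log-likelihood and gradient (enumeration oracles)
#'
#' `rbm_log_likelihood()` returns the mean log-likelihood
#' \eqn{\frac{1}{N}\sum_i (-f(v_i)) - \log Z} of binary vectors under the
#' model, and `rbm_exact_gradient()` the exact gradient of that quantity
#' (data-clamped statistics minus exact model expectations computed by visible
#' enumeration). Both inherit the enumeration caps of [rbm_log_partition()]
#' and exist for testing, diagnostics and CD-k bias studies, not for
#' production-size models.
#'
#' @param data Binary matrix of visible vectors, one per row.
#' @inheritParams rbm_free_energy
#' @return `rbm_log_likelihood()`: a scalar. `rbm_exact_gradient()`: a list
#'   with `dW`, `db`, `dc`.
#' @export
rbm_log_likelihood <- function(data, params) {
  params <- as_rbm_parameters(params)
  mean(-rbm_free_energy(data, params)) - rbm_log_partition(params)
}

#' @rdname rbm_log_likelihood
#' @export
rbm_exact_gradient <- function(data, params) {
  params <- as_rbm_parameters(params)
  V <- as_binary_matrix(data, n_visible(params), arg = "data")
  states <- all_binary_states(n_visible(params))
  logZ <- rbm_log_partition(params)
  pv <- exp(-rbm_free_energy(states, params) - logZ)

  ph_data <- plogis(sweep(V %*% params$W, 2, params$c, "+"))
  ph_model <- plogis(sweep(states %*% params$W, 2, params$c, "+"))

  list(
    dW = t(V) %*% ph_data / nrow(V) - t(states * pv) %*% ph_model,
    db = colMeans(V) - drop(pv %*% states),
    dc = colMeans(ph_data) - drop(pv %*% ph_model)
  )
}
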