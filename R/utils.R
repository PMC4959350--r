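# Internal numeric and RNG helpers shared across modules.

# Numerically stable log(1 + exp(x)); the naive form overflows past x ~ 710.
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a reproducible sub-stream seed from a root seed
#'
#' Every source of randomness in the package (synthetic cohorts, train/test
#' splits, weight initialization, Gibbs sampling) draws its seed from one root
#' seed through this map, so a single integer reproduces a whole experiment.
#' The result always lies in `[0, 2^31 - 2]`.
#'
#' @param seed Integer root seed.
#' @param offset Integer stream offset (distinct per consumer).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(42, 1)
derive_seed <- function(seed, offset) {
  stopifnot(length(seed) == 1, length(offset) == 1, is.finite(seed), is.finite(offset))
  # 2147483629 is prime and < 2^31; arithmetic kept in doubles (exact < 2^53)
  as.integer(((abs(as.numeric(seed)) %% 1000003) * 1009 + abs(as.numeric(offset))) %% 2147483629)
}

assert_binary <- function(x, arg = deparse(substitute(x))) {
  if (!is.numeric(x) || anyNA(x) || !all(x == 0 | x == 1)) {
    stop(sprintf("`%s` must contain only 0/1 entries", arg), call. = FALSE)
  }
  invisible(x)
}

# Coerce a vector or matrix of binary rows to an N x m matrix.
as_binary_matrix <- function(v, m, arg = "v") {
  if (is.data.frame(v)) v <- as.matrix(v)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  assert_binary(v, arg)
  if (ncol(v) != m) {
    stop(sprintf("`%s` has %d columns but the model expects %d", arg, ncol(v), m),
         call. = FALSE)
  }
  storage.mode(v) <- "double"
  dimnames(v) <- NULL
  v
}

# All 2^n binary configurations as a (2^n) x n matrix, row i = bits of i - 1.
all_binary_states <- function(n) {
  stopifnot(n >= 1, n <= 24)
  m <- t(vapply(0:(2^n - 1), function(i) as.integer(intToBits(i)[seq_len(n)]),
                integer(n)))
  storage.mode(m) <- "double"
  m
}
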