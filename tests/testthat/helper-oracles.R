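# Independent brute-force oracles used across tests. Everything here works
# from the energy definition by explicit enumeration, never through the
# package's closed-form code paths it is meant to check.

enum_states <- function(n) {
  m <- as.matrix(rev(expand.grid(rep(list(c(0, 1)), n)))[, n:1, drop = FALSE]) * 1
  dimnames(m) <- NULL
  m
}

oracle_lse <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

row_lse <- function(X) {
  m <- apply(X, 1, max)
  m + log(rowSums(exp(X - m)))
}

oracle_energy <- function(v, h, p) {
  -sum(p$b * v) - sum(p$c * h) - as.numeric(t(v) %*% p$W %*% h)
}

# Energy of every (v, h) pair: rows = visible states, cols = hidden states.
oracle_energy_matrix <- function(p) {
  V <- enum_states(length(p$b))
  H <- enum_states(length(p$c))
  -outer(drop(V %*% p$b), rep(1, nrow(H))) -
    outer(rep(1, nrow(V)), drop(H %*% p$c)) -
    V %*% p$W %*% t(H)
}

# Free energy of one visible vector by summing over all hidden states.
oracle_free_energy <- function(v, p) {
  H <- enum_states(length(p$c))
  -oracle_lse(-apply(H, 1, function(h) oracle_energy(v, h, p)))
}

# Free energies of every visible state at once.
oracle_free_energy_all <- function(p) {
  -row_lse(-oracle_energy_matrix(p))
}

oracle_log_partition <- function(p) {
  oracle_lse(-oracle_energy_matrix(p))
}

# p(h_j = 1 | v) from the joint, by enumeration.
oracle_hidden_conditional <- function(v, p) {
  H <- enum_states(length(p$c))
  w <- exp(-apply(H, 1, function(h) oracle_energy(v, h, p)))
  unname(drop(w %*% H) / sum(w))
}

oracle_visible_conditional <- function(h, p) {
  V <- enum_states(length(p$b))
  w <- exp(-apply(V, 1, function(v) oracle_energy(v, h, p)))
  unname(drop(w %*% V) / sum(w))
}

# Discriminant posterior p(c = 1 | x) from the enumerated joint (label last).
oracle_class_posterior <- function(x, p) {
  w0 <- exp(-oracle_free_energy(c(x, 0), p))
  w1 <- exp(-oracle_free_energy(c(x, 1), p))
  w1 / (w0 + w1)
}

# Pairwise Mann-Whitney AUC with ties counted 1/2.
oracle_auc_pairwise <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

random_rbm <- function(m, n, scale = 0.8) {
  rbm_parameters(
    W = matrix(rnorm(m * n, sd = scale), m, n),
    b = rnorm(m, sd = scale),
    c = rnorm(n, sd = scale)
  )
}

# Exact sampler from an enumerable RBM's visible marginal.
sample_visible_exact <- function(p, n_samples) {
  V <- enum_states(length(p$b))
  prob <- exp(-oracle_free_energy_all(p))
  prob <- prob / sum(prob)
  V[sample.int(nrow(V), n_samples, replace = TRUE, prob = prob), , drop = FALSE]
}
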