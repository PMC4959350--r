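test_that("energy evaluates the bilinear form exactly", {
  p <- rbm_parameters(W = matrix(2), b = 0.5, c = -0.25)
  expect_equal(rbm_energy(1, 1, p), -0.5 + 0.25 - 2)
  expect_equal(rbm_energy(0, 0, p), 0)

  # all-zero configurations have zero energy under any parameters
  withr::with_seed(11, {
    for (i in 1:5) {
      p <- random_rbm(sample(2:6, 1), sample(1:5, 1))
      expect_identical(rbm_energy(rep(0, length(p$b)), rep(0, length(p$c)), p), 0)
      v <- rbinom(length(p$b), 1, 0.5)
      h <- rbinom(length(p$c), 1, 0.5)
      expect_equal(rbm_energy(v, h, p), oracle_energy(v, h, p))
    }
  })

  expect_error(rbm_energy(c(1, 0), c(1), rbm_parameters(matrix(1), 0, 0)),
               "dimension")
  expect_error(rbm_energy(0.5, 1, rbm_parameters(matrix(1), 0, 0)), "0/1")
})

test_that("free energy matches hidden-state enumeration on random models", {
  withr::with_seed(21, {
    for (i in 1:30) {
      m <- sample(2:8, 1)
      n <- sample(1:8, 1)
      p <- random_rbm(m, n)
      fe <- rbm_free_energy(enum_states(m), p)
      fe_oracle <- oracle_free_energy_all(p)
      expect_equal(fe, fe_oracle, tolerance = 1e-12)
    }
  })
})

test_that("free energy collapses to -b.v - n log 2 when W and c vanish", {
  b <- c(0.3, -1.2, 2)
  p <- rbm_parameters(matrix(0, 3, 4), b, rep(0, 4))
  v <- c(1, 0, 1)
  expect_equal(rbm_free_energy(v, p), -sum(b * v) - 4 * log(2))
})

test_that("free energy is finite under extreme activations", {
  p <- rbm_parameters(matrix(0, 2, 2), c(0, 0), c(1000, -1000))
  f <- rbm_free_energy(c(1, 1), p)
  expect_true(is.finite(f))
  # softplus linear regime: log(1 + e^1000) ~ 1000; the -1000 unit adds ~ 0
  expect_equal(f, -1000, tolerance = 1e-9)
})

test_that("a bias shift on a pinned unit shifts the free energy predictably", {
  withr::with_seed(31, {
    p <- random_rbm(4, 3)
    v <- c(1, 0, 1, 1) # unit 1 pinned at 1
    delta <- 0.73
    p2 <- p
    p2$b[1] <- p2$b[1] + delta
    expect_equal(rbm_free_energy(v, p2), rbm_free_energy(v, p) - delta)
  })
})

test_that("exact log partition normalizes the distribution", {
  # all-zero parameters: uniform over 2^(m+n) configurations
  p0 <- rbm_parameters(matrix(0, 3, 2), rep(0, 3), rep(0, 2))
  expect_equal(rbm_log_partition(p0), 5 * log(2))

  withr::with_seed(41, {
    for (i in 1:10) {
      p <- random_rbm(sample(2:6, 1), sample(1:6, 1))
      logZ <- rbm_log_partition(p)
      total <- sum(exp(-rbm_free_energy(enum_states(length(p$b)), p) - logZ))
      expect_equal(total, 1, tolerance = 1e-10)
    }
    # double enumeration over all 16 (v, h) pairs
    p <- random_rbm(2, 2)
    expect_equal(rbm_log_partition(p), oracle_log_partition(p), tolerance = 1e-12)
  })

  big <- rbm_parameters(matrix(0, 21, 2), rep(0, 21), rep(0, 2))
  expect_error(rbm_log_partition(big), "oracle only")
})

test_that("layer conditionals factorize as logistic units", {
  p0 <- rbm_parameters(matrix(0, 3, 4), rep(0, 3), rep(0, 4))
  expect_equal(rbm_hidden_conditional(c(1, 0, 1), p0), rep(0.5, 4))
  expect_equal(rbm_visible_conditional(c(0, 1, 0, 1), p0), rep(0.5, 3))

  sat <- rbm_parameters(matrix(0, 2, 2), c(-50, -50), c(50, 50))
  expect_equal(rbm_hidden_conditional(c(0, 0), sat), c(1, 1), tolerance = 1e-15)
  expect_equal(rbm_visible_conditional(c(0, 0), sat), c(0, 0), tolerance = 1e-15)

  withr::with_seed(51, {
    for (i in 1:10) {
      p <- random_rbm(sample(2:5, 1), sample(1:5, 1))
      v <- rbinom(length(p$b), 1, 0.5)
      h <- rbinom(length(p$c), 1, 0.5)
      expect_equal(rbm_hidden_conditional(v, p), oracle_hidden_conditional(v, p),
                   tolerance = 1e-12)
      expect_equal(rbm_visible_conditional(h, p), oracle_visible_conditional(h, p),
                   tolerance = 1e-12)
    }
  })
})

test_that("gibbs sampling is seed-deterministic and honours saturation", {
  withr::with_seed(61, p <- random_rbm(4, 3))
  v <- c(1, 0, 1, 0)
  s1 <- withr::with_seed(99, rbm_gibbs_step(v, p))
  s2 <- withr::with_seed(99, rbm_gibbs_step(v, p))
  expect_identical(s1, s2)

  sat <- rbm_parameters(matrix(0, 2, 2), c(50, -50), c(50, -50))
  s <- withr::with_seed(7, rbm_gibbs_step(c(1, 1), sat))
  expect_equal(s$h, c(1, 0))
  expect_equal(s$v_next, c(1, 0))
})

test_that("with zero weights the chain's visible means converge to logistic(b)", {
  b <- c(-1, 0, 0.5)
  p <- rbm_parameters(matrix(0, 3, 2), b, c(0, 0))
  n_steps <- 10000
  vs <- withr::with_seed(71, {
    v <- c(0, 0, 0)
    out <- matrix(0, n_steps, 3)
    for (i in seq_len(n_steps)) {
      v <- rbm_gibbs_step(v, p)$v_next
      out[i, ] <- v
    }
    out
  })
  target <- plogis(b)
  mc_sd <- sqrt(target * (1 - target) / n_steps)
  expect_true(all(abs(colMeans(vs) - target) < 3 * mc_sd))
})

test_that("CD statistics are exact on degenerate batches and unbiased for b at the fixed point", {
  # With W = 0 the negative phase is deterministic (reconstruction and final
  # hidden statistics use probabilities), so CD-1 has a closed form: the
  # positive term is exactly v p(h|v)' averaged over the batch.
  b <- c(-0.4, 0.9, 0.1, -1.5)
  cc <- c(0.3, -0.7, 1.1)
  p <- rbm_parameters(matrix(0, 4, 3), b, cc)
  v <- c(1, 0, 1, 1)
  batch <- rbind(v, v, v)
  g <- withr::with_seed(1, rbm_cd_gradient(batch, p, k = 1))
  expect_equal(g$dW, outer(v, plogis(cc)) - outer(plogis(b), plogis(cc)))
  expect_equal(g$db, v - plogis(b))
  expect_equal(g$dc, plogis(cc) - plogis(cc))

  # same seed -> identical estimate on a non-degenerate model
  withr::with_seed(81, pr <- random_rbm(4, 3))
  expect_identical(withr::with_seed(5, rbm_cd_gradient(batch, pr)),
                   withr::with_seed(5, rbm_cd_gradient(batch, pr)))

  # when logistic(b) equals the batch mean and W = 0, E[db] = 0
  pm <- c(0.2, 0.5, 0.8)
  pb <- rbm_parameters(matrix(0, 3, 2), qlogis(pm), c(0, 0))
  batch2 <- withr::with_seed(82, {
    matrix(rbinom(300 * 3, 1, rep(pm, each = 300)), 300, 3)
  })
  batch2 <- batch2[, ] # means close to pm but not exact; use empirical mean
  pb$b <- qlogis(colMeans(batch2))
  dbs <- withr::with_seed(83, {
    t(replicate(200, rbm_cd_gradient(batch2, pb, k = 1)$db))
  })
  se <- apply(dbs, 2, sd) / sqrt(nrow(dbs))
  expect_true(all(abs(colMeans(dbs)) < 3 * pmax(se, 1e-12)))

  expect_error(rbm_cd_gradient(matrix(nrow = 0, ncol = 3), p), "non-empty")
})

test_that("averaged CD-1 points uphill: positive cosine with the exact gradient", {
  withr::with_seed(91, {
    p <- random_rbm(4, 3, scale = 0.6)
    data <- matrix(rbinom(100 * 4, 1, 0.35), 100, 4)
  })
  exact <- rbm_exact_gradient(data, p)
  avg <- withr::with_seed(92, {
    acc <- list(dW = 0 * exact$dW, db = 0 * exact$db, dc = 0 * exact$dc)
    n_rep <- 300
    for (i in seq_len(n_rep)) {
      g <- rbm_cd_gradient(data, p, k = 1)
      acc$dW <- acc$dW + g$dW / n_rep
      acc$db <- acc$db + g$db / n_rep
      acc$dc <- acc$dc + g$dc / n_rep
    }
    acc
  })
  flat_e <- c(exact$dW, exact$db, exact$dc)
  flat_a <- c(avg$dW, avg$db, avg$dc)
  cosine <- sum(flat_e * flat_a) / sqrt(sum(flat_e^2) * sum(flat_a^2))
  expect_gt(cosine, 0)
})

test_that("training is reproducible, null at lr 0, and raises exact likelihood", {
  withr::with_seed(101, {
    truth <- random_rbm(6, 3, scale = 1.2)
  })
  data <- withr::with_seed(102, sample_visible_exact(truth, 500))

  f1 <- rbm_train(data, n_hidden = 3, epochs = 40, seed = 9)
  f2 <- rbm_train(data, n_hidden = 3, epochs = 40, seed = 9)
  expect_identical(f1$params, f2$params)

  f0 <- rbm_train(data, n_hidden = 3, epochs = 5, learning_rate = 0, seed = 9)
  init <- rbm_train(data, n_hidden = 3, epochs = 1, learning_rate = 0, seed = 9)
  expect_identical(f0$params, init$params)

  expect_gt(rbm_log_likelihood(data, f1), rbm_log_likelihood(data, init))

  expect_error(rbm_train(matrix(nrow = 0, ncol = 3)), "at least one")
  expect_error(rbm_train(matrix(c(0, 2), 1, 2)), "0/1")
})

test_that("models round-trip through the JSON serialization exactly", {
  withr::with_seed(111, p <- random_rbm(5, 4))
  fit <- structure(list(params = p,
                        config = list(n_hidden = 4, k = 1, learning_rate = 0.05,
                                      epochs = 10, batch_size = 8, seed = 3,
                                      init_scale = 0.01)),
                   class = "rbm")
  path <- withr::local_tempfile(fileext = ".json")
  write_rbm(fit, path)
  back <- read_rbm(path)
  expect_identical(back$params$W, p$W)
  expect_identical(back$params$b, p$b)
  expect_identical(back$params$c, p$c)
  expect_equal(back$config$seed, 3)

  write_rbm(p, path) # bare parameters round-trip too
  expect_identical(read_rbm(path)$W, p$W)
})
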