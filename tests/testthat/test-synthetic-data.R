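test_that("cohort configuration validates its ranges and rule references", {
  cfg <- synthetic_cohort_config()
  expect_equal(cfg$n_features, 25)
  expect_equal(cfg$n_rows, 1200)
  expect_equal(cfg$shift, 2)

  expect_error(synthetic_cohort_config(label_noise = 0.6))
  expect_error(synthetic_cohort_config(n_features = 3, label_rule = "linear",
                                       rule_params = list(features = 1:5,
                                                          weights = rep(1, 5))),
               "only 3")
  expect_error(synthetic_cohort_config(label_rule = "xor_pair",
                                       rule_params = list(features = 1:3)),
               "exactly two")
  expect_error(apply_label_rule(c(1, 0), "nope", list()), "unknown")
})

test_that("label rules follow their truth tables", {
  xp <- list(features = c(1, 2))
  expect_identical(apply_label_rule(c(1, 0), "xor_pair", xp), 1L)
  expect_identical(apply_label_rule(c(0, 1), "xor_pair", xp), 1L)
  expect_identical(apply_label_rule(c(1, 1), "xor_pair", xp), 0L)
  expect_identical(apply_label_rule(c(0, 0), "xor_pair", xp), 0L)

  z <- rbind(c(1, 1, 0, 0), c(1, 1, 1, 0), c(0, 0, 0, 0))
  expect_identical(apply_label_rule(z, "count_threshold", list(threshold = 0)),
                   c(1L, 1L, 1L))
  expect_identical(apply_label_rule(z, "count_threshold", list(threshold = 3)),
                   c(0L, 1L, 0L))
  lin <- list(features = 1:4, weights = c(1, 1, 1, 1), cut = 1.5)
  expect_identical(apply_label_rule(z, "linear", lin), c(1L, 1L, 0L))
  zero_w <- list(features = 1:4, weights = rep(0, 4), cut = 0.5)
  expect_identical(apply_label_rule(z, "linear", zero_w), c(0L, 0L, 0L))
})

test_that("patients are bit-identical under the same seed and differ across seeds", {
  cfg <- synthetic_cohort_config(n_rows = 80, n_features = 6, seed = 5)
  p1 <- generate_patient(cfg)
  p2 <- generate_patient(cfg)
  expect_identical(p1$data, p2$data)
  expect_identical(p1$truth$z, p2$truth$z)
  p3 <- generate_patient(cfg, patient_seed = 6)
  expect_false(identical(p1$data, p3$data))

  cohort <- generate_cohort(synthetic_cohort_config(n_patients = 3, n_rows = 20,
                                                    n_features = 4, seed = 9))
  expect_length(cohort, 3)
  expect_false(identical(cohort[[1]]$data, cohort[[2]]$data))
})

test_that("generated tables carry the documented layout and missingness", {
  cfg <- synthetic_cohort_config(n_rows = 300, n_features = 8,
                                 missing_rate = 0.1, seed = 13)
  pat <- generate_patient(cfg)
  expect_named(pat$data, c("timestamp", sprintf("item_%02d", 1:8), "pain"))
  expect_equal(dim(pat$truth$z), c(300, 8))
  miss <- mean(is.na(as.matrix(pat$data[sprintf("item_%02d", 1:8)])))
  expect_lt(abs(miss - 0.1), 3 * sqrt(0.1 * 0.9 / (300 * 8)))
  expect_true(all(pat$data$pain %in% 0:1))
})

test_that("labels follow the rule up to the configured flip noise", {
  cfg <- synthetic_cohort_config(n_rows = 2000, n_features = 5,
                                 label_rule = "count_threshold",
                                 rule_params = list(threshold = 1),
                                 label_noise = 0.1, missing_rate = 0, seed = 23)
  pat <- generate_patient(cfg)
  flip_rate <- mean(pat$data$pain != pat$truth$clean_labels)
  expect_lt(abs(flip_rate - 0.1), 3 * sqrt(0.1 * 0.9 / 2000))
  expect_identical(pat$truth$clean_labels,
                   apply_label_rule(pat$truth$z, "count_threshold",
                                    list(threshold = 1)))
})

test_that("an all-in-regime patient binarizes to the coverage rate", {
  cfg <- synthetic_cohort_config(n_rows = 1500, n_features = 4,
                                 abnormality_rate = 0, label_rule = "linear",
                                 label_noise = 0, missing_rate = 0, seed = 29)
  pat <- generate_patient(cfg)
  norm <- fit_normalizer(pat$data, features = sprintf("item_%02d", 1:4))
  xb <- as.matrix(binarize(pat$data, norm))
  # threshold 0.5 flags ~half of in-distribution draws as abnormal
  expect_lt(abs(mean(xb) - 0.5), 3 * sqrt(0.25 / length(xb)))
  # linear rule on the all-zero abnormality matrix is constantly 0
  expect_true(all(pat$truth$clean_labels == 0))
})

test_that("binarization recovers abnormal cells against the generating baseline", {
  cfg <- synthetic_cohort_config(n_rows = 1200, n_features = 10, shift = 2,
                                 missing_rate = 0, seed = 37)
  pat <- generate_patient(cfg)
  raw <- as.matrix(pat$data[sprintf("item_%02d", 1:10)])
  p <- abnormality_probability(
    raw,
    mu = matrix(pat$truth$mu, nrow(raw), 10, byrow = TRUE),
    sigma = matrix(pat$truth$sigma, nrow(raw), 10, byrow = TRUE)
  )
  xhat <- (p > 0.5) * 1
  recovery <- mean(xhat[pat$truth$z == 1])
  expect_gt(recovery, 0.9) # theory: 2 - Phi(z0 - 2) - Phi(z0 + 2) ~ 0.911
})

test_that("patient files round-trip through the CSV dialect", {
  cfg <- synthetic_cohort_config(n_rows = 60, n_features = 3,
                                 missing_rate = 0.1, seed = 43)
  pat <- generate_patient(cfg)
  dir <- withr::local_tempdir()
  paths <- write_patient(pat, dir)
  expect_true(all(file.exists(paths)))
  back <- read_flowsheet(paths[["data"]])
  expect_equal(dim(back), dim(pat$data))
  expect_equal(back$pain, pat$data$pain)
  expect_equal(as.matrix(back[2:4]), as.matrix(pat$data[2:4]))
  z <- readr::read_csv(paths[["truth_z"]], show_col_types = FALSE)
  expect_equal(as.matrix(z), pat$truth$z, ignore_attr = TRUE)
  meta <- jsonlite::read_json(paths[["truth_meta"]], simplifyVector = TRUE)
  expect_equal(meta$mu, pat$truth$mu)
})
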