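test_that("cohens_d is mean over n-1 sample SD, with contract errors", {
  expect_equal(cohens_d(c(1, -1)), 0)
  expect_equal(cohens_d(c(1, 2, 0)), 1) # mean 1, SD 1
  set.seed(4)
  x <- rnorm(200, 0.5, 1)
  expect_equal(cohens_d(x), mean(x) / sd(x)) # independent arithmetic
  expect_lt(abs(cohens_d(x) - 0.5), 3 * sqrt(1 / 200 + 0.25 / 400))
  expect_error(cohens_d(c(2, 2, 2)), "zero sample SD")
  expect_error(cohens_d(1), "at least 2")
})

test_that("combined_d reduces to single-measure d, is scale invariant, and matches a row-sum oracle", {
  sim <- generate_study(fer02_preset(n = 40, seed = 6))
  X <- scale_by_dataset_sd(sim$table)
  for (j in seq_len(4)) {
    onehot <- replace(rep(0, 4), j, 1)
    expect_equal(combined_d(X, weight_vector(onehot, measure_kinds())),
                 cohens_d(X$values[, j]))
  }
  w <- c(0.3, -0.5, 1.2, 0.1)
  expect_equal(combined_d(X$values, w), combined_d(X$values, 7 * w))

  set.seed(2)
  M <- matrix(sample(-5:9, 15, replace = TRUE), 5, 3)
  rs <- rowSums(M)
  expect_equal(combined_d(M, c(1, 1, 1)), mean(rs) / sd(rs))
  expect_error(combined_d(M, c(0, 0, 0)), "all-zero")
})

test_that("optimal weights have the closed form Sigma^-1 m with unit norm and w'm >= 0", {
  # exact identity sample covariance, mean (3, 4) -> w* = (0.6, 0.8)
  X <- with_exact_moments(50, m = c(3, 4), S = diag(2), seed = 1)
  colnames(X) <- c("SCR", "PSR")
  w <- optimal_weights(X)
  expect_equal(unname(w$w), c(0.6, 0.8), tolerance = 1e-10)
  expect_equal(sum(w$w^2), 1, tolerance = 1e-10)

  # diagonal covariance: w_j proportional to m_j / sigma_j^2
  m <- c(0.5, 0.4, 0.3)
  v <- c(2, 0.5, 1)
  Xd <- with_exact_moments(60, m = m, S = diag(v), seed = 2)
  colnames(Xd) <- c("SCR", "PSR", "RAR")
  wd <- optimal_weights(Xd)$w
  expected <- (m / v) / sqrt(sum((m / v)^2))
  expect_equal(unname(wd), expected, tolerance = 1e-8)

  expect_error(optimal_weights(matrix(rnorm(6), 2, 3)), "more participants")
})

test_that("no direction beats the closed-form optimum (random + refined grid oracle)", {
  set.seed(10)
  for (rep in 1:20) {
    p <- sample(2:4, 1)
    vals <- matrix(rnorm(30 * p, mean = 0.3), 30, p)
    colnames(vals) <- measure_kinds()[seq_len(p)]
    d_opt <- combined_d(vals, optimal_weights(vals)$w)
    oracle <- sphere_search_max(vals, n_random = 2000, seed = rep)
    expect_gte(d_opt, oracle$random - 1e-8)
    expect_gte(d_opt, oracle$grid - 1e-8)
    expect_lt(abs(d_opt - max(oracle$grid, oracle$random)), 1e-3)
  }
})

test_that("singular covariance falls back to the pseudo-inverse; redundancy adds no d", {
  sim <- generate_study(fer02_preset(n = 50, seed = 13))
  X2 <- scale_by_dataset_sd(sim$table, c("SCR", "PSR"))
  dup <- cbind(X2$values, X2$values[, 2]) # duplicate PSR column
  colnames(dup) <- c("SCR", "PSR", "RAR")
  expect_warning(w3 <- optimal_weights(dup), "pseudo-inverse")
  d3 <- combined_d(dup, w3$w)
  d2 <- combined_d(X2$values, optimal_weights(X2)$w)
  expect_equal(d3, d2, tolerance = 1e-8)
})

test_that("in-sample report is internally consistent with nonnegative gain", {
  sim <- generate_study(fer02_preset(n = 68, seed = 17))
  X <- scale_by_dataset_sd(sim$table)
  rep <- in_sample_report(X)
  expect_equal(rep$best_d, max(rep$d))
  expect_equal(rep$gain, rep$combined_d - rep$best_d)
  expect_gte(rep$gain, -1e-8)
  expect_equal(rep$n, nrow(X$values))

  # nesting monotonicity on the same participants
  d_sub <- combined_d(X$values[, 1:2],
                      optimal_weights(X$values[, 1:2])$w)
  expect_gte(rep$combined_d, d_sub - 1e-10)
})

test_that("optimal combination is equivariant under positive column rescaling", {
  sim <- generate_study(fer02_preset(n = 60, seed = 19))
  X <- scale_by_dataset_sd(sim$table)
  w0 <- optimal_weights(X)$w
  d0 <- combined_d(X$values, w0)
  vals2 <- X$values
  vals2[, 2] <- vals2[, 2] * 3.7
  w2 <- optimal_weights(vals2)$w
  expect_equal(combined_d(vals2, w2), d0, tolerance = 1e-10)
  # the rescaled component shrinks by the reciprocal (up to renormalization)
  ratio <- (w2 / w0) / (w2[1] / w0[1])
  expect_equal(unname(ratio[2]), 1 / 3.7, tolerance = 1e-8)
})

test_that("per-dataset reports mirror the single-dataset analysis", {
  sim <- generate_study(fer02_preset(n = 68, seed = 23))
  reps <- per_dataset_report(sim$table)
  expect_named(reps, "FER02")
  direct <- in_sample_report(scale_by_dataset_sd(sim$table))
  expect_equal(reps$FER02$combined_d, direct$combined_d)

  tab9 <- generate_study(table1_preset(seed = 3))$table
  reps9 <- suppressWarnings(per_dataset_report(tab9))
  expect_true(all(vapply(reps9, `[[`, 0, "gain") >= -1e-8))
  # each dataset analyzed on its own available measures
  expect_setequal(names(reps9$VC7B$d), c("SCR", "PSR"))
})
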