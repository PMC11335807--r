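test_that("minres recovers loadings exactly from a noiseless one-factor correlation", {
  lambda <- c(0.7, 0.55, 0.4, 0.25)
  R <- tcrossprod(lambda) + diag(1 - lambda^2)
  X <- with_exact_moments(100, m = rep(0, 4), S = R, seed = 3)
  colnames(X) <- measure_kinds()
  fit <- fit_factors(X, k = 1)
  expect_equal(unname(fit$loadings[, 1]), lambda, tolerance = 1e-4)
  expect_equal(unname(fit$uniquenesses), 1 - lambda^2, tolerance = 1e-3)
  # communality + uniqueness = 1 by construction on the correlation scale
  expect_equal(unname(rowSums(fit$loadings^2) + fit$uniquenesses),
               rep(1, 4), tolerance = 1e-6)
})

test_that("one-factor synthetic data yields loadings near the generating pattern", {
  sim <- generate_study(fer02_preset(n = 2000, seed = 31))
  X <- scale_by_dataset_sd(sim$table)
  fit <- fit_factors(X, k = 1)
  l <- fit$loadings[, 1]
  gen <- c(SCR = 0.61, PSR = 0.67, RAR = 0.07, HPR = 0.34)
  expect_true(all(abs(l[names(gen)] - gen) < 0.1))
  expect_true(l["PSR"] > l["SCR"] && l["SCR"] > l["HPR"] && l["HPR"] > l["RAR"])
})

test_that("degenerate and null inputs behave as expected", {
  # almost rank-1 data: first-factor communalities near 1
  set.seed(5)
  f <- rnorm(300)
  X1 <- outer(f, c(1, 0.9, 0.8)) + matrix(rnorm(900, sd = 0.01), 300)
  colnames(X1) <- c("SCR", "PSR", "RAR")
  fit1 <- suppressWarnings(fit_factors(X1, 1))
  expect_true(all(1 - fit1$uniquenesses > 0.99))

  # independent columns: the fitted factor implies near-zero common
  # correlations at n = 2000 (least-squares extraction can park all
  # communality on a single variable under independence, so the implied
  # correlations, not the raw loadings, are the meaningful null check)
  set.seed(6)
  X0 <- matrix(rnorm(8000), 2000, 4)
  colnames(X0) <- measure_kinds()
  fit0 <- suppressWarnings(fit_factors(X0, 1))
  implied <- tcrossprod(fit0$loadings)
  expect_lt(max(abs(implied[upper.tri(implied)])), 0.12)

  expect_error(fit_factors(X0, 0), "k must be")
  expect_error(fit_factors(X0, 4), "k must be")
  expect_error(fit_factors(X0[, 1:2], 1), "at least 3 measures")
})

test_that("parallel analysis retains the generating factor count at fixed seeds", {
  sim <- generate_study(fer02_preset(n = 200, seed = 37))
  X <- scale_by_dataset_sd(sim$table)
  pa <- parallel_analysis(X, n_sim = 300, seed = 1)
  expect_equal(pa$retained, 1L)
  expect_true(all(pa$empirical_p > 0 & pa$empirical_p <= 1))
  # retained = leading run of p <= alpha
  expect_equal(pa$retained,
               match(FALSE, pa$empirical_p <= pa$alpha, nomatch = 5L) - 1L)

  set.seed(8)
  noise <- matrix(rnorm(800), 200, 4)
  colnames(noise) <- measure_kinds()
  pa0 <- parallel_analysis(noise, n_sim = 300, seed = 2)
  expect_equal(pa0$retained, 0L)

  # two orthogonal strong factors (sympathetic vs parasympathetic split)
  mk <- measure_kinds()
  cfg2 <- synthetic_config(
    n_factors = 2,
    loadings = matrix(c(0.8, 0.75, 0, 0,
                        0, 0, 0.75, 0.8), 2, 4, byrow = TRUE,
                      dimnames = list(NULL, mk)),
    measure_means = setNames(c(0.4, 0.5, 0.3, 0.3), mk),
    noise_sd = setNames(sqrt(1 - c(0.8, 0.75, 0.75, 0.8)^2), mk),
    dataset_specs = list(list(dataset_id = "TWO", n = 500, measures = mk)),
    seed = 9)
  X2 <- scale_by_dataset_sd(generate_study(cfg2)$table)
  pa2 <- parallel_analysis(X2, n_sim = 300, seed = 3)
  expect_equal(pa2$retained, 2L)
})

test_that("empirical p-values are invariant to column rescaling and seeds reproduce", {
  sim <- generate_study(fer02_preset(n = 150, seed = 41))
  X <- scale_by_dataset_sd(sim$table)
  pa_a <- parallel_analysis(X, n_sim = 200, seed = 7)
  pa_b <- parallel_analysis(X, n_sim = 200, seed = 7)
  expect_identical(pa_a$empirical_p, pa_b$empirical_p)

  rescaled <- sweep(X$values, 2, c(10, 0.1, 3, 42), `*`)
  pa_c <- parallel_analysis(rescaled, n_sim = 200, seed = 7)
  expect_equal(pa_c$empirical_p, pa_a$empirical_p)

  expect_error(parallel_analysis(X, n_sim = 50), "at least 100")
  const <- X$values; const[, 2] <- 1
  expect_error(parallel_analysis(const, n_sim = 200), "constant column")
})
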