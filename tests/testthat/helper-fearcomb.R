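# shared fixtures and independent oracles used across test files

# a small two-dataset table built in code (SCR+PSR everywhere, HPR in one
# dataset only)
make_toy_table <- function() {
  study_table(data.frame(
    dataset_id = c("A", "A", "A", "B", "B", "B", "B"),
    participant_id = c("a1", "a2", "a3", "b1", "b2", "b3", "b4"),
    SCR = c(0.5, 0.9, 0.2, 1.1, 0.7, 0.4, 0.8),
    PSR = c(0.3, 0.6, 0.1, 0.9, 0.5, 0.2, 0.7),
    RAR = NA_real_,
    HPR = c(NA, NA, NA, 12, 30, -5, 21),
    stringsAsFactors = FALSE))
}

# transform rows so the sample mean and covariance are EXACTLY the targets
# (whiten empirically, then recolor); lets closed-form weight examples be
# checked to numerical precision
with_exact_moments <- function(n, m, S, seed = 1) {
  set.seed(seed)
  p <- length(m)
  X <- matrix(rnorm(n * p), n, p)
  X <- scale(X, center = TRUE, scale = FALSE)
  W <- chol(cov(X))
  X0 <- X %*% solve(W)            # exact identity sample covariance
  Y <- X0 %*% chol(S)
  sweep(Y, 2, m, `+`)
}

# direct-arithmetic effect size of direction w (oracle for combined_d):
# spec formula w'm / sqrt(w' Sigma w) computed from first principles
dir_d <- function(vals, w) {
  m <- colMeans(vals)
  S <- cov(vals)
  sum(w * m) / sqrt(drop(crossprod(w, S %*% w)))
}

# brute-force search of the best direction on the unit sphere: coarse
# hyperspherical-angle grid refined twice around the argmax, plus random
# directions; independent of optimal_weights()
sphere_search_max <- function(vals, n_random = 1e4, seed = 1) {
  set.seed(seed)
  p <- ncol(vals)
  m <- colMeans(vals)
  S <- cov(vals)
  eval_dirs <- function(W) { # W: p x ndir unit columns
    num <- drop(crossprod(W, m))
    den <- sqrt(colSums(W * (S %*% W)))
    max(num / den)
  }
  angles_to_dir <- function(A) { # A: ndir x (p-1) angle matrix
    W <- matrix(1, nrow(A), p)
    for (j in seq_len(p - 1)) {
      W[, j] <- W[, j] * cos(A[, j])
      for (jj in (j + 1):p) W[, jj] <- W[, jj] * sin(A[, j])
    }
    t(W)
  }
  grid_max <- function(centers, half, steps) {
    axes <- lapply(seq_len(p - 1), function(j)
      seq(centers[j] - half, centers[j] + half, length.out = steps))
    A <- as.matrix(expand.grid(axes))
    W <- angles_to_dir(A)
    vals_d <- drop(crossprod(W, m)) / sqrt(colSums(W * (S %*% W)))
    list(best = max(vals_d), at = A[which.max(vals_d), , drop = TRUE])
  }
  steps <- c(721, 181, 41)[p - 1] # coarse resolution by dimension
  g <- grid_max(rep(pi / 2, p - 1), pi, steps)
  for (r in 1:3) { # successive local refinement
    half <- pi / (steps - 1) * 2 / (8^(r - 1))
    g2 <- grid_max(g$at, half, 17)
    if (g2$best > g$best) g <- g2
  }
  Wr <- matrix(rnorm(p * n_random), p)
  Wr <- sweep(Wr, 2, sqrt(colSums(Wr^2)), `/`)
  rand_best <- eval_dirs(Wr)
  list(grid = g$best, random = rand_best)
}
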