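# squared multiple correlations: communality estimates for the reduced
# correlation matrix (pseudo-inverse fallback for singular R)
smc_communalities <- function(R) {
  Ri <- tryCatch(solve(R), error = function(e) MASS::ginv(R))
  pmin(pmax(1 - 1 / diag(Ri), 0), 1)
}

# eigenvalues used for factor retention: "reduced" puts SMC communality
# estimates on the diagonal (common-factor variant); "pca" uses the plain
# correlation matrix
retention_eigenvalues <- function(R, eigen_type = c("reduced", "pca")) {
  eigen_type <- match.arg(eigen_type)
  if (eigen_type == "reduced") diag(R) <- smc_communalities(R)
  eigen(R, symmetric = TRUE, only.values = TRUE)$values
}

#' Unrotated minimum-residual exploratory factor analysis
#'
#' Extracts `k` common factors from the correlation matrix of the columns
#' of `X` by minimum residual (unweighted least squares on the off-diagonal
#' correlations): uniquenesses are optimized so that the best rank-`k`
#' approximation of the reduced correlation matrix reproduces the observed
#' off-diagonal correlations as closely as possible in least squares.
#' Loadings are left unrotated and signed so each factor's loading sum is
#' nonnegative. The solution is deterministic given `X`.
#'
#' @param X A `scaled_matrix` (see [scale_by_dataset_sd()]) or numeric
#'   matrix (participants x measures, complete cases).
#' @param k Number of factors, `1 <= k <= p - 1`.
#' @return Object of class `factor_solution`: `loadings` (p x k, rownames
#'   are measures), `uniquenesses` (`1 -` communality, clamped at 0 with a
#'   warning in Heywood cases), `method = "minres"`, `converged`,
#'   `objective` (residual sum of squares).
#' @export
#' @examples
#' sim <- generate_study(fer02_preset(n = 300, seed = 5))
#' fit_factors(scale_by_dataset_sd(sim$table), k = 1)
fit_factors <- function(X, k = 1) {
  vals <- as_values_matrix(X)
  p <- ncol(vals)
  if (nrow(vals) <= p) stop("need more participants than measures")
  if (p < 3) stop("factor analysis needs at least 3 measures")
  if (k < 1 || k > p - 1) stop("k must be in 1..(p-1)")
  R <- stats::cor(vals)
  if (anyNA(R)) stop("constant column: correlation undefined")
  off <- upper.tri(R)
  lead_loadings <- function(psi) {
    e <- eigen(R - diag(psi, p), symmetric = TRUE)
    ev <- pmax(e$values[seq_len(k)], 0)
    e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k)
  }
  obj <- function(psi) {
    res <- R - tcrossprod(lead_loadings(psi))
    sum(res[off]^2)
  }
  start <- pmin(pmax(1 - smc_communalities(R), 0.01), 0.99)
  opt <- stats::nlminb(start, obj, lower = 1e-3, upper = 1,
                       control = list(iter.max = 500, eval.max = 1000))
  if (opt$convergence != 0) {
    # PORT occasionally reports false convergence on near-flat objectives
    # (e.g. independence); fall back to a bounded quasi-Newton pass
    opt2 <- stats::optim(start, obj, method = "L-BFGS-B",
                         lower = 1e-3, upper = 1,
                         control = list(factr = 1e7, maxit = 1000))
    if (opt2$convergence %in% c(0L, 52L) && opt2$value <= obj(start)) {
      opt <- list(par = opt2$par, objective = opt2$value)
    } else {
      stop("minres extraction did not converge: ", opt$message)
    }
  }
  L <- lead_loadings(opt$par)
  flip <- ifelse(colSums(L) < 0, -1, 1)
  L <- sweep(L, 2, flip, `*`)
  measures <- if (inherits(X, "scaled_matrix")) X$measures else colnames(vals)
  dimnames(L) <- list(measures, paste0("F", seq_len(k)))
  u <- 1 - rowSums(L^2)
  if (any(u < -1e-6)) {
    warning("Heywood case: uniqueness below 0 clamped for ",
            paste(measures[u < -1e-6], collapse = ", "))
  }
  u <- pmax(u, 0)
  structure(list(loadings = L, uniquenesses = stats::setNames(u, measures),
                 method = "minres", converged = TRUE,
                 objective = opt$objective),
            class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat("minres factor solution (", ncol(x$loadings), "factor(s) )\n")
  print(round(cbind(x$loadings, uniqueness = x$uniquenesses), 3))
  invisible(x)
}

#' Monte-Carlo parallel analysis with empirical p-values
#'
#' Decides how many factors underlie the between-person covariance of the
#' measures by comparing the observed eigenvalues against their null
#' distribution in randomized data. The default follows the common-factor
#' (reduced correlation matrix) variant: eigenvalues are taken from the
#' correlation matrix with squared-multiple-correlation communality
#' estimates on the diagonal. The null distribution comes from `n_sim`
#' randomizations of the data (independent column-wise permutations by
#' default, which destroys between-measure association while preserving
#' each measure's margins; a Gaussian null is available). Each component's
#' empirical p-value is `(1 + #(null >= observed)) / (n_sim + 1)`, and
#' components are retained while `p <= alpha`, stopping at the first
#' failure.
#'
#' @param X A `scaled_matrix` or numeric matrix (complete cases, `n > p`).
#' @param n_sim Number of Monte-Carlo randomizations (>= 100; 5000 for
#'   production use).
#' @param alpha Retention level.
#' @param seed Optional seed making the null draw reproducible.
#' @param eigen_type `"reduced"` (common-factor, default) or `"pca"`.
#' @param null_method `"permutation"` (default) or `"gaussian"`.
#' @return Object of class `pa_result`: `observed_eigenvalues`,
#'   `null_eigenvalue_samples` (`n_sim` x p), `empirical_p`, `retained`,
#'   `n_sim`, `alpha`, plus the options used.
#' @export
#' @examples
#' sim <- generate_study(fer02_preset(n = 200, seed = 3))
#' parallel_analysis(scale_by_dataset_sd(sim$table), n_sim = 200, seed = 1)
parallel_analysis <- function(X, n_sim = 5000, alpha = 0.05, seed = NULL,
                              eigen_type = c("reduced", "pca"),
                              null_method = c("permutation", "gaussian")) {
  vals <- as_values_matrix(X)
  eigen_type <- match.arg(eigen_type)
  null_method <- match.arg(null_method)
  n <- nrow(vals); p <- ncol(vals)
  if (n <= p) stop("need more participants than measures")
  if (n_sim < 100) stop("n_sim must be at least 100")
  if (any(apply(vals, 2, stats::sd) == 0)) stop("constant column")
  R <- stats::cor(vals)
  obs <- retention_eigenvalues(R, eigen_type)
  if (!is.null(seed)) set.seed(seed)
  null_eig <- matrix(NA_real_, n_sim, p)
  perm <- vals
  for (s in seq_len(n_sim)) {
    if (null_method == "permutation") {
      for (j in seq_len(p)) perm[, j] <- vals[sample.int(n), j]
    } else {
      perm <- matrix(stats::rnorm(n * p), n, p)
    }
    null_eig[s, ] <- retention_eigenvalues(stats::cor(perm), eigen_type)
  }
  emp_p <- vapply(seq_len(p), function(j) {
    (1 + sum(null_eig[, j] >= obs[j])) / (n_sim + 1)
  }, 0)
  retained <- 0L
  for (j in seq_len(p)) {
    if (emp_p[j] <= alpha) retained <- retained + 1L else break
  }
  structure(list(observed_eigenvalues = obs,
                 null_eigenvalue_samples = null_eig,
                 empirical_p = emp_p, retained = retained,
                 n_sim = n_sim, alpha = alpha, eigen_type = eigen_type,
                 null_method = null_method, n = n),
            class = "pa_result")
}

#' @export
print.pa_result <- function(x, ...) {
  cat("parallel analysis (", x$eigen_type, "eigenvalues,", x$null_method,
      "null,", x$n_sim, "simulations )\n")
  print(data.frame(component = seq_along(x$observed_eigenvalues),
                   eigenvalue = round(x$observed_eigenvalues, 3),
                   null_mean = round(colMeans(x$null_eigenvalue_samples), 3),
                   p = round(x$empirical_p, 4)), row.names = FALSE)
  cat("retained factors:", x$retained, "(alpha =", x$alpha, ")\n")
  invisible(x)
}
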