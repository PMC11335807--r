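#' One-sample Cohen's d
#'
#' Effect size of a vector of difference scores against zero:
#' `mean(x) / sd(x)` with the sample SD (denominator n-1). This is the
#' retrodictive-validity metric used throughout the package: how well a
#' measure separates CS+ from CS- across participants.
#'
#' @param x Numeric vector, length >= 2, with nonzero sample SD.
#' @return Scalar effect size.
#' @export
#' @examples
#' cohens_d(c(1, 1 + 1, 1 - 1)) # mean 1, SD 1 -> d = 1
cohens_d <- function(x) {
  if (length(x) < 2) stop("need at least 2 observations")
  if (anyNA(x)) stop("missing values in x")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero sample SD")
  mean(x) / s
}

#' Weight vector for a linear combination of measures
#'
#' @param w Numeric weights.
#' @param measures Measure subset the weights refer to, same length as `w`.
#' @param normalize Rescale to unit 2-norm; the sign is left untouched here
#'   (see [optimal_weights()] for the `w'm >= 0` convention).
#' @return Object of class `weight_vector` with fields `measures`, `w`,
#'   `normalized`.
#' @export
weight_vector <- function(w, measures, normalize = TRUE) {
  measures <- check_measures(measures)
  stopifnot(length(w) == length(measures), is.numeric(w))
  if (all(w == 0)) stop("all-zero weight vector")
  if (normalize) w <- w / sqrt(sum(w^2))
  structure(list(measures = measures, w = stats::setNames(w, measures),
                 normalized = normalize),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("weight_vector", if (x$normalized) "(unit 2-norm)" else "", "\n")
  print(round(x$w, 4))
  invisible(x)
}

# internal: plain-matrix moment computation shared by the hot paths
.moments <- function(vals) {
  list(m = colMeans(vals), S = stats::cov(vals))
}

#' Cohen's d of a linear combination of measures
#'
#' For weights `w`, the combined score of participant `i` is `w'x_i`; its
#' effect size is `w'm / sqrt(w' Sigma w)` with `m` and `Sigma` the sample
#' mean vector and (n-1)-denominator covariance of the rows. The value is
#' invariant to rescaling of `w`.
#'
#' @param X A `scaled_matrix` (see [scale_by_dataset_sd()]) or numeric
#'   matrix whose columns match `w$measures`.
#' @param w A [weight_vector()] or bare numeric vector.
#' @return Scalar effect size.
#' @export
#' @examples
#' sim <- generate_study(fer02_preset(n = 60, seed = 1))
#' X <- scale_by_dataset_sd(sim$table)
#' combined_d(X, weight_vector(c(1, 1, 1, 1), measure_kinds()))
combined_d <- function(X, w) {
  vals <- as_values_matrix(X)
  if (inherits(w, "weight_vector")) {
    if (inherits(X, "scaled_matrix") &&
        !identical(w$measures, X$measures)) {
      stop("weight vector measures do not match the matrix measures")
    }
    w <- w$w
  }
  stopifnot(length(w) == ncol(vals))
  if (all(w == 0)) stop("all-zero weight vector")
  mo <- .moments(vals)
  v <- drop(crossprod(w, mo$S %*% w))
  if (v <= 0) stop("combined score has no variance")
  drop(crossprod(w, mo$m)) / sqrt(v)
}

#' Closed-form d-maximizing combination weights
#'
#' The weights maximizing the combined Cohen's d solve the Fisher linear
#' discriminant problem of separating the observed difference scores from
#' the origin: `w*` proportional to `Sigma^-1 m`. The returned vector is
#' normalized to unit 2-norm with sign fixed so that `w'm >= 0`.
#'
#' @param X A `scaled_matrix` or numeric matrix with `n > p`.
#' @return A [weight_vector()].
#' @export
#' @examples
#' # identity covariance: weights proportional to the mean vector
#' set.seed(1)
#' X <- matrix(rnorm(400), 200, 2)
#' X <- sweep(X, 2, c(3, 4), `+`)
#' optimal_weights(X)
optimal_weights <- function(X) {
  vals <- as_values_matrix(X)
  measures <- if (inherits(X, "scaled_matrix")) X$measures else
    colnames(vals)
  if (is.null(measures)) measures <- measure_kinds()[seq_len(ncol(vals))]
  if (nrow(vals) <= ncol(vals)) {
    stop("need more participants than measures (n = ", nrow(vals),
         ", p = ", ncol(vals), ")")
  }
  mo <- .moments(vals)
  w <- tryCatch(solve(mo$S, mo$m), error = function(e) {
    warning("singular covariance; using pseudo-inverse")
    drop(MASS::ginv(mo$S) %*% mo$m)
  })
  if (all(w == 0)) stop("degenerate solution: zero mean vector")
  if (drop(crossprod(w, mo$m)) < 0) w <- -w
  weight_vector(w, measures, normalize = TRUE)
}

# lean unexported fit for cross-validation loops: returns raw weights
.fit_weights <- function(vals) {
  m <- colMeans(vals)
  S <- stats::cov(vals)
  w <- tryCatch(solve(S, m), error = function(e) drop(MASS::ginv(S) %*% m))
  if (drop(crossprod(w, m)) < 0) w <- -w
  w
}

#' In-sample effect report for a measure subset
#'
#' Per-measure effect sizes, the best single measure, the optimal
#' combination weights, the combined effect size and the in-sample gain
#' (combined minus best single), on the complete cases of one scaled
#' matrix.
#'
#' @param X A `scaled_matrix` (see [scale_by_dataset_sd()]) or numeric
#'   matrix with named columns.
#' @return Object of class `effect_report`: list with `measures`, `d`
#'   (named per-measure d), `best_measure`, `best_d`, `weights`
#'   ([weight_vector()]), `combined_d`, `gain`, `n`.
#' @export
#' @examples
#' sim <- generate_study(fer02_preset(n = 68, seed = 11))
#' in_sample_report(scale_by_dataset_sd(sim$table))
in_sample_report <- function(X) {
  vals <- as_values_matrix(X)
  measures <- if (inherits(X, "scaled_matrix")) X$measures else
    colnames(vals)
  d <- apply(vals, 2, cohens_d)
  names(d) <- measures
  w <- optimal_weights(X)
  cd <- combined_d(vals, w$w)
  best <- which.max(d)
  structure(list(measures = measures, d = d,
                 best_measure = measures[best], best_d = d[[best]],
                 weights = w, combined_d = cd, gain = cd - d[[best]],
                 n = nrow(vals)),
            class = "effect_report")
}

#' @export
print.effect_report <- function(x, ...) {
  cat("effect_report (n =", x$n, ")\n")
  cat("  per-measure d: ",
      paste(sprintf("%s %.3f", x$measures, x$d), collapse = ", "), "\n")
  cat("  best single:  ", x$best_measure, sprintf("(d = %.3f)", x$best_d), "\n")
  cat("  weights:      ",
      paste(sprintf("%s %.3f", x$weights$measures, x$weights$w),
            collapse = ", "), "\n")
  cat(sprintf("  combined d = %.3f, gain = %+.3f\n", x$combined_d, x$gain))
  invisible(x)
}

#' Per-dataset in-sample effect reports
#'
#' Analyzes each dataset separately on its own available measures (or a
#' requested subset thereof), with within-dataset scaling, mirroring a
#' dataset-by-dataset results table.
#'
#' @param table A [study_table()].
#' @param measures Optional subset restricting the analysis; by default
#'   each dataset uses all measures available in it.
#' @param orient Passed to [scale_by_dataset_sd()].
#' @return Named list of [in_sample_report()] results, one per dataset
#'   retained; datasets with `n <= p` are skipped with a warning.
#' @export
per_dataset_report <- function(table, measures = NULL, orient = TRUE) {
  stopifnot(inherits(table, "study_table"))
  out <- list()
  for (d in rownames(table$availability)) {
    avail <- names(which(table$availability[d, ]))
    use <- if (is.null(measures)) avail else intersect(check_measures(measures), avail)
    if (!length(use)) next
    sub <- study_table(table$data[table$data$dataset_id == d, , drop = FALSE])
    X <- tryCatch(suppressWarnings(scale_by_dataset_sd(sub, use, orient = orient)),
                  error = function(e) NULL)
    if (is.null(X) || nrow(X$values) <= length(use)) {
      warning("dataset ", d, " skipped (n <= p or no complete cases)")
      next
    }
    out[[d]] <- in_sample_report(X)
  }
  out
}
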