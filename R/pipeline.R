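#' Full-pipeline run configuration
#'
#' Bundles every setting of the end-to-end analysis: input data (a
#' [study_table()], a CSV path, or the built-in synthetic preset),
#' screening policy, orientation, the measure subsets to analyze,
#' parallel-analysis / cross-validation / power settings, and the root
#' seed.
#'
#' @param input A [study_table()], a path to a CSV readable by
#'   [read_study_table()], or `NULL` to simulate from `preset`.
#' @param preset Synthetic preset used when `input` is `NULL`; currently
#'   `"table1"` (see [table1_preset()]).
#' @param measure_subsets List of character vectors; default all subsets of
#'   2-4 measures in canonical order.
#' @param screening A [screening_policy()], or `NULL` to skip screening.
#' @param orient Orient measures by their expected effect sign.
#' @param pa List of [parallel_analysis()] settings: `n_sim`, `alpha`,
#'   `eigen_type`, `null_method`.
#' @param cv List of [cv_config()] settings: `k`, `reps`,
#'   `stratify_by_dataset`; plus `level` for the corrected interval.
#' @param power List with `power`, `alpha`, `tails` for [required_n()].
#' @param seed Root seed; every stochastic stage derives its stream from
#'   it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input = NULL, preset = "table1",
                       measure_subsets = NULL,
                       screening = screening_policy(), orient = TRUE,
                       pa = list(), cv = list(), power = list(),
                       seed = 1L) {
  pa_def <- list(n_sim = 5000, alpha = 0.05, eigen_type = "reduced",
                 null_method = "permutation")
  cv_def <- list(k = 5L, reps = 1000L, stratify_by_dataset = TRUE,
                 level = 0.90)
  pw_def <- list(power = 0.80, alpha = 0.05, tails = "two")
  pa <- utils::modifyList(pa_def, pa)
  cv <- utils::modifyList(cv_def, cv)
  power <- utils::modifyList(pw_def, power)
  if (is.null(measure_subsets)) {
    mk <- measure_kinds()
    measure_subsets <- unlist(lapply(2:4, function(sz) {
      utils::combn(mk, sz, simplify = FALSE)
    }), recursive = FALSE)
  } else {
    measure_subsets <- lapply(measure_subsets, check_measures)
  }
  structure(list(input = input, preset = preset,
                 measure_subsets = measure_subsets, screening = screening,
                 orient = orient, pa = pa, cv = cv, power = power,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized top-level blocks: `input` (path), `preset`, `seed`,
#' `subsets` (list of measure vectors), `screening` (`thresholds` map and
#' `exclusions` list of `{dataset, measure}`), `orientation` (map measure
#' -> +1/-1; stored signs are applied via `orient`), `pa`, `cv`, `power`.
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  scr <- screening_policy(
    z_threshold = if (!is.null(y$screening$thresholds))
      unlist(y$screening$thresholds),
    dataset_measure_exclusions = if (!is.null(y$screening$exclusions)) {
      do.call(rbind, lapply(y$screening$exclusions, function(e)
        data.frame(dataset_id = e$dataset, measure = e$measure,
                   stringsAsFactors = FALSE)))
    })
  run_config(input = y$input,
             preset = if (is.null(y$preset)) "table1" else y$preset,
             measure_subsets = y$subsets, screening = scr,
             orient = if (is.null(y$orientation$apply)) TRUE
                      else isTRUE(y$orientation$apply),
             pa = if (is.null(y$pa)) list() else y$pa,
             cv = if (is.null(y$cv)) list() else y$cv,
             power = if (is.null(y$power)) list() else y$power,
             seed = if (is.null(y$seed)) 1L else y$seed)
}

# settings actually in force, recorded in every bundle
.config_log <- function(cfg) {
  list(schema = "fearcomb-report/1",
       seed = cfg$seed, orient = cfg$orient,
       screening = if (is.null(cfg$screening)) NULL else list(
         z_threshold = as.list(cfg$screening$z_threshold),
         level = cfg$screening$level),
       pa = cfg$pa, cv = cfg$cv, power = cfg$power,
       subset_order = vapply(cfg$measure_subsets, paste,
                             "", collapse = "+"))
}

#' Run the full analysis pipeline
#'
#' Ingests or simulates a study table, screens it, then for every
#' configured measure subset: pools the complete cases with dataset-wise
#' scaling, computes the in-sample effect report (per-measure d, optimal
#' weights, combined d, gain), runs parallel analysis (subsets of 3+
#' measures), evaluates the combination out-of-sample with a
#' bias-corrected gain interval, and translates the out-of-sample effect
#' sizes into required sample sizes. A per-dataset report over each
#' dataset's own available measures is produced once. Any stage error
#' aborts only the affected subset and is recorded in the bundle.
#'
#' @param cfg A [run_config()].
#' @return A report bundle: list with `log` (settings in force),
#'   `exclusions`, `per_dataset`, and `subsets` (one entry per measure
#'   subset with `insample`, `pa`, `oos`, `power`, `error`).
#' @export
#' @examples
#' cfg <- run_config(pa = list(n_sim = 100), cv = list(reps = 10),
#'                   measure_subsets = list(c("SCR", "PSR")), seed = 4)
#' bundle <- run_all(cfg)
#' bundle$subsets[["SCR+PSR"]]$insample$gain
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  table <- if (inherits(cfg$input, "study_table")) {
    cfg$input
  } else if (is.character(cfg$input)) {
    read_study_table(cfg$input)
  } else if (identical(cfg$preset, "table1")) {
    generate_study(table1_preset(seed = cfg$seed))$table
  } else {
    stop("unknown preset: ", cfg$preset)
  }
  exclusions <- NULL
  if (!is.null(cfg$screening)) {
    scr <- screen_participants(table, cfg$screening)
    table <- scr$table
    exclusions <- scr$exclusions
  }
  bundle <- list(log = .config_log(cfg), exclusions = exclusions,
                 per_dataset = tryCatch(
                   suppressWarnings(per_dataset_report(table,
                                                       orient = cfg$orient)),
                   error = function(e) conditionMessage(e)),
                 subsets = list())
  for (i in seq_along(cfg$measure_subsets)) {
    ms <- cfg$measure_subsets[[i]]
    key <- paste(ms, collapse = "+")
    entry <- list(measures = ms, insample = NULL, pa = NULL, oos = NULL,
                  power = NULL, error = NULL)
    entry <- tryCatch({
      X <- suppressWarnings(
        scale_by_dataset_sd(table, ms, orient = cfg$orient))
      avail_ok <- nrow(X$values) > length(ms)
      if (!avail_ok) stop("n <= p after complete-case subsetting")
      entry$insample <- in_sample_report(X)
      if (length(ms) >= 3) {
        entry$pa <- parallel_analysis(
          X, n_sim = cfg$pa$n_sim, alpha = cfg$pa$alpha,
          seed = derive_seed(cfg$seed, paste0("pa:", key)),
          eigen_type = cfg$pa$eigen_type,
          null_method = cfg$pa$null_method)
      }
      oos_cfg <- cv_config(k = cfg$cv$k, reps = cfg$cv$reps,
                           seed = derive_seed(cfg$seed, paste0("cv:", key)),
                           stratify_by_dataset = cfg$cv$stratify_by_dataset)
      entry$oos <- bias_corrected_ci(X, oos_cfg, level = cfg$cv$level)
      if (entry$oos$mean_best_single_d > 0 &&
          entry$oos$mean_combined_d > 0) {
        n1 <- required_n(entry$oos$mean_best_single_d, cfg$power$power,
                         cfg$power$alpha, cfg$power$tails)
        n2 <- required_n(entry$oos$mean_combined_d, cfg$power$power,
                         cfg$power$alpha, cfg$power$tails)
        entry$power <- list(n_best_single = n1, n_combined = n2,
                            reduction_pct = 100 * (n1 - n2) / n1)
      }
      entry
    }, error = function(e) {
      entry$error <- conditionMessage(e)
      entry
    })
    bundle$subsets[[key]] <- entry
  }
  class(bundle) <- "report_bundle"
  bundle
}

# flatten one subset entry into plain-list report rows
.subset_rows <- function(bundle) {
  lapply(bundle$subsets, function(e) {
    out <- list(measures = e$measures, error = e$error)
    if (!is.null(e$insample)) {
      out$insample <- list(
        d = as.list(signif(e$insample$d, 6)),
        best_measure = e$insample$best_measure,
        best_d = signif(e$insample$best_d, 6),
        weights = as.list(signif(e$insample$weights$w, 6)),
        combined_d = signif(e$insample$combined_d, 6),
        gain = signif(e$insample$gain, 6), n = e$insample$n)
    }
    if (!is.null(e$pa)) {
      out$pa <- list(
        eigenvalues = signif(e$pa$observed_eigenvalues, 6),
        p = signif(e$pa$empirical_p, 6), retained = e$pa$retained,
        n_sim = e$pa$n_sim, alpha = e$pa$alpha, n = e$pa$n)
    }
    if (!is.null(e$oos)) {
      out$oos <- list(
        best_single_d = signif(e$oos$mean_best_single_d, 6),
        combined_d = signif(e$oos$mean_combined_d, 6),
        gain = signif(e$oos$mean_gain, 6),
        gain_corrected = signif(e$oos$bias_corrected_gain, 6),
        ci_lo = signif(e$oos$gain_ci[["lo"]], 6),
        ci_hi = signif(e$oos$gain_ci[["hi"]], 6),
        level = e$oos$level, n = e$oos$n)
    }
    out$power <- e$power
    out
  })
}

#' Write a report bundle to disk
#'
#' Emits a machine-readable JSON twin plus human-readable TSV tables:
#' `dimensionality.tsv` (eigenvalues, empirical p, retained),
#' `per_dataset.tsv` (per-dataset d and in-sample gains),
#' `insample.tsv` (pooled weights, best d, combined d, gain, n) and
#' `oos.tsv` (out-of-sample means, gain, corrected 90% CI). Floats are
#' written at 6 significant digits.
#'
#' @param bundle A bundle from [run_all()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- .subset_rows(bundle)
  json <- list(log = bundle$log,
               exclusions = bundle$exclusions,
               per_dataset = lapply(bundle$per_dataset, function(r) list(
                 d = as.list(signif(r$d, 6)), best_measure = r$best_measure,
                 combined_d = signif(r$combined_d, 6),
                 gain = signif(r$gain, 6), n = r$n)),
               subsets = rows)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  mk <- measure_kinds()
  pick <- function(lst, f, default = NA) {
    vapply(lst, function(e) {
      v <- tryCatch(f(e), error = function(err) NULL)
      if (is.null(v)) default else v
    }, default)
  }
  ins <- data.frame(subset = names(rows),
                    n = pick(rows, function(e) e$insample$n, NA_integer_))
  for (m in mk) {
    ins[[paste0("w_", m)]] <-
      pick(rows, function(e) e$insample$weights[[m]], NA_real_)
  }
  ins$best_d <- pick(rows, function(e) e$insample$best_d, NA_real_)
  ins$combined_d <- pick(rows, function(e) e$insample$combined_d, NA_real_)
  ins$gain <- pick(rows, function(e) e$insample$gain, NA_real_)
  utils::write.table(ins, file.path(dir, "insample.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  pa <- data.frame(subset = names(rows),
                   retained = pick(rows, function(e) e$pa$retained,
                                   NA_integer_),
                   p1 = pick(rows, function(e) e$pa$p[1], NA_real_),
                   p2 = pick(rows, function(e) e$pa$p[2], NA_real_),
                   p3 = pick(rows, function(e) e$pa$p[3], NA_real_),
                   n = pick(rows, function(e) e$pa$n, NA_integer_))
  utils::write.table(pa, file.path(dir, "dimensionality.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  oos <- data.frame(subset = names(rows),
                    best_single_d = pick(rows, function(e) e$oos$best_single_d,
                                         NA_real_),
                    combined_d = pick(rows, function(e) e$oos$combined_d,
                                      NA_real_),
                    gain = pick(rows, function(e) e$oos$gain, NA_real_),
                    ci_lo = pick(rows, function(e) e$oos$ci_lo, NA_real_),
                    ci_hi = pick(rows, function(e) e$oos$ci_hi, NA_real_),
                    n = pick(rows, function(e) e$oos$n, NA_integer_))
  utils::write.table(oos, file.path(dir, "oos.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  pd <- bundle$per_dataset
  if (is.list(pd) && length(pd)) {
    tab3 <- data.frame(dataset = names(pd))
    for (m in mk) {
      tab3[[m]] <- vapply(pd, function(r)
        if (m %in% names(r$d)) signif(r$d[[m]], 6) else NA_real_, 0)
    }
    tab3$best_d <- vapply(pd, function(r) signif(r$best_d, 6), 0)
    tab3$combined_d <- vapply(pd, function(r) signif(r$combined_d, 6), 0)
    tab3$gain <- vapply(pd, function(r) signif(r$gain, 6), 0)
    tab3$n <- vapply(pd, function(r) r$n, 0L)
    utils::write.table(tab3, file.path(dir, "per_dataset.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
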