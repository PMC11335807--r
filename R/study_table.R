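#' Construct a study table of CS+/CS- difference scores
#'
#' A study table holds one row per participant: a dataset label, a
#' participant label, and the CS+ minus CS- response difference for each of
#' the four autonomic measures (`NA` where a measure was not recorded).
#' Per-dataset measure availability is derived from the data: a measure is
#' available in a dataset if it has at least one non-missing value there.
#'
#' @param data A data.frame with columns `dataset_id`, `participant_id` and
#'   one numeric column per measure present (any subset of
#'   [measure_kinds()]); missing measure columns are added as all-`NA`.
#' @return An object of class `study_table`: a list with elements `data`
#'   (the completed data.frame) and `availability` (datasets x measures
#'   logical matrix).
#' @seealso [read_study_table()], [scale_by_dataset_sd()],
#'   [screen_participants()]
#' @export
study_table <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("dataset_id", "participant_id")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  data$dataset_id <- as.character(data$dataset_id)
  data$participant_id <- as.character(data$participant_id)
  for (m in measure_kinds()) {
    if (!m %in% names(data)) data[[m]] <- NA_real_
    if (!is.numeric(data[[m]])) {
      bad <- which(!is.na(data[[m]]) &
                     is.na(suppressWarnings(as.numeric(data[[m]]))))
      if (length(bad)) {
        stop("non-numeric value for ", m, " in row ", bad[1],
             " (dataset ", data$dataset_id[bad[1]],
             ", participant ", data$participant_id[bad[1]], ")")
      }
      data[[m]] <- suppressWarnings(as.numeric(data[[m]]))
    }
  }
  key <- paste(data$dataset_id, data$participant_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicated (dataset_id, participant_id): ",
         gsub("\r", "/", d, fixed = TRUE))
  }
  vals <- as.matrix(data[measure_kinds()])
  if (any(rowSums(!is.na(vals)) == 0)) {
    stop("record with no non-missing measure: row ",
         which(rowSums(!is.na(vals)) == 0)[1])
  }
  data <- data[c(need, measure_kinds())]
  datasets <- unique(data$dataset_id)
  avail <- t(vapply(datasets, function(d) {
    colSums(!is.na(vals[data$dataset_id == d, , drop = FALSE])) > 0
  }, logical(length(measure_kinds()))))
  dimnames(avail) <- list(datasets, measure_kinds())
  structure(list(data = data, availability = avail), class = "study_table")
}

#' @export
print.study_table <- function(x, ...) {
  cat("study_table:", nrow(x$data), "participants in",
      nrow(x$availability), "dataset(s)\n")
  cat("availability (n participants with data):\n")
  tab <- t(vapply(rownames(x$availability), function(d) {
    sub <- x$data[x$data$dataset_id == d, measure_kinds()]
    colSums(!is.na(sub))
  }, integer(length(measure_kinds()))))
  print(tab)
  invisible(x)
}

#' Read a study table from delimited text
#'
#' Expects a header `dataset_id,participant_id,SCR,PSR,RAR,HPR` (measure
#' columns optional, any order); empty fields encode missing values.
#'
#' @param path Path to a CSV (or TSV) file.
#' @param sep Field separator, `","` by default.
#' @return A [study_table()].
#' @export
#' @examples
#' path <- system.file("extdata", "synthetic_example.csv",
#'                     package = "fearcomb")
#' read_study_table(path)
read_study_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE, na.strings = "",
                          check.names = TRUE, quote = "\"",
                          fileEncoding = "UTF-8")
  study_table(df)
}

#' Write a study table to delimited text
#'
#' Missing values are written as empty fields, so [read_study_table()]
#' round-trips exactly up to numeric formatting.
#'
#' @param x A [study_table()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "study_table"))
  utils::write.table(x$data, path, sep = sep, na = "", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Screening policy for implausible conditioned responses
#'
#' Participants whose raw difference score lies many cross-dataset standard
#' deviations from the cross-dataset mean are treated as technical failures
#' rather than genuine responders. Heart period responses use a wider
#' threshold (5 SD) than the other measures (3 SD), reflecting their larger
#' measurement-unit tail. In addition, a whole measure can be excluded for a
#' whole dataset (e.g. when a recording chain was faulty for one
#' experiment).
#'
#' @param z_threshold Named positive numeric vector of |z| cutoffs per
#'   measure; unnamed defaults are SCR/PSR/RAR = 3, HPR = 5.
#' @param dataset_measure_exclusions Optional data.frame with columns
#'   `dataset_id` and `measure`: these values are blanked wholesale.
#' @param level `"participant"` drops the entire participant when any
#'   measure exceeds its threshold (default); `"value"` only blanks the
#'   offending value.
#' @param min_valid_fraction Reserved knob in (0, 1]; fraction of
#'   non-missing measures a record must retain to be kept.
#' @return An object of class `screening_policy`.
#' @export
screening_policy <- function(z_threshold = NULL,
                             dataset_measure_exclusions = NULL,
                             level = c("participant", "value"),
                             min_valid_fraction = 1e-9) {
  zt <- c(SCR = 3, PSR = 3, RAR = 3, HPR = 5)
  if (!is.null(z_threshold)) {
    bad <- setdiff(names(z_threshold), names(zt))
    if (length(bad)) stop("unknown measure(s): ", paste(bad, collapse = ", "))
    if (any(z_threshold <= 0)) stop("z thresholds must be strictly positive")
    zt[names(z_threshold)] <- z_threshold
  }
  if (!is.null(dataset_measure_exclusions)) {
    stopifnot(is.data.frame(dataset_measure_exclusions),
              all(c("dataset_id", "measure") %in%
                    names(dataset_measure_exclusions)))
    dataset_measure_exclusions$measure <-
      check_measures(dataset_measure_exclusions$measure)
  }
  structure(list(z_threshold = zt,
                 dataset_measure_exclusions = dataset_measure_exclusions,
                 level = match.arg(level),
                 min_valid_fraction = min_valid_fraction),
            class = "screening_policy")
}

#' Screen participants for implausible conditioned response differences
#'
#' For each measure, the mean and sample SD of the raw differences are
#' computed across all datasets; values with |z| above the measure's
#' threshold are flagged. Under the default participant-level policy a
#' flagged value removes the whole participant; under the value-level
#' policy only the value is blanked. Dataset-level measure exclusions are
#' applied first.
#'
#' @param table A [study_table()].
#' @param policy A [screening_policy()].
#' @return A list with elements `table` (screened [study_table()]) and
#'   `exclusions` (data.frame with `dataset_id`, `participant_id`,
#'   `measure`, `value`, `z`, `action`); `exclusions` has zero rows when
#'   nothing was flagged.
#' @export
#' @examples
#' tab <- generate_study(fer02_preset(n = 40, seed = 1))$table
#' scr <- screen_participants(tab, screening_policy())
#' nrow(scr$exclusions)
screen_participants <- function(table, policy = screening_policy()) {
  stopifnot(inherits(table, "study_table"))
  if (!nrow(table$data)) stop("empty study table")
  df <- table$data
  report <- data.frame(dataset_id = character(), participant_id = character(),
                       measure = character(), value = numeric(),
                       z = numeric(), action = character(),
                       stringsAsFactors = FALSE)
  dme <- policy$dataset_measure_exclusions
  if (!is.null(dme) && nrow(dme)) {
    for (i in seq_len(nrow(dme))) {
      sel <- df$dataset_id == dme$dataset_id[i] & !is.na(df[[dme$measure[i]]])
      if (any(sel)) {
        report <- rbind(report, data.frame(
          dataset_id = df$dataset_id[sel],
          participant_id = df$participant_id[sel],
          measure = dme$measure[i], value = df[[dme$measure[i]]][sel],
          z = NA_real_, action = "dataset_measure_excluded",
          stringsAsFactors = FALSE))
        df[[dme$measure[i]]][sel] <- NA_real_
      }
    }
  }
  drop_participant <- rep(FALSE, nrow(df))
  for (m in measure_kinds()) {
    v <- df[[m]]
    if (sum(!is.na(v)) == 0) next
    if (sum(!is.na(v)) < 3) {
      warning("fewer than 3 values for ", m, " across datasets; not screened")
      next
    }
    z <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
    hit <- which(!is.na(z) & abs(z) > policy$z_threshold[[m]])
    if (length(hit)) {
      act <- if (policy$level == "participant") "participant_excluded"
             else "value_excluded"
      report <- rbind(report, data.frame(
        dataset_id = df$dataset_id[hit], participant_id = df$participant_id[hit],
        measure = m, value = v[hit], z = z[hit], action = act,
        stringsAsFactors = FALSE))
      if (policy$level == "participant") drop_participant[hit] <- TRUE
      else df[[m]][hit] <- NA_real_
    }
  }
  if (any(drop_participant)) df <- df[!drop_participant, , drop = FALSE]
  vals <- as.matrix(df[measure_kinds()])
  df <- df[rowSums(!is.na(vals)) > 0, , drop = FALSE]
  list(table = study_table(df), exclusions = report)
}

#' Scale difference scores by the standard deviation of their dataset
#'
#' Different measurement systems (and experiments) report conditioned
#' responses on arbitrary scales; dividing each participant's difference
#' score by the sample SD of its own dataset removes that nuisance scale,
#' allowing participants from several datasets to be pooled. The function
#' keeps only participants with complete data on the requested measure
#' subset, computes the per-dataset, per-measure sample SD (denominator
#' n-1) over those retained participants, and divides. With `orient = TRUE`
#' (the default) each measure column is then multiplied by its expected
#' effect sign (see [effect_signs()]) so the expected conditioned effect is
#' positive for every measure.
#'
#' @param table A [study_table()].
#' @param measures Ordered subset of [measure_kinds()]; defaults to all
#'   four.
#' @param orient Multiply columns by their expected effect sign.
#' @param sd_scope `"subset"` (default) computes the scaling SD over the
#'   complete-case participants entering this analysis; `"dataset"` uses
#'   all non-missing values of the measure in the dataset, whether or not
#'   the participant is a complete case for the subset.
#' @param signs Effect signs, see [effect_signs()].
#' @return An object of class `scaled_matrix`: list with `values`
#'   (participants x measures, no missing entries), `measures`,
#'   `participant_index` (data.frame `dataset_id`, `participant_id`),
#'   `scaling` (data.frame `dataset_id`, `measure`, `sd`), and `oriented`.
#' @export
#' @examples
#' tab <- generate_study(fer02_preset(n = 30, seed = 2))$table
#' X <- scale_by_dataset_sd(tab, c("SCR", "PSR"))
#' round(apply(X$values, 2, sd), 10) # exactly 1 within a single dataset
scale_by_dataset_sd <- function(table, measures = NULL, orient = TRUE,
                                sd_scope = c("subset", "dataset"),
                                signs = effect_signs()) {
  stopifnot(inherits(table, "study_table"))
  sd_scope <- match.arg(sd_scope)
  measures <- check_measures(measures)
  for (m in measures) {
    if (!any(table$availability[, m])) {
      stop("measure ", m, " is unavailable in every dataset")
    }
  }
  df <- table$data
  vals <- as.matrix(df[measures])
  cc <- rowSums(is.na(vals)) == 0
  df <- df[cc, , drop = FALSE]
  vals <- vals[cc, , drop = FALSE]
  if (!nrow(df)) stop("no complete cases for subset ",
                      paste(measures, collapse = "+"))
  # drop datasets that cannot support an SD estimate on this subset
  keep_ds <- names(which(table(df$dataset_id) >= 2))
  dropped <- setdiff(unique(df$dataset_id), keep_ds)
  if (length(dropped)) {
    warning("dataset(s) with <2 complete cases dropped: ",
            paste(dropped, collapse = ", "))
    sel <- df$dataset_id %in% keep_ds
    df <- df[sel, , drop = FALSE]
    vals <- vals[sel, , drop = FALSE]
  }
  if (!nrow(df)) stop("no dataset retains >=2 complete cases")
  scaling <- data.frame(dataset_id = character(), measure = character(),
                        sd = numeric(), stringsAsFactors = FALSE)
  out <- vals
  for (d in unique(df$dataset_id)) {
    rows <- df$dataset_id == d
    for (j in seq_along(measures)) {
      s <- if (sd_scope == "subset") {
        stats::sd(vals[rows, j])
      } else {
        stats::sd(table$data[[measures[j]]][table$data$dataset_id == d],
                  na.rm = TRUE)
      }
      if (!is.finite(s) || s == 0) {
        stop("zero within-dataset SD for ", measures[j], " in dataset ", d)
      }
      out[rows, j] <- vals[rows, j] / s
      scaling <- rbind(scaling, data.frame(dataset_id = d,
                                           measure = measures[j], sd = s,
                                           stringsAsFactors = FALSE))
    }
  }
  if (orient) out <- sweep(out, 2, signs[measures], `*`)
  dimnames(out) <- list(NULL, measures)
  structure(list(values = out, measures = measures,
                 participant_index = df[c("dataset_id", "participant_id")],
                 scaling = scaling, oriented = orient),
            class = "scaled_matrix")
}

#' @export
print.scaled_matrix <- function(x, ...) {
  cat("scaled_matrix:", nrow(x$values), "complete cases x",
      length(x$measures), "measure(s) [",
      paste(x$measures, collapse = ", "), "]",
      if (x$oriented) "(oriented)" else "(raw signs)", "\n")
  invisible(x)
}

# accept either a scaled_matrix or a bare numeric matrix in analysis code
as_values_matrix <- function(X) {
  if (inherits(X, "scaled_matrix")) X$values
  else if (is.matrix(X) && is.numeric(X)) X
  else stop("expected a scaled_matrix or numeric matrix")
}
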