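test_that("CSV parsing derives availability and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dataset_id,participant_id,SCR,HPR",
               "A,p1,0.5,10", "A,p2,0.7,12", "A,p3,0.2,8"), path)
  tab <- read_study_table(path)
  expect_s3_class(tab, "study_table")
  expect_equal(nrow(tab$data), 3)
  expect_equal(unname(tab$availability["A", ]),
               c(TRUE, FALSE, FALSE, TRUE)) # SCR, PSR, RAR, HPR order

  # a whole-dataset empty column marks the measure unavailable there
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("dataset_id,participant_id,SCR,PSR",
               "A,p1,0.5,", "A,p2,0.7,", "B,q1,0.1,0.3", "B,q2,0.2,0.1"),
             path2)
  tab2 <- read_study_table(path2)
  expect_false(tab2$availability["A", "PSR"])
  expect_true(tab2$availability["B", "PSR"])

  # write -> read identity
  out <- withr::local_tempfile(fileext = ".csv")
  write_study_table(tab2, out)
  back <- read_study_table(out)
  expect_equal(back$data, tab2$data)
  expect_equal(back$availability, tab2$availability)
})

test_that("malformed tables are rejected with informative errors", {
  expect_error(study_table(data.frame(dataset_id = "A", participant_id = "p",
                                      SCR = "oops")), "non-numeric")
  df <- data.frame(dataset_id = c("A", "A"), participant_id = c("p1", "p1"),
                   SCR = c(1, 2))
  expect_error(study_table(df), "A/p1")
  expect_error(study_table(data.frame(dataset_id = "A",
                                      participant_id = "p1",
                                      SCR = NA_real_)), "no non-missing")
})

test_that("screening drops participants beyond the cross-dataset z threshold", {
  sim <- generate_study(fer02_preset(n = 60, seed = 42))
  df <- sim$table$data
  # plant an HPR outlier far below the cross-dataset mean (raw HPR is in ms)
  mu <- mean(df$HPR); s <- sd(df$HPR)
  df$HPR[7] <- mu - 10 * s
  scr <- screen_participants(study_table(df), screening_policy())
  expect_true(df$participant_id[7] %in% scr$exclusions$participant_id)
  expect_false(df$participant_id[7] %in% scr$table$data$participant_id)
  expect_equal(scr$exclusions$action[scr$exclusions$participant_id ==
                                       df$participant_id[7]],
               "participant_excluded")
  expect_true(abs(scr$exclusions$z[1]) > 5)

  # value-level alternative blanks the value but keeps the participant
  scr2 <- screen_participants(study_table(df),
                              screening_policy(level = "value"))
  expect_true(df$participant_id[7] %in% scr2$table$data$participant_id)
  expect_true(is.na(scr2$table$data$HPR[scr2$table$data$participant_id ==
                                          df$participant_id[7]]))
})

test_that("clean data passes screening unchanged; dataset-level exclusions blank a measure", {
  tab <- make_toy_table()
  scr <- screen_participants(tab, screening_policy())
  expect_equal(scr$table$data, tab$data)
  expect_equal(nrow(scr$exclusions), 0)

  pol <- screening_policy(dataset_measure_exclusions =
                            data.frame(dataset_id = "B", measure = "HPR"))
  scr2 <- screen_participants(tab, pol)
  expect_true(all(is.na(scr2$table$data$HPR)))
  expect_equal(unique(scr2$exclusions$action), "dataset_measure_excluded")
  expect_equal(nrow(scr2$exclusions), 4)
})

test_that("dataset-SD scaling divides by the n-1 sample SD and orients signs", {
  tab <- study_table(data.frame(dataset_id = "A",
                                participant_id = c("p1", "p2"),
                                SCR = c(1, 3)))
  X <- scale_by_dataset_sd(tab, "SCR")
  expect_equal(unname(X$values[, 1]), c(1, 3) / sqrt(2)) # SD = sqrt(2)
  expect_equal(X$scaling$sd, sqrt(2))

  # within a single dataset every scaled column has sample SD exactly 1,
  # and RAR is flipped positive under orientation
  sim <- generate_study(fer02_preset(n = 40, seed = 9))
  Xs <- scale_by_dataset_sd(sim$table)
  expect_equal(unname(apply(Xs$values, 2, sd)), rep(1, 4))
  expect_gt(mean(Xs$values[, "RAR"]), 0)
  raw_rar <- sim$table$data$RAR
  expect_lt(mean(raw_rar), 0) # raw conditioned RAR effect is negative
  # multiplying back by the stored divisor (and sign) recovers raw values
  rar_sd <- Xs$scaling$sd[Xs$scaling$measure == "RAR"]
  expect_equal(unname(Xs$values[, "RAR"] * rar_sd * -1), raw_rar)
})

test_that("complete-case subsetting matches a brute-force recount", {
  tab <- generate_study(table1_preset(seed = 7))$table
  for (ms in list(c("SCR", "PSR"), c("SCR", "RAR", "HPR"), measure_kinds())) {
    X <- suppressWarnings(scale_by_dataset_sd(tab, ms))
    vals <- as.matrix(tab$data[ms])
    cc <- rowSums(is.na(vals)) == 0
    # brute-force recount, excluding datasets with < 2 complete cases
    counts <- table(tab$data$dataset_id[cc])
    expect_equal(nrow(X$values), sum(counts[counts >= 2]))
  }
  # all-four subset only retains datasets carrying all four measures
  X4 <- scale_by_dataset_sd(tab, measure_kinds())
  expect_setequal(unique(X4$participant_index$dataset_id),
                  c("FER02", "PubFe", "SC4B"))
})

test_that("scaling edge cases: zero SD errors, small datasets dropped, rescaling is a positive rescale", {
  tab <- study_table(data.frame(dataset_id = c("A", "A", "A"),
                                participant_id = c("p1", "p2", "p3"),
                                SCR = c(2, 2, 2)))
  expect_error(scale_by_dataset_sd(tab, "SCR"), "zero within-dataset SD")

  tab2 <- study_table(data.frame(
    dataset_id = c("A", "A", "B"), participant_id = c("p1", "p2", "q1"),
    SCR = c(1, 2, 5)))
  expect_warning(X <- scale_by_dataset_sd(tab2, "SCR"), "dropped")
  expect_equal(nrow(X$values), 2)

  # rescaling an already-scaled single-dataset matrix only multiplies each
  # column by a positive scalar (here exactly 1, since SD is already 1)
  sim <- generate_study(fer02_preset(n = 30, seed = 3))
  X1 <- scale_by_dataset_sd(sim$table)
  tab_rescaled <- study_table(cbind(X1$participant_index,
                                    as.data.frame(X1$values)))
  X2 <- scale_by_dataset_sd(tab_rescaled, measure_kinds(), orient = FALSE)
  ratio <- X2$values / X1$values
  expect_true(all(abs(ratio - 1) < 1e-12))
})

test_that("screen-then-scale equals scale-then-screen on threshold-free data", {
  sim <- generate_study(fer02_preset(n = 50, seed = 21))
  scr <- screen_participants(sim$table, screening_policy())
  expect_equal(nrow(scr$exclusions), 0) # seed chosen small-n: no outliers
  X_direct <- scale_by_dataset_sd(sim$table)
  X_screened <- scale_by_dataset_sd(scr$table)
  expect_equal(X_screened$values, X_direct$values)
})
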