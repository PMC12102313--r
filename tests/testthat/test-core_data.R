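test_that("minor age imputation is uniform on the band and reproducible", {
  expect_true(all(impute_minor_age(rep("5-9", 200), seed = 1) %in% 5:9))
  expect_identical(impute_minor_age(rep("0-4", 50), seed = 3),
                   impute_minor_age(rep("0-4", 50), seed = 3))
  draws <- impute_minor_age(rep("10-14", 10000), seed = 42)
  freq <- table(factor(draws, levels = 10:14)) / 10000
  expect_true(all(abs(freq - 0.2) < 0.02))
  expect_gt(chisq.test(table(factor(draws, levels = 10:14)))$p.value, 0.01)
  expect_error(impute_minor_age("19-25"), "unknown age band")
})

test_that("contact truncation caps at 50 and is idempotent and monotone", {
  expect_identical(truncate_contacts(73L), 50L)
  expect_identical(truncate_contacts(0L), 0L)
  expect_identical(truncate_contacts(50L), 50L)
  y <- 0:120
  expect_identical(truncate_contacts(truncate_contacts(y)), truncate_contacts(y))
  expect_true(all(diff(truncate_contacts(y)) >= 0))
  expect_error(truncate_contacts(-1L), "negative")
})

test_that("preprocessing drops incomplete records, bins household size and builds the age factor", {
  raw <- data.frame(
    participant_id = sprintf("P%d", 1:7),
    wave = 1L, repeat_count = 0L, date = "2020-06-04",
    age = c(30L, NA, NA, 90L, 4L, 17L, 64L),
    age_band = c(NA, NA, "5-9", NA, "0-4", "15-18", NA),
    sex = c("male", "female", "female", "male", "female", "male", NA),
    household_size = c("2", "3", "7", "1", "4", "5+", "2"),
    employment = "Retired", symptoms = "no", day_type = "weekday",
    urban_type = "urban", contact_count = c(3L, 80L, 5L, 2L, 1L, 0L, 4L),
    schooling_flag = c(NA, NA, NA, NA, "raised at home", NA, NA),
    stringsAsFactors = FALSE
  )
  expect_warning(expect_message(out <- preprocess_records(raw, seed = 5),
                                "dropped 2"), "age outside 0-84")
  # P2 (no age info) and P7 (no sex) dropped; P4 dropped for age 90
  expect_setequal(out$participant_id, c("P1", "P3", "P5", "P6"))
  expect_equal(unname(attr(out, "dropped")), c(2, 1, 0))
  expect_true(all(out$contact_count <= 50))
  expect_true(out$age[out$participant_id == "P3"] %in% 5:9)
  expect_equal(as.character(out$household_size[out$participant_id == "P3"]), "5+")
  expect_equal(as.character(out$age_group[out$participant_id == "P5"]),
               "Raised at home (0-5)")
})

test_that("panel validation flags repeated first-time rows and non-increasing repeats", {
  ok <- data.frame(participant_id = c("a", "a", "b"), wave = c(1, 2, 2),
                   repeat_count = c(0, 1, 0))
  expect_true(validate_panel(ok))
  bad1 <- transform(ok, repeat_count = c(0, 0, 0))
  expect_error(validate_panel(bad1), "first-time more than once")
  bad2 <- data.frame(participant_id = "a", wave = 1:2, repeat_count = c(2, 1))
  expect_error(validate_panel(bad2), "not strictly increasing")
})

test_that("one-hot design blocks have the documented dimensions and row sums", {
  rec <- fx_small_panel()$rec
  enc <- encode_design(rec)
  expect_equal(ncol(enc$u), 14 + 2 + 5)
  expect_equal(ncol(enc$v), 9 + 2 + 2 + 3)
  expect_equal(ncol(enc$w), 14 + 2 + 5 + 9 + 3)
  expect_true(all(rowSums(enc$u) == 3))
  expect_true(all(rowSums(enc$v) == 4))
  expect_true(all(rowSums(enc$w) == 5))
  # column order: one block per factor, canonical level order within block
  expect_identical(colnames(enc$u)[15:16], c("sex:male", "sex:female"))
  i <- which(rec$sex == "female")[1]
  expect_equal(unname(enc$u[i, 15:16]), c(0, 1))
  # encode -> label lookup round-trip on every factor of the u block
  for (f in c("age_group", "sex", "household_size")) {
    cols <- grep(paste0("^", f, ":"), colnames(enc$u))
    lev <- sub(paste0(f, ":"), "", colnames(enc$u)[cols], fixed = TRUE)
    decoded <- lev[max.col(enc$u[, cols])]
    expect_identical(decoded, as.character(rec[[f]]))
  }
  bad <- rec[1:3, ]
  bad$employment <- "Astronaut"
  expect_error(encode_design(bad), "employment.*Astronaut")
})

test_that("post-stratification weights normalise each margin to one", {
  rec <- fx_small_panel()$rec
  w <- build_poststrat_weights(synthetic_pop_margins(), rec)
  expect_lt(abs(sum(w$v_ag) - 1), 1e-12)
  expect_lt(abs(sum(w$v_g) - 1), 1e-12)
  expect_lt(abs(sum(w$v_h) - 1), 1e-12)
  expect_lt(abs(sum(w$v_u) - 1), 1e-12)
  expect_lt(abs(sum(w$v_j) - 1), 1e-12)
  expect_true(all(w$v_ag >= 0) && all(w$v_j >= 0))

  # hand-checkable normalisation: 40/60 sex split
  pm <- synthetic_pop_margins()
  pm$age_sex$count <- ifelse(pm$age_sex$sex == "male", 40, 60)
  w2 <- build_poststrat_weights(pm, rec)
  expect_equal(unname(w2$v_g), c(0.4, 0.6), tolerance = 1e-12)

  # employment margin comes from sample counts
  counts <- table(rec$employment)
  expect_equal(w$v_j, as.numeric(counts) / sum(counts), tolerance = 1e-12)

  # empty employment stratum is an error
  rec2 <- rec[rec$employment != "Long-term sick", ]
  rec2$employment <- droplevels(rec2$employment)
  rec2$employment <- factor(as.character(rec2$employment),
                            levels = survey_levels$employment)
  expect_error(build_poststrat_weights(pm, rec2), "Long-term sick")
})

test_that("survey records survive a CSV round-trip", {
  rec <- fx_small_panel()$sim$records[1:50, ]
  path <- tempfile(fileext = ".csv")
  write_survey_records(rec, path)
  back <- read_survey_records(path)
  expect_equal(back$contact_count, rec$contact_count)
  expect_equal(back$participant_id, rec$participant_id)
  expect_equal(preprocess_records(back, seed = 1)$age_group,
               preprocess_records(rec, seed = 1)$age_group)
})
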