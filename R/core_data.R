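## Canonical categorical level sets shared across the package. Level order
## is the column order of every one-hot / dummy encoding, so it is part of
## the package's contract.

#' Canonical factor levels of the survey schema
#'
#' Named list of the level sets used throughout: the 14-category
#' age/schooling factor (children aged 0-5 split into preschool attendees
#' and those raised at home), sex, household size (5+ pooled), employment
#' status (9 categories), COVID-like symptoms, day type and urban-rural
#' typology. Reported age bands for minors are `0-4`, `5-9`, `10-14`,
#' `15-18`.
#'
#' @export
survey_levels <- list(
  age_group = c("Preschool (0-5)", "Raised at home (0-5)", "6-9", "10-14",
                "15-19", "20-24", "25-34", "35-44", "45-54", "55-64",
                "65-69", "70-74", "75-79", "80-84"),
  sex = c("male", "female"),
  household_size = c("1", "2", "3", "4", "5+"),
  employment = c("Full-time employed", "Part-time employed", "Self-employed",
                 "Student (15+)", "Retired", "Long-term sick",
                 "Unemployed (seeking)", "Unemployed (not seeking)",
                 "Stay-at-home parent"),
  symptoms = c("no", "yes"),
  day_type = c("weekday", "weekend"),
  urban_type = c("rural", "intermediate", "urban"),
  age_band = c("0-4", "5-9", "10-14", "15-18"),
  schooling_flag = c("preschool", "raised at home")
)

# age range covered by each age band / age group
.age_band_range <- list("0-4" = c(0, 4), "5-9" = c(5, 9),
                        "10-14" = c(10, 14), "15-18" = c(15, 18))
.age_group_breaks <- c(0, 6, 10, 15, 20, 25, 35, 45, 55, 65, 70, 75, 80, 85)

#' Impute integer age for a minor from the reported age band
#'
#' Minors report age in bands; a detailed age is imputed from a discrete
#' uniform distribution over the band.
#'
#' @param age_band character vector of bands (`0-4`, `5-9`, `10-14`,
#'   `15-18`).
#' @param seed optional integer; when given, imputation is reproducible.
#' @return integer ages, one per band entry.
#' @export
impute_minor_age <- function(age_band, seed = NULL) {
  bad <- !age_band %in% names(.age_band_range)
  if (any(bad))
    stop("impute_minor_age: unknown age band(s): ",
         paste(unique(age_band[bad]), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  vapply(age_band, function(b) {
    rg <- .age_band_range[[b]]
    sample(rg[1]:rg[2], 1L)
  }, 0L, USE.NAMES = FALSE)
}

#' Truncate reported contact counts
#'
#' Counts are truncated at 50 (the 99th percentile in the motivating
#' survey) to limit the influence of extreme outliers.
#'
#' @param y integer contact counts (>= 0).
#' @param cap truncation point, default 50.
#' @return `pmin(y, cap)`.
#' @export
truncate_contacts <- function(y, cap = 50L) {
  if (any(y < 0, na.rm = TRUE)) stop("truncate_contacts: negative counts")
  pmin(y, cap)
}

# map integer ages + schooling flag to the 14-level age/schooling factor
age_to_group <- function(age, schooling_flag = NULL) {
  g <- as.character(cut(age, breaks = .age_group_breaks, right = FALSE,
                        labels = survey_levels$age_group[-1]))
  under6 <- !is.na(age) & age <= 5
  if (is.null(schooling_flag)) schooling_flag <- rep(NA_character_, length(age))
  g[under6] <- ifelse(!is.na(schooling_flag[under6]) &
                        schooling_flag[under6] == "raised at home",
                      "Raised at home (0-5)", "Preschool (0-5)")
  factor(g, levels = survey_levels$age_group)
}

#' Preprocess raw survey records
#'
#' Applies the standard cleaning pipeline: drop records missing both age
#' and age band or missing sex (logged), drop ages above 84 (with a
#' warning; the models cover ages 0-84), impute integer ages for minors
#' reported in bands, bin numeric household sizes to `{1,2,3,4,5+}`,
#' derive the 14-level age/schooling factor, coerce categoricals to their
#' canonical levels, and finally truncate contact counts at 50.
#'
#' @param records data.frame in the survey CSV schema (one row per
#'   participant-wave).
#' @param seed optional seed for the age imputation.
#' @return the cleaned data.frame, with attribute `dropped` (named counts
#'   of removed records by reason).
#' @export
preprocess_records <- function(records, seed = NULL) {
  req <- c("participant_id", "wave", "repeat_count", "sex",
           "household_size", "contact_count")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("preprocess_records: missing columns: ",
                         paste(miss, collapse = ", "))
  if (!"age" %in% names(records)) records$age <- NA_integer_
  if (!"age_band" %in% names(records)) records$age_band <- NA_character_
  dropped <- c(missing_age_or_sex = 0L, age_out_of_range = 0L,
               negative_count = 0L)

  no_age <- is.na(records$age) & (is.na(records$age_band) |
                                    !records$age_band %in% names(.age_band_range))
  no_sex <- is.na(records$sex) | !records$sex %in% survey_levels$sex
  drop1 <- no_age | no_sex
  dropped["missing_age_or_sex"] <- sum(drop1)
  records <- records[!drop1, , drop = FALSE]

  bad_y <- !is.na(records$contact_count) & records$contact_count < 0
  dropped["negative_count"] <- sum(bad_y)
  records <- records[!bad_y, , drop = FALSE]

  need_imp <- is.na(records$age)
  if (any(need_imp)) {
    records$age[need_imp] <- impute_minor_age(records$age_band[need_imp],
                                              seed = seed)
  }
  records$age <- as.integer(round(records$age))

  out_of_range <- records$age < 0 | records$age > 84
  if (any(out_of_range)) {
    warning(sprintf("preprocess_records: dropping %d record(s) with age outside 0-84",
                    sum(out_of_range)))
    dropped["age_out_of_range"] <- sum(out_of_range)
    records <- records[!out_of_range, , drop = FALSE]
  }

  hh <- as.character(records$household_size)
  hh_num <- suppressWarnings(as.numeric(hh))
  hh[!is.na(hh_num) & hh_num >= 5] <- "5+"
  hh[!is.na(hh_num) & hh_num < 5] <- as.character(hh_num[!is.na(hh_num) & hh_num < 5])
  records$household_size <- factor(hh, levels = survey_levels$household_size)

  for (f in c("sex", "employment", "symptoms", "day_type", "urban_type")) {
    if (f %in% names(records))
      records[[f]] <- factor(as.character(records[[f]]), levels = survey_levels[[f]])
  }
  sf <- if ("schooling_flag" %in% names(records))
    as.character(records$schooling_flag) else NULL
  records$age_group <- age_to_group(records$age, sf)
  records$contact_count <- truncate_contacts(records$contact_count)
  if ("date" %in% names(records)) records$date <- as.Date(records$date)

  if (dropped["missing_age_or_sex"] > 0)
    message(sprintf("preprocess_records: dropped %d record(s) missing age or sex",
                    dropped["missing_age_or_sex"]))
  attr(records, "dropped") <- dropped
  records
}

#' Validate the longitudinal panel structure
#'
#' Checks that each participant is first-time (`repeat_count == 0`) at most
#' once and that repeat counts increase strictly with wave.
#'
#' @param records preprocessed records.
#' @return invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_panel <- function(records) {
  by_id <- split(records[, c("wave", "repeat_count")], records$participant_id)
  for (id in names(by_id)) {
    d <- by_id[[id]][order(by_id[[id]]$wave), ]
    if (sum(d$repeat_count == 0) > 1)
      stop("validate_panel: participant ", id, " is first-time more than once")
    if (any(diff(d$repeat_count) <= 0))
      stop("validate_panel: repeat_count not strictly increasing for participant ", id)
  }
  invisible(TRUE)
}

## ---- categorical encodings -------------------------------------------------

# full one-hot encoding (no reference level dropped), columns "factor:level"
one_hot <- function(f, name) {
  if (anyNA(f)) stop("one_hot: missing values in factor '", name, "'")
  m <- stats::model.matrix(~ x - 1, data.frame(x = f))
  colnames(m) <- paste0(name, ":", levels(f))
  m
}

# dummy (reference-level-dropped) encoding, columns "factor:level"
dummy_encode <- function(f, name) {
  if (anyNA(f)) stop("dummy_encode: missing values in factor '", name, "'")
  m <- stats::model.matrix(~ x, data.frame(x = f))[, -1, drop = FALSE]
  colnames(m) <- paste0(name, ":", levels(f)[-1])
  m
}

as_canonical_factor <- function(x, name) {
  lev <- survey_levels[[if (name == "age_group") "age_group" else name]]
  f <- factor(as.character(x), levels = lev)
  if (anyNA(f)) {
    bad <- unique(as.character(x)[is.na(f)])
    stop("encode_design: unseen level(s) in '", name, "': ",
         paste(bad, collapse = ", "))
  }
  f
}

#' One-hot design blocks for the selection models
#'
#' Builds the three full one-hot blocks used by the feature-selection
#' models: `u` (controls: age/schooling 14, sex 2, household size 5),
#' `v` (intensity test features: employment 9, symptoms 2, day type 2,
#' urban type 3) and `w` (fatigue test features: age/schooling 14, sex 2,
#' household size 5, employment 9, urban type 3). No reference level is
#' dropped; identifiability comes from the sum-to-zero priors.
#'
#' @param records preprocessed records.
#' @param blocks which blocks to build (any of `"u"`, `"v"`, `"w"`).
#' @return list of class `encoded_design` with the requested blocks (each a
#'   matrix with `factor:level` column names) and `block_factors`, the
#'   factor composition of each block.
#' @export
encode_design <- function(records, blocks = c("u", "v", "w")) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  comp <- list(
    u = c("age_group", "sex", "household_size"),
    v = c("employment", "symptoms", "day_type", "urban_type"),
    w = c("age_group", "sex", "household_size", "employment", "urban_type")
  )
  out <- list(block_factors = comp[blocks])
  for (b in blocks) {
    mats <- lapply(comp[[b]], function(f)
      one_hot(as_canonical_factor(records[[f]], f), f))
    out[[b]] <- do.call(cbind, mats)
  }
  structure(out, class = "encoded_design")
}

## ---- post-stratification weights -------------------------------------------

#' Build post-stratification weights
#'
#' Sex, age-sex, household-size and urban-type margins are normalised from
#' population counts; the employment margin is normalised from the sample
#' (population estimates at that stratification level being unavailable).
#'
#' @param pop_margins list with data.frames `age_sex` (columns `age`,
#'   `sex`, `count`), `household_size` (`level`, `count`) and `urban_type`
#'   (`level`, `count`); all counts strictly positive.
#' @param sample preprocessed survey records supplying the employment
#'   margin.
#' @return object of class `poststrat_table` with margins `v_ag` (85 x 2
#'   matrix over ages 0-84 and sex), `v_g`, `v_h`, `v_u`, `v_j`, each
#'   summing to one.
#' @export
build_poststrat_weights <- function(pop_margins, sample) {
  for (nm in c("age_sex", "household_size", "urban_type")) {
    if (is.null(pop_margins[[nm]]))
      stop("build_poststrat_weights: missing population margin '", nm, "'")
    if (any(pop_margins[[nm]]$count <= 0))
      stop("build_poststrat_weights: non-positive count in margin '", nm, "'")
  }
  as_margin <- function(df, levels) {
    v <- tapply(df$count, factor(df$level, levels = levels), sum)
    if (anyNA(v)) stop("build_poststrat_weights: empty stratum in margin: ",
                       paste(levels[is.na(v)], collapse = ", "))
    v / sum(v)
  }
  ag <- pop_margins$age_sex
  ag$sex <- factor(as.character(ag$sex), levels = survey_levels$sex)
  if (anyNA(ag$sex) || !all(0:84 %in% ag$age))
    stop("build_poststrat_weights: age_sex margin must cover ages 0-84 and both sexes")
  v_ag <- with(ag, tapply(count, list(factor(age, 0:84), sex), sum))
  if (anyNA(v_ag)) stop("build_poststrat_weights: empty age-sex stratum")
  v_ag <- v_ag / sum(v_ag)

  emp <- factor(as.character(sample$employment), levels = survey_levels$employment)
  n_j <- table(emp)
  if (any(n_j == 0))
    stop("build_poststrat_weights: no sample records for employment level(s): ",
         paste(names(n_j)[n_j == 0], collapse = ", "))

  structure(list(
    v_ag = v_ag,
    v_g = colSums(v_ag),
    v_h = as_margin(pop_margins$household_size, survey_levels$household_size),
    v_u = as_margin(pop_margins$urban_type, survey_levels$urban_type),
    v_j = as.numeric(n_j) / sum(n_j),
    provenance = c(age_sex = "population", household_size = "population",
                   urban_type = "population", employment = "sample")
  ), class = "poststrat_table")
}

#' @export
print.poststrat_table <- function(x, ...) {
  cat("<poststrat_table>\n")
  cat("  sex:", paste(sprintf("%s=%.3f", survey_levels$sex, x$v_g), collapse = ", "), "\n")
  cat("  household:", paste(sprintf("%s=%.3f", survey_levels$household_size, x$v_h),
                            collapse = ", "), "\n")
  cat("  urban:", paste(sprintf("%s=%.3f", survey_levels$urban_type, x$v_u),
                        collapse = ", "), "\n")
  cat("  employment (from sample):",
      paste(sprintf("%.3f", x$v_j), collapse = ", "), "\n")
  invisible(x)
}

## ---- delimited text I/O ----------------------------------------------------

#' Read survey records from CSV
#'
#' @param path CSV file with the survey schema header (one row per
#'   participant-wave).
#' @return data.frame of raw records (not yet preprocessed).
#' @export
read_survey_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(participant_id = "character"))
}

#' Write survey records to CSV
#'
#' @param records data.frame of survey records.
#' @param path output path.
#' @export
write_survey_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
}

#' Read population margin tables
#'
#' Expects `age_sex.csv` (`age`, `sex`, `count`), `household_size.csv` and
#' `urban_type.csv` (`level`, `count`) inside `dir`.
#'
#' @param dir directory containing the three margin CSVs.
#' @return named list of margin data.frames.
#' @export
read_pop_margins <- function(dir) {
  read1 <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  list(age_sex = read1("age_sex.csv"),
       household_size = read1("household_size.csv"),
       urban_type = read1("urban_type.csv"))
}
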