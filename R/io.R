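# Readers and writers for the package's plain-text interchange formats:
# UTF-8 CSV with a header row for the data tables, JSON for the salt policy
# and the DRI table. Readers validate on the way in; writers emit exactly
# what the readers accept (round-trip safe).

read_csv_checked <- function(path, what) {
  if (!file.exists(path)) fail(what, ": file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a subjects table from CSV
#'
#' Expected columns: `subject_id`, `age`, `sex`, `survey_weight`,
#' `discretionary_status`, `has_salt_questionnaire`, `suppl_day1`,
#' `suppl_day2`, `suppl_quest_user`. See [validate_subjects()] for the
#' column semantics and units.
#'
#' @param path CSV file path.
#' @param age_bounds permitted age range.
#' @return validated subjects data frame.
#' @export
read_subjects <- function(path, age_bounds = c(7L, 69L)) {
  df <- read_csv_checked(path, "subjects")
  need_cols(df, c("subject_id", "age", "sex", "survey_weight",
                  "discretionary_status", "has_salt_questionnaire",
                  "suppl_day1", "suppl_day2", "suppl_quest_user"), "subjects")
  df$subject_id <- as.character(df$subject_id)
  if (!is.numeric(df$survey_weight)) {
    bad <- is.na(suppressWarnings(as.numeric(df$survey_weight)))
    fail("subjects: non-numeric survey_weight (subject_id ",
         paste(df$subject_id[bad], collapse = ", "), ")")
  }
  df$has_salt_questionnaire <- as.logical(df$has_salt_questionnaire)
  df$suppl_quest_user <- as.logical(df$suppl_quest_user)
  validate_subjects(df, age_bounds)
  df
}

#' Read a consumption-record table from CSV
#'
#' Expected columns: `subject_id`, `day`, `food_code`, `food_group`,
#' `amount` (g). An empty file with a header row is a valid, empty table.
#'
#' @param path CSV file path.
#' @param subjects optional subjects table for referential-integrity checks.
#' @return validated consumption data frame.
#' @export
read_consumption <- function(path, subjects = NULL) {
  df <- read_csv_checked(path, "consumption")
  df$subject_id <- as.character(df$subject_id)
  df$food_code <- as.character(df$food_code)
  validate_consumption(df, subjects)
  df
}

#' Read a food-composition table from CSV
#'
#' Expected columns: `food_code`, `iodine_nat` (ug/100 g), `added_salt`
#' (g/100 g), `manufacturer_group` (empty for none),
#' `discretionary_eligible`, `produced_with_salt`.
#'
#' @param path CSV file path.
#' @return validated composition data frame.
#' @export
read_composition <- function(path) {
  df <- read_csv_checked(path, "composition")
  need_cols(df, c("food_code", "iodine_nat", "added_salt",
                  "manufacturer_group", "discretionary_eligible",
                  "produced_with_salt"), "composition")
  df$food_code <- as.character(df$food_code)
  df$manufacturer_group <- as.character(df$manufacturer_group)
  df$manufacturer_group[!nzchar(df$manufacturer_group) |
                          is.na(df$manufacturer_group)] <- NA_character_
  df$discretionary_eligible <- as.logical(df$discretionary_eligible)
  df$produced_with_salt <- as.logical(df$produced_with_salt)
  validate_composition(df)
  df
}

#' Read a salt-policy configuration from JSON
#'
#' See [validate_policy()] for the document structure. Omitted
#' `salt_fraction` entries default to 1.
#'
#' @param path JSON file path.
#' @param age_bounds ages the never-user proportions must cover.
#' @return validated policy list.
#' @export
read_policy <- function(path, age_bounds = c(7L, 69L)) {
  if (!file.exists(path)) fail("policy: file not found: ", path)
  pol <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(pol$never_user_proportions)) {
    pol$never_user_proportions <-
      as.data.frame(do.call(rbind, lapply(pol$never_user_proportions,
                                          as.data.frame)))
  }
  pol <- fill_policy_defaults(pol)
  validate_policy(pol, age_bounds)
  pol
}

fill_policy_defaults <- function(pol) {
  for (g in names(pol$manufacturer)) {
    if (is.null(pol$manufacturer[[g]]$salt_fraction)) {
      pol$manufacturer[[g]]$salt_fraction <- 1.0
    }
  }
  pol
}

#' Read a DRI table from JSON
#'
#' The document is an array of objects with `age_low`, `age_high`, `sex`,
#' `ear`, `ul` (ug/d).
#'
#' @param path JSON file path.
#' @param age_bounds ages the bands must cover.
#' @return validated DRI data frame.
#' @export
read_dri <- function(path, age_bounds = c(7L, 69L)) {
  if (!file.exists(path)) fail("dri: file not found: ", path)
  dri <- jsonlite::read_json(path, simplifyVector = TRUE)
  dri <- as.data.frame(dri)
  validate_dri(dri, age_bounds)
  dri
}

#' Write package tables and configurations back to disk
#'
#' `write_survey_tables()` writes subjects, consumption and composition as
#' CSV plus the policy and DRI as JSON into a directory, using the exact
#' formats the `read_*` functions accept.
#'
#' @param data list with components `subjects`, `consumption`,
#'   `composition`, `policy`, `dri` (any subset).
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_survey_tables <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(data$subjects)) {
    utils::write.csv(data$subjects, file.path(dir, "subjects.csv"),
                     row.names = FALSE)
  }
  if (!is.null(data$consumption)) {
    utils::write.csv(data$consumption, file.path(dir, "consumption.csv"),
                     row.names = FALSE)
  }
  if (!is.null(data$composition)) {
    utils::write.csv(data$composition, file.path(dir, "composition.csv"),
                     row.names = FALSE)
  }
  if (!is.null(data$policy)) {
    pol <- data$policy
    pol$never_user_proportions <-
      lapply(seq_len(nrow(pol$never_user_proportions)), function(i) {
        as.list(pol$never_user_proportions[i, ])
      })
    jsonlite::write_json(pol, file.path(dir, "policy.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(data$dri)) {
    jsonlite::write_json(data$dri, file.path(dir, "dri.json"),
                         digits = NA, pretty = TRUE)
  }
  invisible(dir)
}
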