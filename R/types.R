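# Domain types and their validators. All tabular types are plain data
# frames with fixed column sets; the salt policy and the dietary reference
# intake (DRI) table carry structured configuration. Every validator either
# returns its argument invisibly or stops with a diagnostic naming the
# offending row/field -- no partially validated object ever escapes.

SEXES <- c("male", "female")
DISCRETIONARY_STATUSES <- c("never_adds_salt", "adds_salt", "unknown")
SOURCES <- c("natural", "manufacturer_salt", "discretionary_salt", "supplement")

fail <- function(...) stop(..., call. = FALSE)

need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    fail(what, ": missing column(s) ", paste(miss, collapse = ", "))
  }
}

#' Validate a subjects table
#'
#' A subjects table has one row per survey participant with columns:
#' \describe{
#'   \item{subject_id}{unique identifier (character).}
#'   \item{age}{age in whole years, within `age_bounds`.}
#'   \item{sex}{`"male"` or `"female"`.}
#'   \item{survey_weight}{positive weight making the sample representative
#'     of the target population.}
#'   \item{discretionary_status}{`"never_adds_salt"`, `"adds_salt"` or
#'     `"unknown"`. `"unknown"` is only allowed when `has_salt_questionnaire`
#'     is `FALSE` for that row (survey years in which the salt-use
#'     questionnaire was not administered).}
#'   \item{has_salt_questionnaire}{logical; whether the subject answered the
#'     salt-use questionnaire.}
#'   \item{suppl_day1, suppl_day2}{reported supplemental iodine (ug/d) on
#'     each recall day; `NA` when no supplemental iodine was reported.}
#'   \item{suppl_quest_user}{logical; reported use of possibly
#'     iodine-containing supplement categories in the frequency
#'     questionnaire.}
#' }
#'
#' @param subjects data frame as described above.
#' @param age_bounds length-2 integer vector of permitted ages (inclusive).
#' @return `subjects`, invisibly, if valid; otherwise an error naming the
#'   offending row and field.
#' @export
validate_subjects <- function(subjects, age_bounds = c(7L, 69L)) {
  need_cols(subjects, c("subject_id", "age", "sex", "survey_weight",
                        "discretionary_status", "has_salt_questionnaire",
                        "suppl_day1", "suppl_day2", "suppl_quest_user"),
            "subjects")
  id <- as.character(subjects$subject_id)
  if (anyDuplicated(id)) {
    fail("subjects: duplicated subject_id: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  bad_w <- !is.finite(subjects$survey_weight) | subjects$survey_weight <= 0
  if (any(bad_w)) {
    fail("subjects: survey_weight must be a positive number (subject_id ",
         paste(id[bad_w], collapse = ", "), ")")
  }
  bad_a <- !is.finite(subjects$age) | subjects$age < age_bounds[1] |
    subjects$age > age_bounds[2]
  if (any(bad_a)) {
    fail("subjects: age outside [", age_bounds[1], ", ", age_bounds[2],
         "] (subject_id ", paste(id[bad_a], collapse = ", "), ")")
  }
  if (!all(subjects$sex %in% SEXES)) {
    fail("subjects: sex must be one of ", paste(SEXES, collapse = "/"))
  }
  if (!all(subjects$discretionary_status %in% DISCRETIONARY_STATUSES)) {
    fail("subjects: discretionary_status must be one of ",
         paste(DISCRETIONARY_STATUSES, collapse = "/"))
  }
  bad_u <- subjects$discretionary_status == "unknown" &
    subjects$has_salt_questionnaire
  if (any(bad_u)) {
    fail("subjects: discretionary_status 'unknown' with ",
         "has_salt_questionnaire TRUE (subject_id ",
         paste(id[bad_u], collapse = ", "), ")")
  }
  for (cl in c("suppl_day1", "suppl_day2")) {
    bad_s <- !is.na(subjects[[cl]]) & subjects[[cl]] < 0
    if (any(bad_s)) {
      fail("subjects: negative ", cl, " (subject_id ",
           paste(id[bad_s], collapse = ", "), ")")
    }
  }
  invisible(subjects)
}

#' Validate a consumption-record table
#'
#' One row per food eaten by one subject on one recall day:
#' `subject_id`, `day` (1 or 2), `food_code`, `food_group`, `amount`
#' (g consumed, non-negative). A day on which a subject ate no eligible food
#' is simply absent from the table.
#'
#' @param records data frame of consumption records.
#' @param subjects optional validated subjects table; when given, referential
#'   integrity of `subject_id` is checked.
#' @return `records`, invisibly, if valid.
#' @export
validate_consumption <- function(records, subjects = NULL) {
  need_cols(records, c("subject_id", "day", "food_code", "food_group",
                       "amount"), "consumption")
  if (nrow(records)) {
    if (!all(records$day %in% c(1L, 2L))) {
      fail("consumption: day must be 1 or 2 (rows ",
           paste(utils::head(which(!records$day %in% c(1L, 2L)), 5),
                 collapse = ", "), ")")
    }
    bad <- !is.finite(records$amount) | records$amount < 0
    if (any(bad)) {
      fail("consumption: amount must be >= 0 (rows ",
           paste(utils::head(which(bad), 5), collapse = ", "), ")")
    }
    if (!is.null(subjects)) {
      unknown <- setdiff(unique(records$subject_id), subjects$subject_id)
      if (length(unknown)) {
        fail("consumption: subject_id not in subjects table: ",
             paste(utils::head(unknown, 5), collapse = ", "))
      }
    }
  }
  invisible(records)
}

#' Validate a food-composition table
#'
#' One row per food code: `food_code`, `iodine_nat` (ug iodine per 100 g,
#' naturally present), `added_salt` (g salt per 100 g added during
#' manufacture), `manufacturer_group` (label of the iodised-salt assignment
#' group, `NA` for foods outside the manufacturer-salt model),
#' `discretionary_eligible` (may salt be added at table/preparation) and
#' `produced_with_salt`. Foods produced with salt are never eligible for
#' discretionary salt addition.
#'
#' @param composition data frame as described above.
#' @return `composition`, invisibly, if valid.
#' @export
validate_composition <- function(composition) {
  need_cols(composition, c("food_code", "iodine_nat", "added_salt",
                           "manufacturer_group", "discretionary_eligible",
                           "produced_with_salt"), "composition")
  if (anyDuplicated(composition$food_code)) {
    fail("composition: duplicated food_code")
  }
  if (any(composition$iodine_nat < 0) || any(composition$added_salt < 0)) {
    fail("composition: iodine_nat and added_salt must be >= 0")
  }
  clash <- composition$produced_with_salt & composition$discretionary_eligible
  if (any(clash)) {
    fail("composition: foods produced with salt cannot be ",
         "discretionary_eligible (food_code ",
         paste(composition$food_code[clash], collapse = ", "), ")")
  }
  invisible(composition)
}

#' Validate a salt-policy configuration
#'
#' A salt policy is a list with components:
#' \describe{
#'   \item{manufacturer}{named list, one entry per manufacturer group, each a
#'     list with `market_share` (fraction of consumed product containing
#'     iodised salt, in \[0,1\]), `iodine_conc` (mg iodine per kg salt) and
#'     optional `salt_fraction` (fraction of the food's added salt
#'     attributable to iodised salt; defaults to 1).}
#'   \item{discretionary}{list with `iodine_conc` (mg iodine per kg salt),
#'     `added_amount` (named list: eligible food group -> g salt added per
#'     100 g food) and `use_share` (named list: eligible food group ->
#'     fraction of salt-adding subjects who add salt to that group).}
#'   \item{never_user_proportions}{data frame with columns `age_low`,
#'     `age_high`, `sex`, `proportion`: the fraction of each age-sex stratum
#'     that never adds salt discretionarily.}
#' }
#'
#' @param policy list as described above.
#' @param age_bounds ages that `never_user_proportions` must cover.
#' @return the policy, with `salt_fraction` defaults filled in, invisibly.
#' @export
validate_policy <- function(policy, age_bounds = c(7L, 69L)) {
  for (comp in c("manufacturer", "discretionary", "never_user_proportions")) {
    if (is.null(policy[[comp]])) fail("policy: missing component ", comp)
  }
  for (g in names(policy$manufacturer)) {
    e <- policy$manufacturer[[g]]
    if (is.null(e$market_share) || is.null(e$iodine_conc)) {
      fail("policy: manufacturer group '", g,
           "' needs market_share and iodine_conc")
    }
    if (e$market_share < 0 || e$market_share > 1) {
      fail("policy: market_share for '", g, "' must be in [0, 1], got ",
           e$market_share)
    }
    if (e$iodine_conc < 0) fail("policy: negative iodine_conc for '", g, "'")
    if (is.null(e$salt_fraction)) e$salt_fraction <- 1.0
    if (e$salt_fraction < 0 || e$salt_fraction > 1) {
      fail("policy: salt_fraction for '", g, "' must be in [0, 1]")
    }
    policy$manufacturer[[g]] <- e
  }
  d <- policy$discretionary
  if (is.null(d$iodine_conc) || d$iodine_conc < 0) {
    fail("policy: discretionary iodine_conc missing or negative")
  }
  if (is.null(d$added_amount) || !length(d$added_amount)) {
    fail("policy: discretionary added_amount missing")
  }
  if (any(unlist(d$added_amount) < 0)) {
    fail("policy: negative discretionary added_amount")
  }
  if (is.null(d$use_share)) {
    fail("policy: discretionary use_share missing")
  }
  us <- unlist(d$use_share)
  if (any(us < 0 | us > 1)) fail("policy: use_share must be in [0, 1]")
  miss_us <- setdiff(names(d$added_amount), names(d$use_share))
  if (length(miss_us)) {
    fail("policy: use_share missing for group(s) ",
         paste(miss_us, collapse = ", "))
  }
  nup <- policy$never_user_proportions
  need_cols(nup, c("age_low", "age_high", "sex", "proportion"),
            "policy$never_user_proportions")
  if (any(nup$proportion < 0 | nup$proportion > 1)) {
    fail("policy: never_user_proportions must be in [0, 1]")
  }
  check_band_cover(nup, age_bounds, "policy$never_user_proportions")
  invisible(policy)
}

# Bands must partition [age_bounds] per sex: no overlap, no gap.
check_band_cover <- function(bands, age_bounds, what) {
  for (s in SEXES) {
    b <- bands[bands$sex == s, , drop = FALSE]
    b <- b[order(b$age_low), , drop = FALSE]
    ages <- seq.int(age_bounds[1], age_bounds[2])
    hit <- integer(length(ages))
    for (i in seq_len(nrow(b))) {
      hit <- hit + (ages >= b$age_low[i] & ages <= b$age_high[i])
    }
    if (any(hit > 1)) {
      fail(what, ": overlapping age bands for sex ", s, " at age(s) ",
           paste(utils::head(ages[hit > 1], 5), collapse = ", "))
    }
    if (any(hit == 0)) {
      fail(what, ": uncovered (age, sex) cells for sex ", s, ": age(s) ",
           paste(utils::head(ages[hit == 0], 5), collapse = ", "))
    }
  }
  invisible(bands)
}

#' Validate a dietary-reference-intake table
#'
#' Columns `age_low`, `age_high`, `sex`, `ear`, `ul` (both ug/d). Bands must
#' partition the configured age range within each sex, and `ear < ul`
#' everywhere. Reference values (e.g. IOM EARs, SCF ULs) are user-supplied
#' configuration, not package constants.
#'
#' @param dri data frame as described.
#' @param age_bounds ages the bands must cover.
#' @return `dri`, invisibly, if valid.
#' @export
validate_dri <- function(dri, age_bounds = c(7L, 69L)) {
  need_cols(dri, c("age_low", "age_high", "sex", "ear", "ul"), "dri")
  bad <- dri$ear >= dri$ul
  if (any(bad)) {
    fail("dri: EAR must be < UL in every band (rows ",
         paste(which(bad), collapse = ", "), ")")
  }
  if (any(dri$ear < 0)) fail("dri: negative EAR")
  check_band_cover(dri, age_bounds, "dri")
  invisible(dri)
}

#' Find the DRI/stratum band for given ages and sexes
#'
#' @param bands data frame with `age_low`, `age_high`, `sex`.
#' @param age,sex vectors of equal length.
#' @return integer vector of row indices into `bands` (NA when uncovered).
#' @export
band_index <- function(bands, age, sex) {
  out <- rep(NA_integer_, length(age))
  for (i in seq_len(nrow(bands))) {
    hit <- sex == bands$sex[i] & age >= bands$age_low[i] &
      age <= bands$age_high[i]
    out[hit] <- i
  }
  out
}

band_label <- function(bands) {
  paste0(bands$sex, "_", bands$age_low, "-", bands$age_high)
}
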