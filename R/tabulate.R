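# Tabulation: convert consumption records plus composition and policy into
# per-subject-per-day iodine intakes for each of the four sources.
#
# Unit convention (fixed throughout the package): consumed amounts in g,
# composition per 100 g of food, salt iodine concentrations in mg iodine
# per kg salt, intakes in ug/d. The identity
#   g salt x (mg iodine / kg salt) = ug iodine
# makes the salt arithmetic below dimensionally exact.

# Every subject-day gets a row, including zero-intake days.
all_subject_days <- function(subjects) {
  data.frame(subject_id = rep(subjects$subject_id, each = 2L),
             day = rep(1:2, nrow(subjects)),
             stringsAsFactors = FALSE)
}

sum_by_day <- function(subjects, sub_ids, days, values, source) {
  base <- all_subject_days(subjects)
  key <- paste(base$subject_id, base$day)
  agg <- tapply(values, paste(sub_ids, days), sum)
  intake <- as.numeric(agg[key])
  intake[is.na(intake)] <- 0
  data.frame(subject_id = base$subject_id, day = base$day,
             source = source, intake = intake, stringsAsFactors = FALSE)
}

match_composition <- function(records, composition, what) {
  idx <- match(records$food_code, composition$food_code)
  if (anyNA(idx)) {
    fail(what, ": food code(s) not in composition table: ",
         paste(unique(records$food_code[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Daily iodine intake naturally present in foods
#'
#' Per subject-day, sums `amount * iodine_nat / 100` over consumed foods.
#' Foods assigned to a manufacturer iodised-salt group (e.g. bread) are
#' excluded here; their iodine is accounted for by the manufacturer-salt
#' source.
#'
#' @param records consumption records.
#' @param composition composition table.
#' @param subjects subjects table (defines the subject-day grid; days
#'   without eligible foods get intake 0).
#' @return data frame `subject_id`, `day`, `source = "natural"`, `intake`
#'   (ug/d), one row per subject-day.
#' @export
natural_iodine <- function(records, composition, subjects) {
  idx <- match_composition(records, composition, "natural_iodine")
  keep <- is.na(composition$manufacturer_group[idx])
  r <- records[keep, , drop = FALSE]
  conc <- composition$iodine_nat[idx[keep]]
  sum_by_day(subjects, r$subject_id, r$day, r$amount * conc / 100, "natural")
}

#' Daily iodine intake from manufacturer iodised salt
#'
#' For foods whose (subject, manufacturer group) pair is assigned as
#' iodised in `assignment`, contributes
#' `amount * added_salt/100 * salt_fraction * iodine_conc` ug.
#'
#' @param records consumption records.
#' @param composition composition table.
#' @param policy validated salt policy.
#' @param subjects subjects table.
#' @param assignment an assignment from [build_ensemble()] (component
#'   `iodised`: logical matrix subjects x manufacturer groups).
#' @return data frame of `manufacturer_salt` intakes per subject-day.
#' @export
manufacturer_iodine <- function(records, composition, policy, subjects,
                                assignment) {
  idx <- match_composition(records, composition, "manufacturer_iodine")
  grp <- composition$manufacturer_group[idx]
  keep <- !is.na(grp)
  r <- records[keep, , drop = FALSE]
  grp <- grp[keep]
  missing_pol <- setdiff(unique(grp), names(policy$manufacturer))
  if (length(missing_pol)) {
    fail("manufacturer_iodine: no policy entry for group(s) ",
         paste(missing_pol, collapse = ", "))
  }
  if (nrow(r) == 0L) {
    return(sum_by_day(subjects, character(), integer(), numeric(),
                      "manufacturer_salt"))
  }
  conc <- vapply(grp, function(g) policy$manufacturer[[g]]$iodine_conc,
                 numeric(1))
  sfrac <- vapply(grp, function(g) policy$manufacturer[[g]]$salt_fraction,
                  numeric(1))
  salt <- composition$added_salt[idx[keep]]
  si <- match(r$subject_id, rownames(assignment$iodised))
  gi <- match(grp, colnames(assignment$iodised))
  assigned <- assignment$iodised[cbind(si, gi)]
  assigned[is.na(assigned)] <- FALSE
  intake <- ifelse(assigned,
                   r$amount * salt / 100 * sfrac * conc, 0)
  sum_by_day(subjects, r$subject_id, r$day, intake, "manufacturer_salt")
}

#' Daily iodine intake from discretionarily added iodised salt
#'
#' For (subject, eligible food group) pairs assigned `adds_salt`,
#' contributes `amount * added_amount/100 * iodine_conc` ug over the
#' subject's foods of that group. Foods produced with salt are excluded
#' from discretionary addition, and subjects with status
#' `never_adds_salt` (or not assigned as discretionary users) always
#' contribute 0.
#'
#' @param records consumption records.
#' @param composition composition table.
#' @param policy validated salt policy.
#' @param subjects subjects table.
#' @param assignment assignment with components `discretionary_user`
#'   (named logical per subject) and `adds_salt` (logical matrix
#'   subjects x eligible groups).
#' @return data frame of `discretionary_salt` intakes per subject-day.
#' @export
discretionary_iodine <- function(records, composition, policy, subjects,
                                 assignment) {
  idx <- match_composition(records, composition, "discretionary_iodine")
  eligible <- composition$discretionary_eligible[idx] &
    !composition$produced_with_salt[idx]
  r <- records[eligible, , drop = FALSE]
  grp <- r$food_group
  if (nrow(r)) {
    missing_amt <- setdiff(unique(grp),
                           names(policy$discretionary$added_amount))
    if (length(missing_amt)) {
      fail("discretionary_iodine: no added_amount configured for group(s) ",
           paste(missing_amt, collapse = ", "))
    }
    added <- vapply(grp,
                    function(g) policy$discretionary$added_amount[[g]],
                    numeric(1))
    user <- assignment$discretionary_user[r$subject_id]
    user[is.na(user)] <- FALSE
    si <- match(r$subject_id, rownames(assignment$adds_salt))
    gi <- match(grp, colnames(assignment$adds_salt))
    adds <- assignment$adds_salt[cbind(si, gi)]
    adds[is.na(adds)] <- FALSE
    never <- subjects$discretionary_status[
      match(r$subject_id, subjects$subject_id)] == "never_adds_salt"
    active <- user & adds & !never
    intake <- ifelse(active,
                     r$amount * added / 100 * policy$discretionary$iodine_conc,
                     0)
  } else {
    intake <- numeric()
  }
  sum_by_day(subjects, r$subject_id, r$day, intake, "discretionary_salt")
}

#' Daily supplemental iodine intake
#'
#' The supplemental iodine a subject reported on each recall day; 0 when
#' none was reported.
#'
#' @param subjects subjects table.
#' @return data frame of `supplement` intakes per subject-day.
#' @export
supplement_daily <- function(subjects) {
  d1 <- subjects$suppl_day1
  d2 <- subjects$suppl_day2
  if (any(c(d1, d2) < 0, na.rm = TRUE)) {
    fail("supplement_daily: negative supplemental dose")
  }
  base <- all_subject_days(subjects)
  v <- ifelse(base$day == 1L,
              d1[match(base$subject_id, subjects$subject_id)],
              d2[match(base$subject_id, subjects$subject_id)])
  v[is.na(v)] <- 0
  data.frame(subject_id = base$subject_id, day = base$day,
             source = "supplement", intake = v, stringsAsFactors = FALSE)
}

#' Food-group contributions to natural iodine intake
#'
#' Per subject, the 2-day mean natural iodine intake of each food group is
#' divided by the subject's 2-day mean total; the survey-weighted mean of
#' these per-subject proportions is reported per group. Fractions sum to 1.
#'
#' @param records consumption records.
#' @param composition composition table.
#' @param subjects subjects table.
#' @return named numeric vector of weighted mean fractions, one per food
#'   group with any natural iodine.
#' @export
group_contributions <- function(records, composition, subjects) {
  idx <- match_composition(records, composition, "group_contributions")
  keep <- is.na(composition$manufacturer_group[idx])
  r <- records[keep, , drop = FALSE]
  iod <- r$amount * composition$iodine_nat[idx[keep]] / 100
  # 2-day mean per subject x group; a missing day contributes 0
  per_sg <- tapply(iod / 2, list(r$subject_id, r$food_group), sum,
                   default = 0)
  totals <- rowSums(per_sg)
  pos <- totals > 0
  if (!any(pos)) {
    fail("group_contributions: no subject with positive natural intake")
  }
  props <- per_sg[pos, , drop = FALSE] / totals[pos]
  w <- subjects$survey_weight[match(rownames(props), subjects$subject_id)]
  out <- colSums(props * w) / sum(w)
  out[order(-out)]
}

#' Assemble all four daily source intakes
#'
#' Runs the four tabulation steps and row-binds the result; total daily
#' intake is the sum of the four source rows per subject-day.
#'
#' @param records,composition,policy,subjects as in the individual steps.
#' @param assignment a salt-use assignment (see [build_ensemble()]).
#' @return data frame `subject_id`, `day`, `source`, `intake` with four
#'   rows per subject-day.
#' @export
tabulate_sources <- function(records, composition, policy, subjects,
                             assignment) {
  rbind(
    natural_iodine(records, composition, subjects),
    manufacturer_iodine(records, composition, policy, subjects, assignment),
    discretionary_iodine(records, composition, policy, subjects, assignment),
    supplement_daily(subjects)
  )
}
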