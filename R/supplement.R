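# Habitual supplemental iodine. Supplement doses are label amounts taken
# with a stable personal pattern, so a reported recall amount is treated as
# the subject's habitual amount rather than run through the
# measurement-error model. Potential users with no recall amount (user by
# frequency questionnaire only) get an amount predicted by a
# recursive-partitioning (regression-tree) model trained on the users with
# known amounts.

#' Habitual supplemental iodine intake
#'
#' Potential users are subjects with reported supplemental iodine in at
#' least one recall and/or reported use of possibly iodine-containing
#' supplement categories in the frequency questionnaire. Users with recall
#' amounts keep the mean of their reported daily amounts as habitual
#' intake; questionnaire-only users receive a regression-tree prediction
#' (default covariates: age and sex); non-users contribute 0.
#'
#' @param subjects subjects table.
#' @param covariates character vector of subjects-table columns used by the
#'   tree predictor.
#' @param control an [rpart::rpart.control()] for the tree (default: small
#'   tree suited to modest user counts).
#' @return an object of class `suppl_fit`; [habitual()] extracts the
#'   distribution over all subjects.
#' @export
supplement_habitual <- function(subjects, covariates = c("age", "sex"),
                                control = rpart::rpart.control(
                                  minsplit = 20, cp = 0.01, xval = 0)) {
  has_amount <- !is.na(subjects$suppl_day1) | !is.na(subjects$suppl_day2)
  potential <- has_amount | subjects$suppl_quest_user
  known_mean <- rowMeans(cbind(subjects$suppl_day1, subjects$suppl_day2),
                         na.rm = TRUE)
  habitual <- numeric(nrow(subjects))
  habitual[has_amount] <- known_mean[has_amount]

  quest_only <- potential & !has_amount
  tree <- NULL
  if (any(quest_only)) {
    if (!any(has_amount)) {
      fail("supplement_habitual: questionnaire-only users present but no ",
           "user has a known amount to train the predictor on")
    }
    train <- subjects[has_amount, covariates, drop = FALSE]
    train$.amount <- known_mean[has_amount]
    tree <- rpart::rpart(.amount ~ ., data = train, control = control,
                         weights = subjects$survey_weight[has_amount])
    habitual[quest_only] <- stats::predict(
      tree, newdata = subjects[quest_only, covariates, drop = FALSE])
  }

  structure(list(values = data.frame(subject_id = subjects$subject_id,
                                     age = subjects$age, sex = subjects$sex,
                                     habitual = habitual,
                                     weight = subjects$survey_weight,
                                     potential_user = potential,
                                     stringsAsFactors = FALSE),
                 tree = tree,
                 n_known = sum(has_amount),
                 n_quest_only = sum(quest_only)),
            class = "suppl_fit")
}

#' @export
habitual.suppl_fit <- function(fit, ...) {
  v <- fit$values
  intake_dist(v[, c("subject_id", "age", "sex", "habitual", "weight")])
}

#' @export
print.suppl_fit <- function(x, ...) {
  cat("Habitual supplemental iodine\n")
  cat(sprintf("  users with recall amounts: %d; questionnaire-only: %d\n",
              x$n_known, x$n_quest_only))
  d <- habitual(x)
  cat(sprintf("  weighted mean over all subjects: %.1f ug/d\n", mean(d)))
  invisible(x)
}
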