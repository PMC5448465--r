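# Two-part habitual-intake model for episodically consumed sources with
# true non-consumers. The habitual intake of a potential consumer is
# (age-dependent probability of consuming on a day) x (habitual amount on
# consumption days); identified true non-consumers (e.g. subjects who never
# add salt) contribute a structural habitual zero.

#' Fit the two-part habitual-intake model
#'
#' The probability part is an age-dependent consumption-day proportion
#' fitted by quasibinomial spline regression (per sex) to the day-level
#' consumption indicators of potential consumers. The amount part is a
#' one-part model ([hab_fit()]) on the positive-intake days only. The
#' habitual intake of potential consumer i is `p_i * amount_i`; never
#' consumers get 0.
#'
#' @param daily data frame `subject_id`, `day`, `intake` with one row per
#'   subject-day for every potential consumer (zeros included).
#' @param subjects subjects table.
#' @param never_ids subject ids of true non-consumers of this source
#'   (identified externally, e.g. by questionnaire or assignment); their
#'   daily rows, if present, are ignored.
#' @param lambda,df_spline,weighted,gh_order passed to [hab_fit()] for the
#'   amount part.
#' @return an object of class `hab_fit2`.
#' @export
hab_fit2 <- function(daily, subjects, never_ids = character(),
                     lambda = NULL, df_spline = 3L, weighted = TRUE,
                     gh_order = 15L) {
  stopifnot(all(c("subject_id", "day", "intake") %in% names(daily)))
  daily <- daily[!daily$subject_id %in% never_ids, , drop = FALSE]
  pot <- subjects[!subjects$subject_id %in% never_ids, , drop = FALSE]
  if (!nrow(daily) || !any(daily$intake > 0)) {
    fail("hab_fit2: no positive consumption days among potential consumers")
  }
  daily <- merge(daily, pot[, c("subject_id", "age", "sex", "survey_weight")],
                 by = "subject_id")

  ## probability part: day-level consumption indicator on age, per sex
  daily$consumed <- as.numeric(daily$intake > 0)
  prob_fits <- lapply(split(daily, daily$sex), function(d) {
    if (length(unique(d$consumed)) == 1L) {
      list(constant = d$consumed[1])
    } else if (length(unique(d$age)) < 7L || nrow(d) < 60L) {
      stats::glm(consumed ~ age, family = stats::quasibinomial(), data = d,
                 weights = d$survey_weight)
    } else {
      stats::glm(consumed ~ splines::bs(age, df = 4), data = d,
                 family = stats::quasibinomial(), weights = d$survey_weight)
    }
  })
  p_of <- function(age, sex) {
    out <- numeric(length(age))
    for (s in unique(sex)) {
      f <- prob_fits[[s]]
      sel <- sex == s
      out[sel] <- if (is.list(f) && !is.null(f$constant)) f$constant else
        stats::predict(f, newdata = data.frame(age = age[sel]),
                       type = "response")
    }
    pmin(pmax(out, 0), 1)
  }

  ## amount part: positive days only (1 or 2 per subject)
  amount_fit <- hab_fit(daily[daily$intake > 0,
                              c("subject_id", "day", "intake")],
                        pot, lambda = lambda, df_spline = df_spline,
                        weighted = weighted, gh_order = gh_order,
                        require_two_days = FALSE)

  amt <- habitual(amount_fit)
  # subjects with no positive day: habitual amount predicted from the
  # population age curve (their probability part keeps them near zero)
  miss <- setdiff(pot$subject_id, amt$subject_id)
  if (length(miss)) {
    ms <- pot[match(miss, pot$subject_id), , drop = FALSE]
    amt <- rbind(as.data.frame(amt),
                 data.frame(subject_id = ms$subject_id, age = ms$age,
                            sex = ms$sex,
                            habitual = predict(amount_fit, ms, type = "mean"),
                            weight = ms$survey_weight,
                            stringsAsFactors = FALSE))
  }
  p_i <- p_of(amt$age, amt$sex)
  pot_dist <- data.frame(subject_id = amt$subject_id, age = amt$age,
                         sex = amt$sex, habitual = p_i * amt$habitual,
                         weight = amt$weight, p = p_i,
                         amount = amt$habitual, stringsAsFactors = FALSE)
  nev <- subjects[subjects$subject_id %in% never_ids, , drop = FALSE]
  all_dist <- rbind(pot_dist,
                    if (nrow(nev)) data.frame(subject_id = nev$subject_id,
                                              age = nev$age, sex = nev$sex,
                                              habitual = 0,
                                              weight = nev$survey_weight,
                                              p = 0, amount = 0,
                                              stringsAsFactors = FALSE))
  structure(list(amount_fit = amount_fit, prob_fits = prob_fits,
                 values = all_dist, never_ids = never_ids,
                 never_fraction = sum(all_dist$weight[all_dist$subject_id
                                                      %in% never_ids]) /
                   sum(all_dist$weight),
                 call = match.call()),
            class = "hab_fit2")
}

#' @export
habitual.hab_fit2 <- function(fit, ...) {
  v <- fit$values
  intake_dist(v[, c("subject_id", "age", "sex", "habitual", "weight")])
}

#' @export
print.hab_fit2 <- function(x, ...) {
  cat("Habitual intake model (two-part, with true non-consumers)\n")
  cat(sprintf("  never-consumer fraction (weighted): %.3f\n",
              x$never_fraction))
  cat(sprintf("  mean consumption probability: %.3f\n",
              stats::weighted.mean(x$values$p, x$values$weight)))
  cat("  amount part:\n")
  print(x$amount_fit)
  invisible(x)
}

#' @export
coef.hab_fit2 <- function(object, ...) {
  coef(object$amount_fit)
}
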