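# Shared fixtures, all built in code. Expensive synthetic fits are
# memoised so several test files can reuse them.

make_subjects <- function(n = 3, age = NULL, sex = NULL, weight = NULL,
                          status = "adds_salt") {
  data.frame(
    subject_id = sprintf("T%03d", seq_len(n)),
    age = if (is.null(age)) rep(30L, n) else age,
    sex = if (is.null(sex)) rep("female", n) else sex,
    survey_weight = if (is.null(weight)) rep(1, n) else weight,
    discretionary_status = rep(status, length.out = n),
    has_salt_questionnaire = rep(status, length.out = n) != "unknown",
    suppl_day1 = NA_real_, suppl_day2 = NA_real_,
    suppl_quest_user = FALSE,
    stringsAsFactors = FALSE
  )
}

tiny_composition <- function() {
  data.frame(
    food_code = c("MILK", "BREAD", "PIZZA", "POTATO", "HAM"),
    iodine_nat = c(16, 1, 2, 2, 3),
    added_salt = c(0, 1.25, 1.5, 0, 2),
    manufacturer_group = c(NA, "bread", "pizza", NA, NA),
    discretionary_eligible = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    produced_with_salt = c(FALSE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

tiny_policy <- function() {
  validate_policy(list(
    manufacturer = list(
      bread = list(market_share = 0.95, iodine_conc = 58),
      pizza = list(market_share = 0.4, iodine_conc = 25, salt_fraction = 0.5)
    ),
    discretionary = list(iodine_conc = 20,
                         added_amount = list(potatoes = 1),
                         use_share = list(potatoes = 0.5)),
    never_user_proportions = {
      b <- data.frame(age_low = rep(7L, 2), age_high = rep(69L, 2),
                      sex = c("male", "female"), stringsAsFactors = FALSE)
      b$proportion <- 0.3
      b
    }
  ))
}

# full-assignment helper: everyone a user, every flag on
full_assignment <- function(subjects, mgroups = c("bread", "pizza"),
                            dgroups = "potatoes") {
  ids <- subjects$subject_id
  du <- rep(TRUE, length(ids)); names(du) <- ids
  list(iteration = 1L, discretionary_user = du,
       adds_salt = matrix(TRUE, length(ids), length(dgroups),
                          dimnames = list(ids, dgroups)),
       iodised = matrix(TRUE, length(ids), length(mgroups),
                        dimnames = list(ids, mgroups)))
}

.fixture_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(name, maker) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, maker(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# n=2000 recovery-preset survey plus a one-part fit with lambda fixed at
# the generating value (variance components are only comparable on the
# generating scale). The preset has no sex differences, so the fit is
# pooled over sexes at the full n.
recovery_fixture <- function() {
  memoise_fixture("recovery", function() {
    dat <- simulate_survey(2000, gt_preset("recovery"), seed = 20260901)
    nat <- natural_iodine(dat$consumption, dat$composition, dat$subjects)
    fit <- hab_fit(nat, dat$subjects, lambda = 1, by_sex = FALSE)
    list(dat = dat, daily = nat, fit = fit)
  })
}

lognormal_fixture <- function() {
  memoise_fixture("lognormal", function() {
    dat <- simulate_survey(2000, gt_preset("lognormal"), seed = 20260902)
    nat <- natural_iodine(dat$consumption, dat$composition, dat$subjects)
    list(dat = dat, daily = nat,
         fit0 = hab_fit(nat, dat$subjects, lambda = 0),
         fit_free = hab_fit(nat, dat$subjects))
  })
}
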