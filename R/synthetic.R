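# Synthetic survey generator. Produces populations and 2-day recall
# datasets with known ground truth that match the statistical structure the
# estimation pipeline assumes: noise on a Box-Cox transformed scale with
# between- and within-person components, episodic food groups with true
# never-consumers, supplement use defined by recall and/or questionnaire,
# and age/sex-stratified never-discretionary-salt proportions.

DEFAULT_BANDS <- data.frame(
  age_low  = rep(c(7L, 9L, 14L, 19L, 31L, 51L), 2L),
  age_high = rep(c(8L, 13L, 18L, 30L, 50L, 69L), 2L),
  sex      = rep(c("male", "female"), each = 6L),
  stringsAsFactors = FALSE
)

#' Construct a ground-truth specification for the synthetic survey
#'
#' The ground truth fixes, for the natural-food iodine source, a Box-Cox
#' parameter `lambda`, a linear age trend on the transformed scale
#' (`age_coef` = intercept and slope), and between-/within-person standard
#' deviations on that scale: a person-day total is
#' `inv_boxcox(age_coef[1] + age_coef[2]*age + b_i + e_ij)` with
#' `b_i ~ N(0, sigma_b^2)`, `e_ij ~ N(0, sigma_w^2)`. The total is then
#' split over the natural food groups consumed that day in proportion to
#' their configured shares. Manufacturer-salt food groups (bread, pizza,
#' processed meat by default) get log-normal consumed amounts with their own
#' variance components, episodic consumption and true never-consumers.
#' Supplement users and never-discretionary-salt proportions are drawn per
#' the configured fractions.
#'
#' Defaults emulate a national food-consumption survey of ages 7-69 with
#' two non-consecutive recall days: a habitual natural-iodine intake around
#' 120-180 ug/d with within-person variation exceeding between-person
#' variation, bread as a near-universal staple, and roughly a third of
#' subjects with a known (questionnaire-year) discretionary-salt status.
#'
#' @param lambda Box-Cox parameter of the natural-iodine noise scale.
#' @param age_coef intercept and slope of the transformed-scale age trend.
#' @param sigma_b,sigma_w between- and within-person SDs (transformed scale).
#' @param natural_groups data frame: `group`, `food_code`, `iodine_nat`
#'   (ug/100 g), `share` (share of the day's natural iodine), `consume_prob`
#'   (daily consumption probability), `never_frac` (true never-consumers),
#'   `discretionary_eligible`.
#' @param manufacturer_groups data frame: `group`, `food_code`, `added_salt`
#'   (g/100 g), `consume_prob`, `never_frac`, `amount_meanlog`,
#'   `amount_sdlog_b`, `amount_sdlog_w` (log-scale amount model) and
#'   `amount_age_slope` (log-scale trend per year of age, centred at 38,
#'   so children consume smaller portions).
#' @param supplement list: `user_frac`, `doses` (ug), `dose_probs`,
#'   `report_prob` (probability a user's dose appears in a given recall).
#' @param never_user_proportions data frame (`age_low`, `age_high`, `sex`,
#'   `proportion`): true never-discretionary-salt fractions per stratum.
#' @param known_status_frac fraction of subjects with questionnaire-observed
#'   discretionary status.
#' @return an object of class `iod_ground_truth`.
#' @export
ground_truth <- function(lambda = 0,
                         age_coef = c(log(110), 0.004),
                         sigma_b = 0.25,
                         sigma_w = 0.35,
                         natural_groups = default_natural_groups(),
                         manufacturer_groups = default_manufacturer_groups(),
                         supplement = list(user_frac = 0.2,
                                           doses = c(50, 100, 150),
                                           dose_probs = c(0.4, 0.4, 0.2),
                                           report_prob = 0.7),
                         never_user_proportions = default_never_props(),
                         known_status_frac = 1 / 3) {
  gt <- list(lambda = lambda, age_coef = age_coef,
             sigma_b = sigma_b, sigma_w = sigma_w,
             natural_groups = natural_groups,
             manufacturer_groups = manufacturer_groups,
             supplement = supplement,
             never_user_proportions = never_user_proportions,
             known_status_frac = known_status_frac)
  class(gt) <- "iod_ground_truth"
  validate_ground_truth(gt)
  gt
}

validate_ground_truth <- function(gt) {
  if (gt$sigma_b < 0 || gt$sigma_w < 0) fail("ground truth: negative SD")
  ng <- gt$natural_groups
  probs <- c(ng$consume_prob, ng$never_frac,
             gt$manufacturer_groups$consume_prob,
             gt$manufacturer_groups$never_frac,
             gt$supplement$user_frac, gt$supplement$report_prob,
             gt$never_user_proportions$proportion)
  if (any(probs < 0 | probs > 1)) {
    fail("ground truth: probabilities must be in [0, 1]")
  }
  if (any(ng$share < 0) || sum(ng$share) <= 0) {
    fail("ground truth: natural shares must be nonnegative, not all zero")
  }
  invisible(gt)
}

default_natural_groups <- function() {
  data.frame(
    group = c("dairy", "cereals", "fish", "eggs", "vegetables", "potatoes"),
    food_code = c("F_DAIRY", "F_CEREAL", "F_FISH", "F_EGG", "F_VEG", "F_POT"),
    iodine_nat = c(16, 10, 60, 30, 3, 2),
    share = c(0.40, 0.25, 0.10, 0.10, 0.10, 0.05),
    consume_prob = c(1, 1, 0.25, 0.35, 0.9, 0.8),
    never_frac = c(0, 0, 0.10, 0.05, 0, 0),
    discretionary_eligible = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

default_manufacturer_groups <- function() {
  data.frame(
    group = c("bread", "pizza", "meat_products"),
    food_code = c("F_BREAD", "F_PIZZA", "F_MEATPR"),
    added_salt = c(1.25, 1.5, 2.0),
    consume_prob = c(0.95, 0.08, 0.6),
    never_frac = c(0.02, 0.30, 0.05),
    amount_meanlog = log(c(120, 250, 50)),
    amount_age_slope = c(0.012, 0.012, 0.012),
    amount_sdlog_b = c(0.30, 0.20, 0.30),
    amount_sdlog_w = c(0.40, 0.25, 0.45),
    stringsAsFactors = FALSE
  )
}

# Synthetic never-discretionary-salt proportions per age/sex band. These are
# illustrative survey-like values, not measured ones.
default_never_props <- function() {
  b <- DEFAULT_BANDS
  b$proportion <- rep(c(0.45, 0.40, 0.35, 0.25, 0.30, 0.35), 2L)
  b
}

#' Ground-truth presets for testing and demonstrations
#'
#' `"default"`: the full four-source configuration of [ground_truth()].
#' `"recovery"`: natural source only, untransformed scale (`lambda = 1`),
#' constant transformed-scale mean 150, `sigma_b = 20`, `sigma_w = 30`,
#' one always-consumed food group -- the habitual distribution is
#' Normal in closed form, so fitted parameters and percentiles can be
#' checked against analytic truth. `"lognormal"`: natural source only on
#' the log scale (`lambda = 0`, mean log(100), `sigma_b = 0.2`,
#' `sigma_w = 0.3`), log-normal closed forms.
#'
#' @param name preset name.
#' @return an `iod_ground_truth` object.
#' @export
gt_preset <- function(name = c("default", "recovery", "lognormal")) {
  name <- match.arg(name)
  if (name == "default") return(ground_truth())
  one_group <- data.frame(
    group = "staple", food_code = "F_STAPLE", iodine_nat = 20,
    share = 1, consume_prob = 1, never_frac = 0,
    discretionary_eligible = FALSE, stringsAsFactors = FALSE
  )
  no_manu <- default_manufacturer_groups()[0, ]
  no_suppl <- list(user_frac = 0, doses = 100, dose_probs = 1,
                   report_prob = 0)
  if (name == "recovery") {
    ground_truth(lambda = 1, age_coef = c(150, 0), sigma_b = 20,
                 sigma_w = 30, natural_groups = one_group,
                 manufacturer_groups = no_manu, supplement = no_suppl)
  } else {
    ground_truth(lambda = 0, age_coef = c(log(100), 0), sigma_b = 0.2,
                 sigma_w = 0.3, natural_groups = one_group,
                 manufacturer_groups = no_manu, supplement = no_suppl)
  }
}

#' Generate a stratified synthetic population
#'
#' Ages and sexes are drawn over the age-sex strata in proportion to
#' `strata_weights`; survey weights are set to the ratio of each stratum's
#' target population share (proportional to its width in years) to its
#' realised sample share, i.e. inverse sampling fractions.
#'
#' @param n number of subjects (>= 1).
#' @param strata_weights data frame `age_low`, `age_high`, `sex`, `weight`
#'   (nonnegative sampling weights, not all zero). Default: uniform over the
#'   survey reporting bands.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a validated subjects data frame (discretionary status `unknown`,
#'   no supplement use; those fields are filled by [generate_recalls()]).
#' @export
generate_population <- function(n, strata_weights = NULL, seed = 1L) {
  if (n < 1) fail("generate_population: n must be >= 1")
  if (is.null(strata_weights)) {
    strata_weights <- DEFAULT_BANDS
    strata_weights$weight <- 1
  }
  sw <- strata_weights
  if (any(sw$weight < 0) || sum(sw$weight) <= 0) {
    fail("generate_population: strata weights must be nonnegative, ",
         "not all zero")
  }
  with_seed(seed, {
    stratum <- sample.int(nrow(sw), n, replace = TRUE,
                          prob = sw$weight / sum(sw$weight))
    age <- sw$age_low[stratum] +
      floor(stats::runif(n) * (sw$age_high[stratum] - sw$age_low[stratum] + 1))
    width <- sw$age_high - sw$age_low + 1
    target_share <- width / sum(width)
    counts <- tabulate(stratum, nbins = nrow(sw))
    wt <- ifelse(counts > 0, target_share / (counts / n), 0)
    subjects <- data.frame(
      subject_id = sprintf("S%05d", seq_len(n)),
      age = as.integer(age),
      sex = sw$sex[stratum],
      survey_weight = wt[stratum],
      discretionary_status = "unknown",
      has_salt_questionnaire = FALSE,
      suppl_day1 = NA_real_,
      suppl_day2 = NA_real_,
      suppl_quest_user = FALSE,
      stringsAsFactors = FALSE
    )
    validate_subjects(subjects)
    subjects
  })
}

#' Generate 2-day recall data for a population
#'
#' For each subject, two recall days are generated. The natural-iodine
#' person-day total is `inv_boxcox(f(age) + b_i + e_ij)` on the ground
#' truth's transformed scale and is split over the natural food groups the
#' subject consumes that day (episodic groups consumed with their configured
#' probability; true never-consumers never consume). Manufacturer-salt food
#' groups get log-normal amounts. Discretionary-salt status and supplement
#' use are drawn per the ground truth. The returned composition table is
#' consistent with the generated intakes.
#'
#' @param population subjects data frame from [generate_population()].
#' @param gt ground truth from [ground_truth()].
#' @param seed integer seed.
#' @return list with `subjects` (population with discretionary and
#'   supplement fields filled), `consumption` and `composition`.
#' @export
generate_recalls <- function(population, gt, seed = 1L) {
  validate_ground_truth(gt)
  n <- nrow(population)
  with_seed(seed, {
    subjects <- population
    age <- subjects$age

    ## --- natural source -------------------------------------------------
    f_age <- gt$age_coef[1] + gt$age_coef[2] * age
    b <- stats::rnorm(n, 0, gt$sigma_b)
    recs <- vector("list", 2L * n * (nrow(gt$natural_groups) +
                                       nrow(gt$manufacturer_groups)))
    k <- 0L
    ng <- gt$natural_groups
    never_nat <- matrix(FALSE, n, nrow(ng))
    for (g in seq_len(nrow(ng))) {
      never_nat[, g] <- stats::runif(n) < ng$never_frac[g]
    }
    e <- matrix(stats::rnorm(2L * n, 0, gt$sigma_w), n, 2L)
    for (day in 1:2) {
      total <- inv_box_cox(f_age + b + e[, day], gt$lambda)
      consumed <- matrix(FALSE, n, nrow(ng))
      for (g in seq_len(nrow(ng))) {
        consumed[, g] <- !never_nat[, g] &
          stats::runif(n) < ng$consume_prob[g]
      }
      share_sum <- as.numeric(consumed %*% ng$share)
      for (g in seq_len(nrow(ng))) {
        sel <- consumed[, g] & share_sum > 0
        if (!any(sel)) next
        intake <- total[sel] * ng$share[g] / share_sum[sel]
        k <- k + 1L
        recs[[k]] <- data.frame(
          subject_id = subjects$subject_id[sel], day = day,
          food_code = ng$food_code[g], food_group = ng$group[g],
          amount = intake / (ng$iodine_nat[g] / 100),
          stringsAsFactors = FALSE
        )
      }
    }

    ## --- manufacturer-salt food groups ---------------------------------
    mg <- gt$manufacturer_groups
    for (g in seq_len(nrow(mg))) {
      never <- stats::runif(n) < mg$never_frac[g]
      bm <- stats::rnorm(n, 0, mg$amount_sdlog_b[g])
      for (day in 1:2) {
        sel <- !never & stats::runif(n) < mg$consume_prob[g]
        if (!any(sel)) next
        amt <- exp(mg$amount_meanlog[g] +
                     mg$amount_age_slope[g] * (age[sel] - 38) + bm[sel] +
                     stats::rnorm(sum(sel), 0, mg$amount_sdlog_w[g]))
        k <- k + 1L
        recs[[k]] <- data.frame(
          subject_id = subjects$subject_id[sel], day = day,
          food_code = mg$food_code[g], food_group = mg$group[g],
          amount = amt, stringsAsFactors = FALSE
        )
      }
    }
    consumption <- do.call(rbind, recs[seq_len(k)])
    if (is.null(consumption)) {
      consumption <- data.frame(subject_id = character(), day = integer(),
                                food_code = character(),
                                food_group = character(),
                                amount = numeric(),
                                stringsAsFactors = FALSE)
    }

    ## --- discretionary-salt status --------------------------------------
    nup <- gt$never_user_proportions
    band <- band_index(nup, subjects$age, subjects$sex)
    true_never <- stats::runif(n) < nup$proportion[band]
    known <- stats::runif(n) < gt$known_status_frac
    subjects$has_salt_questionnaire <- known
    subjects$discretionary_status <-
      ifelse(known, ifelse(true_never, "never_adds_salt", "adds_salt"),
             "unknown")

    ## --- supplements -----------------------------------------------------
    sp <- gt$supplement
    user <- stats::runif(n) < sp$user_frac
    dose <- rep(NA_real_, n)
    if (any(user)) {
      dose[user] <- sample(sp$doses, sum(user), replace = TRUE,
                           prob = sp$dose_probs)
    }
    rep1 <- user & stats::runif(n) < sp$report_prob
    rep2 <- user & stats::runif(n) < sp$report_prob
    subjects$suppl_day1 <- ifelse(rep1, dose, NA_real_)
    subjects$suppl_day2 <- ifelse(rep2, dose, NA_real_)
    subjects$suppl_quest_user <- user

    composition <- data.frame(
      food_code = ng$food_code, iodine_nat = ng$iodine_nat,
      added_salt = 0, manufacturer_group = NA_character_,
      discretionary_eligible = ng$discretionary_eligible,
      produced_with_salt = FALSE, stringsAsFactors = FALSE)
    if (nrow(mg)) {
      composition <- rbind(
        composition,
        data.frame(food_code = mg$food_code, iodine_nat = 0,
                   added_salt = mg$added_salt, manufacturer_group = mg$group,
                   discretionary_eligible = FALSE, produced_with_salt = TRUE,
                   stringsAsFactors = FALSE))
    }
    validate_subjects(subjects)
    validate_consumption(consumption, subjects)
    validate_composition(composition)
    list(subjects = subjects, consumption = consumption,
         composition = composition)
  })
}

#' Salt policy matching a ground truth
#'
#' Returns a salt-policy configuration whose never-user proportions equal
#' the ground truth's and whose manufacturer market shares and
#' concentrations follow the default national-policy assumptions: 95% of
#' bread iodised at 58 mg I/kg bakery salt, a 40% pizza market share with
#' half of pizza salt attributable to added iodised salt, a 0.5% share for
#' processed meat, and 20 mg I/kg low-iodine salt elsewhere, including
#' discretionary salt.
#'
#' @param gt ground truth.
#' @return validated policy list.
#' @export
gt_policy <- function(gt) {
  manu_defaults <- list(
    bread = list(market_share = 0.95, iodine_conc = 58, salt_fraction = 1),
    pizza = list(market_share = 0.40, iodine_conc = 20, salt_fraction = 0.5),
    meat_products = list(market_share = 0.005, iodine_conc = 20,
                         salt_fraction = 1)
  )
  manu <- manu_defaults[intersect(names(manu_defaults),
                                  gt$manufacturer_groups$group)]
  extra <- setdiff(gt$manufacturer_groups$group, names(manu_defaults))
  for (g in extra) {
    manu[[g]] <- list(market_share = 0.5, iodine_conc = 20,
                      salt_fraction = 1)
  }
  eligible <- gt$natural_groups$group[gt$natural_groups$discretionary_eligible]
  added <- as.list(rep(0.7, length(eligible)))
  use <- as.list(rep(0.5, length(eligible)))
  names(added) <- names(use) <- eligible
  if (!length(eligible)) {
    # keep the policy schema valid even for natural-only ground truths
    added <- list(none = 0)
    use <- list(none = 0)
  }
  pol <- list(
    manufacturer = manu,
    discretionary = list(iodine_conc = 20, added_amount = added,
                         use_share = use),
    never_user_proportions = gt$never_user_proportions
  )
  validate_policy(pol)
  pol
}

#' Illustrative DRI table
#'
#' Approximate iodine reference values by age band (EAR in the style of the
#' IOM values, UL in the style of the SCF values), shipped as an
#' illustrative default; analyses of real data should supply their own
#' configuration via [read_dri()].
#'
#' @return validated DRI data frame.
#' @export
default_dri <- function() {
  dri <- data.frame(
    age_low  = rep(c(7L, 9L, 14L, 19L), 2L),
    age_high = rep(c(8L, 13L, 18L, 69L), 2L),
    sex      = rep(c("male", "female"), each = 4L),
    ear      = rep(c(65, 73, 95, 95), 2L),
    ul       = rep(c(300, 450, 500, 600), 2L),
    stringsAsFactors = FALSE
  )
  validate_dri(dri)
  dri
}

#' Generate a complete synthetic survey
#'
#' Convenience wrapper: population + recalls + matching policy and DRI.
#'
#' @param n number of subjects.
#' @param gt ground truth (default [gt_preset()] `"default"`).
#' @param seed integer seed.
#' @return list with `subjects`, `consumption`, `composition`, `policy`,
#'   `dri` and `ground_truth`.
#' @export
simulate_survey <- function(n, gt = gt_preset("default"), seed = 1L) {
  pop <- generate_population(n, seed = seed)
  dat <- generate_recalls(pop, gt, seed = seed + 1L)
  dat$policy <- gt_policy(gt)
  dat$dri <- default_dri()
  dat$ground_truth <- gt
  dat
}

#' Analytic prevalence below a threshold under the ground truth
#'
#' For natural-only ground truths with a constant age trend, the habitual
#' natural-iodine intake has a closed form: `inv_boxcox(f + b)` for
#' `lambda = 1` (Normal) and `exp(f + b) * exp(sigma_w^2 / 2)` for
#' `lambda = 0` (log-Normal; the within-day noise shifts the mean on the
#' original scale). This returns the analytic P(habitual < threshold) used
#' as the recovery target in tests.
#'
#' @param gt ground truth with `age_coef[2] == 0` and `lambda` 0 or 1.
#' @param threshold intake threshold in ug/d (e.g. an EAR).
#' @return probability in \[0, 1\].
#' @export
true_prevalence_below <- function(gt, threshold) {
  if (gt$age_coef[2] != 0) {
    fail("true_prevalence_below: closed form requires a constant age trend")
  }
  f <- gt$age_coef[1]
  if (abs(gt$lambda - 1) < 1e-8) {
    # habitual = f + 1 + b (Box-Cox offset), b ~ N(0, sigma_b^2)
    if (gt$sigma_b == 0) return(as.numeric(threshold > f + 1))
    stats::pnorm(threshold, mean = f + 1, sd = gt$sigma_b)
  } else if (abs(gt$lambda) < 1e-8) {
    m <- f + gt$sigma_w^2 / 2
    if (threshold <= 0) return(0)
    if (gt$sigma_b == 0) return(as.numeric(threshold > exp(m)))
    stats::plnorm(threshold, meanlog = m, sdlog = gt$sigma_b)
  } else {
    fail("true_prevalence_below: closed form implemented for lambda 0 or 1")
  }
}

#' Analytic habitual percentiles under the ground truth
#'
#' Companion to [true_prevalence_below()]: quantiles of the closed-form
#' habitual distribution for natural-only ground truths.
#'
#' @param gt ground truth with constant age trend, `lambda` 0 or 1.
#' @param probs probabilities in (0, 1).
#' @return numeric vector of quantiles (ug/d).
#' @export
true_habitual_quantiles <- function(gt, probs) {
  if (gt$age_coef[2] != 0) {
    fail("true_habitual_quantiles: closed form requires a constant age trend")
  }
  f <- gt$age_coef[1]
  if (abs(gt$lambda - 1) < 1e-8) {
    stats::qnorm(probs, mean = f + 1, sd = gt$sigma_b)
  } else if (abs(gt$lambda) < 1e-8) {
    stats::qlnorm(probs, meanlog = f + gt$sigma_w^2 / 2, sdlog = gt$sigma_b)
  } else {
    fail("true_habitual_quantiles: closed form implemented for lambda 0 or 1")
  }
}
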