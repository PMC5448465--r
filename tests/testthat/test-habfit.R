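# One-part habitual-intake model: degenerate cases, closed-form oracles,
# parameter recovery against the generator, and cross-checks against
# independent implementations (lme4 REML, MASS box-cox).

two_day_data <- function(intakes_by_subject) {
  n <- nrow(intakes_by_subject)
  data.frame(subject_id = rep(sprintf("T%03d", seq_len(n)), each = 2),
             day = rep(1:2, n),
             intake = as.numeric(t(intakes_by_subject)),
             stringsAsFactors = FALSE)
}

test_that("a constant dataset collapses to zero variance components", {
  s <- make_subjects(6)
  d <- two_day_data(matrix(100, 6, 2))
  fit <- hab_fit(d, s)
  co <- coef(fit)
  expect_equal(unname(co[1, "sigma_b"]), 0)
  expect_equal(unname(co[1, "sigma_w"]), 0)
  expect_equal(habitual(fit)$habitual, rep(100, 6), tolerance = 1e-8)
})

test_that("subjects must have exactly two recall days unless relaxed", {
  s <- make_subjects(3)
  d <- two_day_data(matrix(c(90, 110, 95, 105, 100, 100), 3, 2,
                           byrow = TRUE))
  expect_silent(fit <- hab_fit(d, s, lambda = 1))
  expect_error(hab_fit(d[-1, ], s), "exactly 2 recall days")
  expect_silent(hab_fit(d[-1, ], s, require_two_days = FALSE))
  # within-person variance needs at least one subject with both days
  d1 <- d[d$day == 1, ]
  expect_error(hab_fit(d1, s, require_two_days = FALSE),
               "not identifiable")
})

test_that("variance components match lme4 REML on equal-weight data", {
  skip_if_not_installed("lme4")
  set.seed(404)
  n <- 300
  b <- rnorm(n, 0, 15)
  y <- 150 + rep(b, each = 2) + rnorm(2 * n, 0, 25)
  d <- two_day_data(matrix(y, n, 2, byrow = TRUE))
  s <- make_subjects(n)   # constant age -> intercept-only design
  fit <- hab_fit(d, s, lambda = 1)
  ml <- lme4::lmer((intake - 1) ~ 1 + (1 | subject_id), data = d,
                   REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(ml))
  expect_equal(fit$fits[[1]]$sigma2_b, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$fits[[1]]$sigma2_w, vc$vcov[2], tolerance = 1e-4)
})

test_that("profile Box-Cox agrees with the MASS profile on pooled data", {
  skip_if_not_installed("MASS")
  fx <- lognormal_fixture()
  d <- merge(fx$daily, fx$dat$subjects[, c("subject_id", "age")])
  prof <- MASS::boxcox(intake ~ age, data = d,
                       lambda = seq(-0.5, 1, 0.01), plotit = FALSE)
  lam_mass <- prof$x[which.max(prof$y)]
  lam_fit <- coef(fx$fit_free)[, "lambda"]
  expect_true(all(abs(lam_fit - lam_mass) < 0.1))
})

test_that("the estimated transformation recovers lambda = 0 within 0.15", {
  fx <- lognormal_fixture()
  expect_true(all(abs(coef(fx$fit_free)[, "lambda"]) < 0.15))
})

test_that("log-scale fits match the log-normal closed form to 1e-6", {
  fx <- lognormal_fixture()
  fit <- fx$fit0
  for (g in names(fit$fits)) {
    f <- fit$fits[[g]]
    closed <- exp(f$subjects$mu) * exp(f$sigma2_w / 2)
    expect_equal(f$subjects$habitual, pmax(closed - f$shift, 0),
                 tolerance = 1e-6)
  }
})

test_that("with zero within-person variance the habitual equals the
           back-transformed two-day mean", {
  gt <- gt_preset("lognormal"); gt$sigma_w <- 0
  dat <- simulate_survey(80, gt, seed = 5)
  nat <- natural_iodine(dat$consumption, dat$composition, dat$subjects)
  fit <- hab_fit(nat, dat$subjects, lambda = 0)
  zbar <- tapply(log(nat$intake), nat$subject_id, mean)
  h <- habitual(fit)
  # sigma_w is estimated, so it is near zero rather than exactly zero
  expect_equal(h$habitual, as.numeric(exp(zbar[h$subject_id])),
               tolerance = 1e-3)
})

test_that("the linear case preserves the weighted mean and shrinks the
           variance of person values", {
  fx <- recovery_fixture()
  h <- habitual(fx$fit)
  daily <- fx$daily
  w_obs <- fx$dat$subjects$survey_weight[
    match(daily$subject_id, fx$dat$subjects$subject_id)]
  expect_equal(mean(h),
               sum(daily$intake * w_obs) / sum(w_obs),
               tolerance = 1e-9)
  two_day_means <- tapply(daily$intake, daily$subject_id, mean)
  expect_lt(var(h$habitual), var(as.numeric(two_day_means)))
})

test_that("shrinkage holds across generated datasets whenever sigma_w > 0", {
  for (seed in c(11, 12, 13)) {
    dat <- simulate_survey(150, gt_preset("default"), seed = seed)
    nat <- natural_iodine(dat$consumption, dat$composition, dat$subjects)
    fit <- hab_fit(nat, dat$subjects)
    means <- tapply(nat$intake, nat$subject_id, mean)
    expect_lt(var(habitual(fit)$habitual), var(as.numeric(means)))
  }
})

test_that("weighted quantiles invert the weighted ECDF (brute force)", {
  set.seed(21)
  x <- rnorm(50)
  w <- runif(50, 0.2, 3)
  d <- intake_dist(data.frame(habitual = x, weight = w))
  probs <- c(0.05, 0.25, 0.5, 0.9)
  brute <- sapply(probs, function(p) {
    ord <- order(x)
    cw <- cumsum(w[ord]) / sum(w)
    x[ord][min(which(cw >= p))]
  })
  expect_equal(unname(quantile(d, probs)), brute)
  expect_equal(unname(quantile(intake_dist(
    data.frame(habitual = rep(100, 4), weight = 1)), probs)), rep(100, 4))
  expect_equal(unname(quantile(intake_dist(
    data.frame(habitual = 1:99, weight = 1)), 0.5)), 50)
  # monotone in p
  q <- quantile(d, seq(0.05, 0.95, 0.05))
  expect_true(all(diff(q) >= 0))
})

test_that("Gauss-Hermite rule matches an independent implementation", {
  skip_if_not_installed("pracma")
  gh <- iodintake:::gauss_hermite(15)
  ref <- pracma::gaussHermite(15)
  expect_equal(gh$nodes, ref$x, tolerance = 1e-10)
  expect_equal(gh$weights, ref$w, tolerance = 1e-10)
  # E[exp(Z)] for Z ~ N(0, s2) is exp(s2/2)
  expect_equal(iodintake:::gh_expect(exp, 0, 0.25), exp(0.125),
               tolerance = 1e-8)
})

test_that("model methods behave: predict, residuals, simulate", {
  fx <- lognormal_fixture()
  fit <- fx$fit0
  nd <- data.frame(age = c(10, 40), sex = c("male", "female"))
  mu <- predict(fit, nd, type = "mean")
  expect_true(all(is.finite(mu) & mu > 0))
  r <- residuals(fit)
  expect_equal(length(r), 2000L)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(length(sims), 2L)
  expect_equal(nrow(sims[[1]]), 2L * 2000L)
  expect_true(all(sims[[1]]$intake >= 0))
  # simulated data refit close to the generating fit (round trip)
  refit <- hab_fit(sims[[1]], fx$dat$subjects, lambda = 0)
  expect_equal(coef(refit)[, "sigma_w"], coef(fit)[, "sigma_w"],
               tolerance = 0.15)
})
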