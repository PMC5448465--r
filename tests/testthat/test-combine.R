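# Monte Carlo combination, prevalence queries, source shares and ensemble
# summaries.

adult_strata <- function() {
  data.frame(age_low = rep(19L, 2), age_high = rep(69L, 2),
             sex = c("male", "female"), stringsAsFactors = FALSE)
}

point_dist <- function(value, n = 20, sex = "female") {
  intake_dist(data.frame(subject_id = sprintf("%s%03d", sex, 1:n),
                         age = 30L, sex = sex, habitual = value,
                         weight = 1, stringsAsFactors = FALSE))
}

test_that("point-mass sources sum exactly and zero sources drop out", {
  dists <- lapply(c(60, 80, 20, 5), point_dist)
  tot <- combine_sources(dists, adult_strata(), mc_size = 500, seed = 1)
  expect_equal(tot$habitual, rep(165, 500))

  with_zero <- lapply(c(60, 80, 0, 5), point_dist)
  tot0 <- combine_sources(with_zero, adult_strata(), mc_size = 200,
                          seed = 2, by_person = TRUE)
  three <- combine_sources(lapply(c(60, 80, 5), point_dist),
                           adult_strata(), mc_size = 200, seed = 2,
                           by_person = TRUE)
  expect_equal(tot0$habitual, three$habitual)
})

test_that("combination is deterministic and validates its inputs", {
  d <- point_dist(10)
  expect_identical(combine_sources(list(d, d), adult_strata(), 100, seed = 9),
                   combine_sources(list(d, d), adult_strata(), 100, seed = 9))
  empty_cover <- point_dist(10, sex = "male")
  expect_error(combine_sources(list(d, empty_cover), adult_strata(), 100),
               "no individuals in")
})

test_that("prevalence implements the EAR cut-point method", {
  set.seed(7)
  d <- intake_dist(data.frame(habitual = rnorm(1e5, 150, 30), weight = 1))
  pr <- prevalence(d, ear = 95, ul = 600)
  expect_equal(unname(pr["below_ear"]), pnorm((95 - 150) / 30),
               tolerance = 0.1)
  # partition: below + between + above = 1 exactly
  between <- weighted.mean(d$habitual >= 95 & d$habitual <= 600, d$weight)
  expect_equal(unname(pr["below_ear"]) + between + unname(pr["above_ul"]),
               1, tolerance = 1e-12)

  all_between <- intake_dist(data.frame(habitual = runif(100, 200, 300),
                                        weight = 1))
  expect_equal(unname(prevalence(all_between, 95, 600)), c(0, 0))
  all_above <- intake_dist(data.frame(habitual = rep(700, 10), weight = 1))
  expect_equal(unname(prevalence(all_above, 599.9, 600)), c(0, 1))
})

test_that("prevalence falls under any upward location shift", {
  set.seed(8)
  base <- rnorm(5000, 120, 25)
  w <- runif(5000, 0.5, 2)
  p0 <- prevalence(intake_dist(data.frame(habitual = base, weight = w)), 95)
  for (shift in c(5, 20, 60)) {
    p1 <- prevalence(intake_dist(data.frame(habitual = base + shift,
                                            weight = w)), 95)
    expect_lte(p1[["below_ear"]], p0[["below_ear"]])
  }
})

test_that("source shares report weighted mean fractions that sum to one", {
  mk <- function(v) point_dist(v, n = 10)
  sh <- source_shares(list(natural = mk(40), manufacturer = mk(43),
                           discretionary = mk(14), supplement = mk(3)))
  expect_equal(sh$mean_share, c(0.40, 0.43, 0.14, 0.03))
  expect_equal(sh$sd_share, rep(0, 4))
  expect_equal(sum(sh$mean_share), 1)

  single <- source_shares(list(only = mk(50), zero = mk(0)))
  expect_equal(single$mean_share, c(1, 0))

  # two individuals with different shares, equal weights -> arithmetic mean
  d1 <- intake_dist(data.frame(subject_id = c("a", "b"), age = 30L,
                               sex = "female", habitual = c(30, 10),
                               weight = 1))
  d2 <- intake_dist(data.frame(subject_id = c("a", "b"), age = 30L,
                               sex = "female", habitual = c(10, 30),
                               weight = 1))
  sh2 <- source_shares(list(x = d1, y = d2))
  expect_equal(sh2$mean_share, c(0.5, 0.5))

  # zero totals excluded with a warning
  dz <- intake_dist(data.frame(subject_id = c("a", "b"), age = 30L,
                               sex = "female", habitual = c(0, 10),
                               weight = 1))
  z2 <- intake_dist(data.frame(subject_id = c("a", "b"), age = 30L,
                               sex = "female", habitual = 0, weight = 1))
  expect_warning(shz <- source_shares(list(x = dz, y = z2)), "excluded")
  expect_equal(attr(shz, "n_excluded"), 1L)
})

test_that("ensemble summaries behave at the edges and bracket the median", {
  one <- list(data.frame(band = "a", p50 = 2.5, below_ear = 0.1))
  s1 <- summarise_ensemble(one)
  expect_equal(s1$median, c(2.5, 0.1))
  expect_equal(s1$sd, c(0, 0))

  same <- rep(list(data.frame(band = "a", p50 = 2.5)), 10)
  expect_equal(summarise_ensemble(same)$sd, 0)

  set.seed(3)
  varied <- lapply(1:20, function(i) data.frame(band = "a",
                                                p50 = rnorm(1, 10)))
  sv <- summarise_ensemble(varied)
  expect_gte(sv$median, sv$min)
  expect_lte(sv$median, sv$max)
  expect_gt(sv$sd, 0)
})

test_that("raising a market share raises the combined distribution at
           every percentile (same seeds)", {
  dat <- simulate_survey(150, seed = 23)
  run_share <- function(share) {
    pol <- dat$policy
    pol$manufacturer$bread$market_share <- share
    asg <- build_ensemble(dat$subjects, dat$consumption, pol, 1,
                          seed = 5)[[1]]
    md <- manufacturer_iodine(dat$consumption, dat$composition, pol,
                              dat$subjects, asg)
    habitual(hab_fit2(md, dat$subjects, lambda = 0))
  }
  lo <- run_share(0.5)
  hi <- run_share(1.0)
  nat <- habitual(hab_fit(natural_iodine(dat$consumption, dat$composition,
                                         dat$subjects),
                          dat$subjects, lambda = 0))
  probs <- seq(0.1, 0.9, 0.1)
  tot_lo <- combine_sources(list(nat, lo), default_dri(), 2e4, seed = 31)
  tot_hi <- combine_sources(list(nat, hi), default_dri(), 2e4, seed = 31)
  expect_true(all(quantile(tot_hi, probs) >= quantile(tot_lo, probs)))
})

test_that("per-band evaluation partitions prevalence and flags empty
           bands", {
  dat <- simulate_survey(250, seed = 41)
  nat <- habitual(hab_fit(natural_iodine(dat$consumption, dat$composition,
                                         dat$subjects), dat$subjects))
  ev <- evaluate_bands(nat, dat$dri)
  expect_equal(nrow(ev), nrow(dat$dri))
  expect_true(all(ev$below_ear >= 0 & ev$above_ul >= 0 &
                    ev$below_ear + ev$above_ul <= 1))
  expect_true(all(ev$p5 <= ev$p50 & ev$p50 <= ev$p95))
  young_only <- nat[nat$age < 15, ]
  expect_error(evaluate_bands(intake_dist(young_only), dat$dri),
               "no individuals in band")
})
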