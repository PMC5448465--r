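# Tabulation: forced arithmetic on the unit convention, source exclusion
# rules, additivity and linearity.

test_that("natural iodine sums amount x concentration/100 and excludes
           manufacturer-group foods", {
  s <- make_subjects(1)
  comp <- tiny_composition()
  r <- data.frame(subject_id = "T001", day = 1L, food_code = "MILK",
                  food_group = "dairy", amount = 200)
  out <- natural_iodine(r, comp, s)
  expect_equal(out$intake[out$day == 1], 32)   # 200 g x 16 ug/100 g
  expect_equal(out$intake[out$day == 2], 0)    # recordless day is 0

  r_bread <- data.frame(subject_id = "T001", day = 1L, food_code = "BREAD",
                        food_group = "bread", amount = 100)
  out <- natural_iodine(r_bread, comp, s)
  expect_equal(out$intake, c(0, 0))  # bread counted under manufacturer salt

  r_bad <- transform(r, food_code = "NOPE")
  expect_error(natural_iodine(r_bad, comp, s), "NOPE")
})

test_that("manufacturer salt follows the g x mg/kg = ug identity and the
           assignment", {
  s <- make_subjects(1)
  comp <- tiny_composition()
  pol <- tiny_policy()
  r <- data.frame(subject_id = "T001", day = 1L, food_code = "BREAD",
                  food_group = "bread", amount = 120)
  asg <- full_assignment(s)
  out <- manufacturer_iodine(r, comp, pol, s, asg)
  expect_equal(out$intake[out$day == 1], 120 * 1.25 / 100 * 58)  # 87 ug

  # not assigned -> zero
  asg0 <- asg; asg0$iodised[] <- FALSE
  out0 <- manufacturer_iodine(r, comp, pol, s, asg0)
  expect_equal(out0$intake, c(0, 0))

  # pizza: half the salt attributable to added iodised salt
  rp <- data.frame(subject_id = "T001", day = 2L, food_code = "PIZZA",
                   food_group = "pizza", amount = 200)
  outp <- manufacturer_iodine(rp, comp, pol, s, asg)
  expect_equal(outp$intake[outp$day == 2], 200 * 1.5 / 100 * 0.5 * 25) # 37.5

  pol_missing <- pol; pol_missing$manufacturer$bread <- NULL
  expect_error(manufacturer_iodine(r, comp, pol_missing, s, asg),
               "no policy entry.*bread")
})

test_that("discretionary salt respects user status, eligibility and the
           produced-with-salt exclusion", {
  s <- make_subjects(2, status = c("adds_salt", "never_adds_salt"))
  comp <- tiny_composition()
  pol <- tiny_policy()
  r <- data.frame(subject_id = c("T001", "T002"), day = 1L,
                  food_code = "POTATO", food_group = "potatoes",
                  amount = 300)
  asg <- full_assignment(s)
  out <- discretionary_iodine(r, comp, pol, s, asg)
  # 300 g x 1 g salt/100 g x 20 mg/kg = 60 ug
  expect_equal(out$intake[out$subject_id == "T001" & out$day == 1], 60)
  # a questionnaire-confirmed never-user contributes 0 regardless of flags
  expect_equal(out$intake[out$subject_id == "T002"], c(0, 0))

  # group consumed but not drawn for this subject -> 0
  asg_nd <- asg; asg_nd$adds_salt[] <- FALSE
  out_nd <- discretionary_iodine(r, comp, pol, s, asg_nd)
  expect_true(all(out_nd$intake == 0))

  # foods produced with salt are never eligible
  r_ham <- data.frame(subject_id = "T001", day = 1L, food_code = "PIZZA",
                      food_group = "pizza", amount = 300)
  out_ham <- discretionary_iodine(r_ham, comp, pol, s, asg)
  expect_true(all(out_ham$intake == 0))
})

test_that("supplement rows echo per-day reported doses", {
  s <- make_subjects(3)
  s$suppl_day1 <- c(150, NA, 100)
  s$suppl_day2 <- c(NA, NA, 200)
  out <- supplement_daily(s)
  get <- function(id, day) out$intake[out$subject_id == id & out$day == day]
  expect_equal(c(get("T001", 1), get("T001", 2)), c(150, 0))
  expect_equal(c(get("T002", 1), get("T002", 2)), c(0, 0))
  expect_equal(c(get("T003", 1), get("T003", 2)), c(100, 200))
  s$suppl_day1[1] <- -5
  expect_error(supplement_daily(s), "negative")
})

test_that("total daily intake is exactly additive over the four sources
           and linear in amounts", {
  dat <- simulate_survey(60, seed = 17)
  asg <- build_ensemble(dat$subjects, dat$consumption, dat$policy, 1,
                        seed = 2)[[1]]
  all4 <- tabulate_sources(dat$consumption, dat$composition, dat$policy,
                           dat$subjects, asg)
  # every source emits the same subject-day grid in the same order
  by_src <- split(all4, all4$source)
  grids <- lapply(by_src, function(d) paste(d$subject_id, d$day))
  for (g in grids[-1]) expect_identical(g, grids[[1]])
  total <- Reduce(`+`, lapply(by_src, `[[`, "intake"))
  per_day <- tapply(all4$intake, paste(all4$subject_id, all4$day), sum)
  expect_equal(total, as.numeric(per_day[grids[[1]]]),
               tolerance = 1e-12)

  dbl <- dat$consumption; dbl$amount <- 2 * dbl$amount
  for (f in list(natural_iodine)) {
    expect_equal(f(dbl, dat$composition, dat$subjects)$intake,
                 2 * f(dat$consumption, dat$composition,
                       dat$subjects)$intake)
  }
  expect_equal(
    manufacturer_iodine(dbl, dat$composition, dat$policy, dat$subjects,
                        asg)$intake,
    2 * manufacturer_iodine(dat$consumption, dat$composition, dat$policy,
                            dat$subjects, asg)$intake)
  expect_equal(
    discretionary_iodine(dbl, dat$composition, dat$policy, dat$subjects,
                         asg)$intake,
    2 * discretionary_iodine(dat$consumption, dat$composition, dat$policy,
                             dat$subjects, asg)$intake)
})

test_that("group contributions are weighted means of per-subject shares
           and sum to one", {
  s <- make_subjects(1)
  comp <- tiny_composition()
  r <- data.frame(subject_id = "T001", day = c(1L, 1L), food_code = "MILK",
                  food_group = "dairy", amount = c(100, 100))
  expect_equal(unname(group_contributions(r, comp, s)), 1)

  # two groups at 30 and 10 ug for every subject -> 75% / 25%
  s2 <- make_subjects(2)
  r2 <- rbind(
    data.frame(subject_id = rep(c("T001", "T002"), each = 2),
               day = rep(1:2, 2), food_code = "MILK", food_group = "dairy",
               amount = 30 / 16 * 100),
    data.frame(subject_id = rep(c("T001", "T002"), each = 2),
               day = rep(1:2, 2), food_code = "POTATO",
               food_group = "potatoes", amount = 10 / 2 * 100)
  )
  gc2 <- group_contributions(r2, comp, s2)
  expect_equal(unname(gc2[c("dairy", "potatoes")]), c(0.75, 0.25))

  # hand-computed weighted mean on 3 subjects with unequal weights
  s3 <- make_subjects(3, weight = c(1, 2, 3))
  shares <- rbind(c(0.5, 0.5), c(0.8, 0.2), c(0.2, 0.8))
  r3 <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(subject_id = s3$subject_id[i], day = 1L,
               food_code = c("MILK", "POTATO"),
               food_group = c("dairy", "potatoes"),
               amount = c(shares[i, 1] * 100 / 16 * 100,
                          shares[i, 2] * 100 / 2 * 100))
  }))
  gc3 <- group_contributions(r3, comp, s3)
  oracle <- colSums(shares * c(1, 2, 3)) / 6
  expect_equal(unname(gc3[c("dairy", "potatoes")]), unname(oracle))
  expect_equal(sum(gc3), 1, tolerance = 1e-9)

  # all-zero natural intake is an error
  r0 <- data.frame(subject_id = "T001", day = 1L, food_code = "POTATO",
                   food_group = "potatoes", amount = 0)
  expect_error(group_contributions(r0, comp, s), "positive natural intake")
})
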