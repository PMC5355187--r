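test_that("credit estimation is the flora-reference intersection", {
  est <- estimate_credit(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(est$credit0, 2L)
  expect_setequal(est$eligible, c("b", "c"))

  expect_warning(est0 <- estimate_credit(c("A", "B"), c("X", "Y")),
                 "share no species")
  expect_equal(est0$credit0, 0L)

  expect_error(estimate_credit(character(0), c("A")), "flora list is empty")
})

test_that("flag counting respects the eligible set and the flora schema", {
  flora <- ecocredit:::new_flora_list(
    data.frame(species_id = c("a", "b", "c")),
    flags = list(large_seeded_reliant = c(FALSE, TRUE, FALSE))
  )
  expect_equal(count_flagged(c("b", "c"), flora), 1L)
  expect_equal(count_flagged(c("a", "c"), flora), 0L)
  expect_error(count_flagged(c("a"), flora, flag = "nope"), "unknown flag")
})

test_that("accumulation counts each species once, at its first observation", {
  log <- data.frame(time_months = c(3.7, 1.2), plant_id = c("x", "x"))
  cv <- accumulation_curve(log, eligible = c("x", "y"), horizon = 5)
  expect_equal(cv$cumulative, c(0, 1, 1, 1, 1))  # 1 from the bin holding 1.2
  expect_equal(cv$first_observation$first_time, 1.2)

  empty <- data.frame(time_months = numeric(0), plant_id = character(0))
  cv0 <- accumulation_curve(empty, eligible = "x", horizon = 3)
  expect_equal(cv0$cumulative, c(0, 0, 0))
  expect_error(accumulation_curve(empty, eligible = "x"), "horizon is required")

  bad <- data.frame(time_months = c(-1, 2), plant_id = c("x", "y"))
  expect_error(accumulation_curve(bad, "x", horizon = 3), "non-negative")
})

test_that("the curve is invariant to event-record order", {
  set.seed(7)
  log <- data.frame(
    time_months = runif(40, 0, 12),
    plant_id = sample(letters[1:8], 40, replace = TRUE)
  )
  eligible <- letters[1:5]
  cv1 <- accumulation_curve(log, eligible, horizon = 12)
  cv2 <- accumulation_curve(log[sample(40), ], eligible, horizon = 12)
  expect_equal(cv1$cumulative, cv2$cumulative)
  expect_equal(cv1$first_observation, cv2$first_observation)
})

test_that("every event is accounted for exactly once", {
  log <- data.frame(
    time_months = c(0.5, 1.5, 2.5, 2.6, 9.0, 16.0, 17.0),
    plant_id = c("a", "a", "b", "zz", "c", "a", "zz"),
    evidence = c("fruit_consumption", "seed_burial", "fruit_consumption",
                 "other", "other", "fruit_consumption", "other")
  )
  cv <- accumulation_curve(log, eligible = c("a", "b", "c"), horizon = 15)
  acc <- cv$accounting
  expect_equal(acc$n_eligible_first, 3L)   # a, b, c
  expect_equal(acc$n_eligible_repeat, 1L)  # a at 1.5
  expect_equal(acc$n_unexpected, 1L)       # zz at 2.6
  expect_equal(acc$n_beyond_horizon, 2L)   # events at 16 and 17
  expect_equal(acc$n_eligible_first + acc$n_eligible_repeat + acc$n_unexpected +
                 acc$n_beyond_horizon + acc$n_evidence_filtered, acc$n_events)
  expect_equal(cv$unexpected_species, "zz")

  # evidence filter keeps the identity intact
  cvf <- accumulation_curve(log, eligible = c("a", "b", "c"), horizon = 15,
                            evidence = "fruit_consumption")
  accf <- cvf$accounting
  expect_equal(accf$n_evidence_filtered, 4L)  # 1 seed_burial + 3 other
  expect_equal(accf$n_eligible_first + accf$n_eligible_repeat +
                 accf$n_unexpected + accf$n_beyond_horizon +
                 accf$n_evidence_filtered, accf$n_events)
  expect_error(accumulation_curve(log, "a", horizon = 15, evidence = "tracks"),
               "unknown evidence")
})

test_that("remaining credit is conserved and guards against overdrafts", {
  # curve reaching 23 of a credit of 65 leaves 42 to cash
  log <- data.frame(time_months = seq_len(23) * 0.6,
                    plant_id = paste0("sp", 1:23))
  eligible <- paste0("sp", 1:65)
  cv <- accumulation_curve(log, eligible, horizon = 15)
  rem <- remaining_credit(cv, 65)
  expect_equal(max(cv$cumulative), 23L)
  expect_equal(min(rem), 42)
  expect_true(all(cv$cumulative + rem == 65))

  expect_true(all(remaining_credit(cv, 65) <= 65))
  expect_error(remaining_credit(cv, 20), "exceeds credit0")

  # zero observations leave the full credit everywhere
  cv0 <- accumulation_curve(log[0, ], eligible, horizon = 5)
  expect_true(all(remaining_credit(cv0, 65) == 65))
})

test_that("noiseless asymptotic fits recover their generating parameters", {
  t <- 1:24
  mm <- data.frame(t = t, richness = 50 * t / (3 + t))
  fit <- fit_accumulation(mm, "michaelis_menten")
  expect_s3_class(fit, "asymptotic_fit")
  expect_equal(fit$asymptote, 50, tolerance = 1e-6)
  expect_equal(fit$rate_or_halfsat, 3, tolerance = 1e-6)
  expect_lt(fit$residual_sse, 1e-10)

  ne <- data.frame(t = t, richness = 65 * (1 - exp(-0.15 * t)))
  fit2 <- fit_accumulation(ne, "negative_exponential")
  expect_equal(fit2$asymptote, 65, tolerance = 1e-6)
  expect_equal(fit2$rate_or_halfsat, 0.15, tolerance = 1e-6)

  # fitted curves are non-decreasing on t >= 0
  grid <- seq(0, 100, by = 0.5)
  expect_true(all(diff(predict(fit, grid)) >= 0))
  expect_true(all(diff(predict(fit2, grid)) >= 0))
})

test_that("degenerate curves yield a no-fit sentinel, not an error", {
  const <- data.frame(t = 1:6, richness = rep(4, 6))
  nf <- fit_accumulation(const)
  expect_s3_class(nf, "asymptotic_fit_failure")
  expect_match(nf$reason, "constant")

  expect_error(fit_accumulation(data.frame(t = 1:2, richness = c(1, 2))),
               "at least 3 distinct non-zero bins")
})

test_that("time_to_fraction inverts the fit and refuses the full asymptote", {
  fit <- fit_accumulation(data.frame(t = 1:24, richness = 50 * (1:24) / (3 + 1:24)))
  tq <- time_to_fraction(fit, c(0.5, 0.9))
  expect_equal(unname(tq["q0.5"]), 3, tolerance = 1e-6)        # t = b at half
  expect_equal(unname(tq["q0.9"]), 0.9 * 3 / 0.1, tolerance = 1e-6)
  expect_warning(t1 <- time_to_fraction(fit, 1), "never attained")
  expect_true(is.na(t1))

  ne <- fit_accumulation(data.frame(t = 1:24, richness = 65 * (1 - exp(-0.15 * 1:24))),
                         "negative_exponential")
  expect_equal(unname(time_to_fraction(ne, 0.5)), log(2) / 0.15,
               tolerance = 1e-6)
})

test_that("success is judged against the ceiling of the credit proportion", {
  log <- data.frame(time_months = c(1.1, 2.2, 3.3), plant_id = c("a", "b", "c"))
  eligible <- paste0(letters[1:10])
  cv <- accumulation_curve(log, eligible, horizon = 5)

  # threshold ceiling(0.25 * 10) = 3, reached when the third species appears
  rep1 <- success_assessment(cv, credit0 = 10, proportion = 0.25)
  expect_true(rep1$achieved)
  expect_equal(rep1$threshold_species, 3L)
  expect_equal(rep1$time_achieved, 4)  # bin (3, 4] holds the 3.3 observation

  rep2 <- success_assessment(cv, credit0 = 10, proportion = 1)
  expect_false(rep2$achieved)
  expect_equal(rep2$proportion_cashed, 0.3)
  expect_true(is.na(rep2$time_achieved))

  # cashing everything achieves proportion 1 at that bin
  log_all <- data.frame(time_months = seq_along(eligible),
                        plant_id = eligible)
  cv_all <- accumulation_curve(log_all, eligible, horizon = 10)
  rep3 <- success_assessment(cv_all, credit0 = 10, proportion = 1)
  expect_true(rep3$achieved)
  expect_equal(rep3$time_achieved, 10)

  # a 23-of-65 curve is not yet a success under proportion 1
  log23 <- data.frame(time_months = seq_len(23) * 0.5,
                      plant_id = paste0("sp", 1:23))
  cv23 <- accumulation_curve(log23, paste0("sp", 1:65), horizon = 15)
  rep4 <- success_assessment(cv23, credit0 = 65, proportion = 1)
  expect_false(rep4$achieved)
  expect_equal(rep4$proportion_cashed, 23 / 65)

  undef <- success_assessment(cv, credit0 = 0)
  expect_true(is.na(undef$achieved))
  expect_match(undef$note, "nothing to cash")
  expect_error(success_assessment(cv, 10, proportion = 0), "proportion")
})
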