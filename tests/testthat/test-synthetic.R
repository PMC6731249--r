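test_that("generation is reproducible from the seed", {
  a <- generate_cohort(seed = 123)
  b <- generate_cohort(seed = 123)
  expect_identical(a$participants, b$participants)
  c <- generate_cohort(seed = 124)
  expect_false(identical(a$participants, c$participants))
  d <- null_cohort(seed = 123)
  expect_identical(d$participants$participant_id, a$participants$participant_id)
})

test_that("generated cohorts respect all hard invariants", {
  st <- generate_cohort(seed = 200)
  df <- st$participants
  expect_equal(nrow(df), 373)
  expect_equal(as.integer(table(df$sample)[fc_samples()]),
               c(120L, 72L, 103L, 78L))
  expect_equal(nrow(attr(st, "rejected")), 0)
  expect_true(all(df$own_correct %in% 0:72))
  expect_true(all(df$other_correct %in% 0:72))
  pct <- df[, grep("classmates|friends|neighbours", names(df))]
  expect_true(all(is.na(pct) | (pct >= 0 & pct <= 100)))
  expect_true(all(df$prejudice %in% 1:9))
  # the smaller primary cell: only 57 Caucasians report primary contact
  cauc <- df[df$sample == "caucasian_western", ]
  expect_equal(sum(!is.na(cauc$primary_classmates_other)), 57)
  # months in the West exist only for the Eastern-raised sample
  tw <- df$adult_time_in_west_other
  expect_true(all(is.na(tw[df$sample != "asian_eastern_raised"])))
  tw_e <- tw[df$sample == "asian_eastern_raised"]
  expect_true(all(tw_e >= 1 & tw_e <= 61))
})

test_that("contact marginals have the stated shape", {
  st <- generate_cohort(seed = 201)
  df <- st$participants
  # primary other-group contact is significantly right-skewed (skew gate)
  cc <- df$primary_classmates_other[df$sample == "caucasian_western"]
  expect_identical(skewness_gate(cc), "tau_b")
  expect_gt(skewness_test(cc)$g1, 0)
  # Eastern-raised school-age other-group contact: median 0, range-gated out
  e <- df[df$sample == "asian_eastern_raised", ]
  expect_equal(median(e$primary_classmates_other), 0)
  expect_equal(median(e$secondary_classmates_other), 0)
  expect_false(range_sufficient(e$primary_classmates_other))
  # but adult contact has usable range
  expect_true(range_sufficient(e$adult_classmates_other))
  # Caucasian primary classmates pass the 10% criterion
  expect_true(range_sufficient(cc))
})

test_that("copula correlations match the arcsin transform at large n", {
  marg <- default_contact_marginals()
  marg$pi0 <- 0  # continuous marginals: tau is invariant to them
  lambda2 <- sin(0.40 * pi / 2)  # target within-stage tau of 0.40
  cfg <- synthetic_config(n = c(caucasian_western = 10000,
                                asian_eastern_raised = 5,
                                asian_western_raised = 5,
                                northern_european = 5),
                          lambda2 = lambda2, marginals = marg,
                          caucasian_primary_n = 10000)
  st <- generate_cohort(cfg, seed = 300)
  df <- st$participants[st$participants$sample == "caucasian_western", ]
  tau <- correlate(df$primary_classmates_other, df$primary_friends_other,
                   "tau_b")$estimate
  expect_lt(abs(tau - 0.40), 0.03)
})

test_that("invalid copula configurations are rejected", {
  bad <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.99, -0.99, 0.99, 1), 3, 3)
  expect_error(synthetic_config(stage_corr = bad), "positive definite")
  expect_error(synthetic_config(lambda2 = 1.5), "lambda2")
})

test_that("binomial trial noise makes reliability meaningful by construction", {
  st <- generate_cohort(seed = 400, return_trials = TRUE)
  tr <- attr(st, "trials")
  expect_equal(rowSums(tr$own), st$participants$own_correct)
  expect_equal(rowSums(tr$other), st$participants$other_correct)
  rel <- cronbach_alpha(tr$own)
  expect_gt(rel$alpha, 0.70)
  expect_lt(rel$alpha, 0.97)
  expect_gt(rel$sem, 0)
})

test_that("null cohorts carry no contact or prejudice effects", {
  st <- null_cohort(seed = 500)
  b <- run_battery(st, "primary")
  # no planted effect: the direction count is binomial-like, not extreme
  expect_lt(sum(b$significant), 5)
  pspec <- default_battery_spec(outcome = "prejudice")
  pb <- run_battery(st, "adult", pspec)
  expect_lt(mean(pb$significant), 0.5)
  # contact structure is retained: marginals still skewed
  cc <- st$participants$primary_classmates_other[
    st$participants$sample == "caucasian_western"]
  expect_identical(skewness_gate(cc), "tau_b")
})

test_that("the prejudice link points the predicted way in effect cohorts", {
  st <- generate_cohort(seed = 600)
  pspec <- default_battery_spec(outcome = "prejudice")
  pb <- run_battery(st, "adult", pspec)
  # greater other-group contact goes with more willingness to marry
  expect_gt(mean(pb$in_predicted_direction), 0.7)
  expect_true(all(pb$predicted_sign == 1))
})
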