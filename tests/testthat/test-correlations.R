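test_that("skewness test reproduces frozen reference values", {
  # reference z and p computed with an independent implementation of the
  # D'Agostino (1970) transformation
  r1 <- skewness_test((1:20)^3)
  expect_equal(r1$z, 2.0979016502, tolerance = 1e-8)
  expect_equal(r1$p, 0.0359138342, tolerance = 1e-7)
  # exactly symmetric data: zero skew, z = 0 (the reference implementation
  # remaps y = 0 to 1 here, a documented wart we do not reproduce)
  r2 <- skewness_test(1:20)
  expect_equal(r2$z, 0)
  expect_equal(r2$p, 1)
  r4 <- skewness_test(c(1:19, 30))
  expect_equal(r4$z, 1.6672412466, tolerance = 1e-8)
  expect_equal(r4$p, 0.0954664441, tolerance = 1e-7)
  r3 <- skewness_test(c(rep(0, 12), 1, 2, 3, 5, 8, 13, 21, 40))
  expect_equal(r3$z, 4.2266453634, tolerance = 1e-8)
  expect_equal(r3$p, 2.37201e-05, tolerance = 1e-6)
  expect_error(skewness_test(1:5), "n >= 8")
  expect_error(skewness_test(rep(3, 20)), "no variance")
})

test_that("skew gate picks tau for skewed and r for symmetric distributions", {
  set.seed(20)
  expect_identical(skewness_gate(rnorm(500)), "pearson")
  zi <- ifelse(runif(500) < 0.6, 0, rexp(500, 1 / 15))  # zero-inflated
  expect_identical(skewness_gate(zi), "tau_b")
  expect_error(skewness_gate(rep(1, 20)), "no variance")
})

test_that("tau-b agrees with the brute-force pairwise oracle on tied data", {
  # includes the classic untied case: x=(1,2,3,4), y=(2,1,4,3) -> 2/6
  expect_equal(oracle_tau_b(c(1, 2, 3, 4), c(2, 1, 4, 3)), 1 / 3)
  set.seed(21)
  for (i in 1:200) {
    n <- sample(5:8, 1)
    x <- sample(0:4, n, replace = TRUE)
    y <- sample(0:4, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    r <- correlate(x, y, method = "tau_b")
    expect_equal(r$estimate, oracle_tau_b(x, y), tolerance = 1e-12)
    # and against the standard library implementation
    expect_equal(r$estimate,
                 unname(suppressWarnings(cor(x, y, method = "kendall"))),
                 tolerance = 1e-12)
  }
})

test_that("correlation identities: perfect association, sign flips", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(correlate(x, x, "tau_b")$estimate, 1)
  expect_equal(correlate(x, x, "pearson")$estimate, 1)
  set.seed(22)
  y <- rnorm(30); x <- rnorm(30)
  for (m in c("tau_b", "pearson")) {
    a <- correlate(x, y, m)
    b <- correlate(x, -y, m)
    expect_equal(b$estimate, -a$estimate)
    expect_equal(b$p_two_tailed, a$p_two_tailed)
  }
  expect_error(correlate(1:4, 4:1), "n >= 5")
  expect_error(correlate(rep(1, 10), rnorm(10)), "tied")
})

test_that("tau p-values: tie-adjusted approximation and exact enumeration", {
  set.seed(23)
  # approximation matches the standard library's tie-adjusted normal p
  for (i in 1:50) {
    n <- sample(20:60, 1)
    x <- sample(0:5, n, replace = TRUE)
    y <- sample(0:5, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(correlate(x, y, "tau_b")$p_two_tailed,
                 suppressWarnings(cor.test(x, y, method = "kendall"))$p.value,
                 tolerance = 1e-12)
  }
  # exact enumeration agrees with a direct R enumeration over arrangements
  x <- c(1, 1, 2, 3, 5, 5)
  y <- c(0, 2, 2, 1, 4, 3)
  ex <- correlate(x, y, "tau_b", exact = TRUE)$p_two_tailed
  S_of <- function(yy) sum(vapply(seq_along(x)[-length(x)], function(i) {
    sum(sign(x[i] - x[(i + 1):length(x)]) * sign(yy[i] - yy[(i + 1):length(x)]))
  }, 1))
  perms <- perm_all(6L)
  Ss <- apply(perms, 1, function(p) S_of(y[p]))
  expect_equal(ex, mean(abs(Ss) >= abs(S_of(y)) - 1e-9), tolerance = 1e-12)
  expect_error(correlate(rnorm(12), rnorm(12), "tau_b", exact = TRUE),
               "n <= 9")
})

test_that("pearson p matches the closed-form t transformation", {
  set.seed(24)
  x <- rnorm(40); y <- 0.3 * x + rnorm(40)
  r <- correlate(x, y, "pearson")
  tval <- r$estimate * sqrt((40 - 2) / (1 - r$estimate^2))
  expect_equal(r$p_two_tailed, 2 * pt(-abs(tval), 38))
  expect_equal(r$p_two_tailed, cor.test(x, y)$p.value, tolerance = 1e-12)
})

test_that("range gate applies the classmates-median inclusion criterion", {
  expect_false(range_sufficient(rep(0, 20)))          # median 0
  expect_false(range_sufficient(c(rep(0, 10), rep(5, 11))))  # median 5
  expect_true(range_sufficient(c(rep(10, 11), rep(0, 10))))  # median 10
  expect_false(range_sufficient(numeric(0)))
})

test_that("battery output is invariant to participant row order", {
  st <- tiny_study(n_per_sample = 8)
  b1 <- run_battery(st, "primary", tiny_spec())
  set.seed(30)
  st2 <- st
  st2$participants <- st2$participants[sample(nrow(st2$participants)), ]
  b2 <- run_battery(st2, "primary", tiny_spec())
  key <- function(b) b[order(b$sample, b$measure, b$group), ]
  expect_equal(key(b1)$estimate, key(b2)$estimate)
  expect_equal(key(b1)$p_two_tailed, key(b2)$p_two_tailed)
})

test_that("battery flags follow the predicted-direction logic", {
  st <- generate_cohort(seed = 11)
  b <- run_battery(st, "primary")
  expect_equal(nrow(b), 20)  # the design's primary-stage bar count
  # planted primary effects: other-group bars negative, own-group (the
  # weaker planted effect) predominantly positive
  expect_true(all(b$estimate[b$group == "other"] < 0))
  expect_gte(mean(b$estimate[b$group == "own"] > 0), 0.8)
  expect_true(all(b$significant == (b$in_predicted_direction &
                                      b$p_two_tailed < 0.05)))
  expect_true(all(!(b$significant & b$approaching)))
  expect_true(all(b$p_two_tailed > 0 & b$p_two_tailed <= 1))
  expect_true(all(abs(b$estimate) <= 1))
  # the Eastern-raised sample is excluded at school stages by the range gate
  excl <- attr(b, "exclusions")
  expect_true("asian_eastern_raised" %in% excl$sample)
})

test_that("stage dissociation recovers copula targets and identity", {
  st <- tiny_study(n_per_sample = 10)
  df <- st$participants
  df$adult_classmates_other <- df$primary_classmates_other
  st$participants <- df
  r <- stage_dissociation(st, "caucasian_western", "classmates")
  expect_equal(r$estimate, 1)

  # generator with a continuous-marginal copula targeting cross-stage tau 0.4
  marg <- default_contact_marginals()
  marg$pi0 <- 0
  cfg <- synthetic_config(n = c(caucasian_western = 2000,
                                asian_eastern_raised = 5,
                                asian_western_raised = 5,
                                northern_european = 5),
                          lambda2 = 0.8,
                          stage_corr = {
                            m <- default_stage_corr()
                            m["primary", "adult"] <- sin(0.4 * pi / 2) / 0.8
                            m["adult", "primary"] <- m["primary", "adult"]
                            m
                          },
                          marginals = marg, caucasian_primary_n = 2000)
  st2 <- generate_cohort(cfg, seed = 99)
  r2 <- stage_dissociation(st2, "caucasian_western", "classmates")
  expect_lt(abs(r2$estimate - 0.4), 0.07)

  dt <- dissociation_table(generate_cohort(seed = 12))
  expect_true(all(abs(dt$estimate) < 0.6))  # low-to-medium, as required
  expect_true(all(dt$method %in% c("tau_b", "pearson")))
})

test_that("per-bar false-positive rate is calibrated under the null", {
  set.seed(31)
  frac <- numeric(40)
  cfg <- synthetic_config()
  for (i in 1:40) {
    st <- null_cohort(cfg, seed = 4000 + i)
    b <- run_battery(st, "primary")
    frac[i] <- mean(b$significant)
  }
  # significant = p < 0.05 two-tailed AND predicted direction ~ alpha/2
  expect_lt(abs(mean(frac) - 0.025), 0.012)
})
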