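test_that("evidence patterns encode battery flags", {
  st <- tiny_study(n_per_sample = 8)
  b <- run_battery(st, "primary", tiny_spec())
  pat <- encode_pattern(b)
  expect_equal(pat$m, nrow(b))
  expect_equal(pat$d, sum(b$in_predicted_direction))
  expect_equal(pat$s, sum(b$significant))
  expect_equal(pat$a, sum(b$approaching))
  # all wrong-signed, null rows -> (m, 0, 0, 0)
  b0 <- b
  b0$in_predicted_direction <- FALSE
  b0$significant <- FALSE
  b0$approaching <- FALSE
  expect_equal(unlist(encode_pattern(b0)[c("d", "s", "a")]),
               c(d = 0, s = 0, a = 0))
  expect_error(encode_pattern(b[0, ]), "empty")
  expect_error(evidence_pattern(m = 5, d = 3, s = 4), "s \\+ a <= d")
})

test_that("the strength ordering is a preorder with (d, s) dominance", {
  obs <- evidence_pattern(20, 18, 10, 2)
  expect_true(at_least_as_strong(obs, obs))                    # reflexive
  expect_true(at_least_as_strong(evidence_pattern(20, 19, 10), obs, "ds"))
  expect_false(at_least_as_strong(evidence_pattern(20, 19, 9), obs, "ds"))
  expect_false(at_least_as_strong(evidence_pattern(20, 17, 11), obs, "ds"))
  # lex refines dominance: dominance-stronger implies lex-stronger, and lex
  # additionally ranks d-increases above any s-decrease
  expect_true(at_least_as_strong(evidence_pattern(20, 19, 10), obs, "lex"))
  expect_true(at_least_as_strong(evidence_pattern(20, 19, 0), obs, "lex"))
  expect_false(at_least_as_strong(evidence_pattern(20, 18, 9), obs, "lex"))
  expect_error(at_least_as_strong(evidence_pattern(16, 10, 2), obs),
               "different m")
  # transitivity over random triples, all orderings
  set.seed(40)
  for (ord in c("ds", "dsa", "lex")) {
    for (i in 1:200) {
      ps <- replicate(3, {
        d <- sample(0:10, 1); s <- sample(0:d, 1)
        a <- sample(0:(d - s), 1)
        evidence_pattern(10, d, s, a)
      }, simplify = FALSE)
      if (at_least_as_strong(ps[[1]], ps[[2]], ord) &&
          at_least_as_strong(ps[[2]], ps[[3]], ord)) {
        expect_true(at_least_as_strong(ps[[1]], ps[[3]], ord))
      }
      expect_true(at_least_as_strong(ps[[1]], ps[[1]], ord))
    }
  }
})

test_that("permutation runs conserve outcomes and reproduce the observed pattern", {
  st <- tiny_study(n_per_sample = 8)
  spec <- tiny_spec()
  plan <- battery_plan(st, "primary", spec)
  # identity permutation reproduces the observed battery pattern
  idp <- lapply(plan$samples, function(s) seq_along(s$y))
  obs <- encode_pattern(run_battery(st, "primary", spec, plan = plan))
  expect_equal(permutation_run(plan, perms = idp), obs)
  # permutation is a bijection: per-sample outcome multisets unchanged
  set.seed(41)
  for (i in 1:20) {
    prm <- lapply(plan$samples, function(s) sample(length(s$y)))
    for (k in seq_along(prm)) {
      expect_equal(sort(plan$samples[[k]]$y[prm[[k]]]),
                   sort(plan$samples[[k]]$y))
    }
    pat <- permutation_run(plan, perms = prm)
    expect_true(pat$d <= pat$m && pat$s + pat$a <= pat$d)
  }
})

test_that("the pooled pattern is the sum of independent per-sample patterns", {
  st <- tiny_study(n_per_sample = 8)
  spec <- tiny_spec()
  plan <- battery_plan(st, "primary", spec)
  set.seed(42)
  prm <- lapply(plan$samples, function(s) sample(length(s$y)))
  whole <- permutation_run(plan, perms = prm)
  parts <- lapply(seq_along(plan$samples), function(k) {
    sub <- plan
    sub$samples <- plan$samples[k]
    permutation_run(sub, perms = prm[k])
  })
  expect_equal(whole$d, sum(vapply(parts, `[[`, 1, "d")))
  expect_equal(whole$s, sum(vapply(parts, `[[`, 1, "s")))
  expect_equal(whole$a, sum(vapply(parts, `[[`, 1, "a")))
})

test_that("Monte-Carlo p is deterministic in the seed and sane at the extremes", {
  st <- tiny_study(n_per_sample = 8)
  spec <- tiny_spec()
  mc1 <- monte_carlo_p(st, "primary", spec, n_runs = 5000, seed = 7,
                       keep_patterns = TRUE)
  mc2 <- monte_carlo_p(st, "primary", spec, n_runs = 5000, seed = 7,
                       keep_patterns = TRUE)
  expect_identical(mc1$n_qualifying, mc2$n_qualifying)
  expect_identical(mc1$patterns, mc2$patterns)
  mc3 <- monte_carlo_p(st, "primary", spec, n_runs = 5000, seed = 8,
                       keep_patterns = TRUE)
  expect_false(identical(mc1$patterns, mc3$patterns))
  expect_error(monte_carlo_p(st, "primary", spec, n_runs = 100), "unstable")

  # weakest possible observed evidence -> p = 1 (every run qualifies)
  mc <- monte_carlo_p(st, "primary", spec, n_runs = 2000, seed = 1,
                      keep_patterns = TRUE)
  pats <- mc$patterns
  n_weak <- sum(pats[, 1] >= 0 & pats[, 2] >= 0)  # vs observed (d=0, s=0)
  expect_equal(n_weak, 2000)
  # censored reporting: bound, not a point value, when nothing qualifies
  expect_true(mc1$mc_se >= 0)
})

test_that("strengthening the observed pattern never increases p (fixed stream)", {
  st <- tiny_study(n_per_sample = 8)
  spec <- tiny_spec()
  mc <- monte_carlo_p(st, "primary", spec, n_runs = 4000, seed = 9,
                      keep_patterns = TRUE)
  pats <- mc$patterns
  p_of <- function(d, s) mean(pats[, 1] >= d & pats[, 2] >= s)
  for (d in 0:3) {
    for (s in 0:d) {
      expect_gte(p_of(d, s), p_of(d + 1, s))
      expect_gte(p_of(d, s), p_of(d, s + 1))
    }
  }
})

test_that("Monte-Carlo p converges to the fully independent exhaustive oracle", {
  st <- tiny_study(seed = 5, n_per_sample = 5)
  spec <- tiny_spec()
  oracle <- oracle_exact_p(st, spec)          # base-R enumeration, cor() + pt()
  for (ord in c("lex", "ds")) {
    p_oracle <- if (ord == "lex") oracle$p_lex else oracle$p_ds
    pkg <- exact_permutation_p(st, "primary", spec, ordering = ord)
    expect_equal(pkg$p_exact, p_oracle, tolerance = 1e-12)
    expect_equal(pkg$n_total, oracle$n_total)
    mc <- monte_carlo_p(st, "primary", spec, n_runs = 2e4, seed = 3,
                        ordering = ord)
    se <- max(mc$mc_se, sqrt(p_oracle * (1 - p_oracle) / mc$n_runs))
    expect_lt(abs(mc$p_value - p_oracle), 3 * se + 1e-9)
  }
})

test_that("binomial direction probability reproduces the printed benchmark", {
  # 13 of 16 independent correlations in the predicted direction
  expect_equal(round(binomial_direction_p(13, 16), 4), 0.0085)
  expect_equal(binomial_direction_p(2, 4), 6 / 16)
  expect_equal(binomial_direction_p(10, 10), 0.5^10)
  # the upper-tail variant
  expect_equal(binomial_direction_p(13, 16, tail = TRUE),
               pbinom(12, 16, 0.5, lower.tail = FALSE))
  expect_error(binomial_direction_p(5, 4), "k <= n")
})
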