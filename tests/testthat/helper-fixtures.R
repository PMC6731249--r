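# Shared fixtures and independent oracles, all built in code.

# brute-force Kendall tau-b over all pairs (independent of the package's
# compiled routines)
oracle_tau_b <- function(x, y) {
  n <- length(x)
  S <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      S <- S + sign(x[i] - x[j]) * sign(y[i] - y[j])
    }
  }
  ties <- function(v) sum(sapply(table(v), function(t) t * (t - 1) / 2))
  n0 <- n * (n - 1) / 2
  S / sqrt((n0 - ties(x)) * (n0 - ties(y)))
}

# all permutations of 1..n as a matrix (n! rows)
perm_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perm_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, sub + (sub >= k))))
}

# a tiny two-sample cohort with two other-group primary contact measures and
# a planted negative contact-ORE relationship; small enough for exhaustive
# permutation enumeration
tiny_study <- function(seed = 42, n_per_sample = 5) {
  set.seed(seed)
  samples <- c("caucasian_western", "northern_european")
  rows <- list()
  for (s in seq_along(samples)) {
    n <- n_per_sample
    contact <- round(runif(n, 5, 60))
    ore <- round(30 - 0.4 * contact + rnorm(n, 0, 6), 1)
    own <- round(runif(n, 60, 90), 1)
    rows[[s]] <- data.frame(
      participant_id = paste0("T", s, seq_len(n)),
      sample = samples[s],
      own_pct = own, other_pct = own - ore,
      primary_classmates_other = contact,
      primary_friends_other = pmin(100, round(contact * 0.6 + runif(n, 0, 20))),
      stringsAsFactors = FALSE)
  }
  study_table(do.call(rbind, rows))
}

# battery spec restricted to the tiny cohort's two cells per sample
tiny_spec <- function() {
  cells <- expand.grid(
    sample = c("caucasian_western", "northern_european"),
    stage = "primary",
    measure = c("classmates", "friends"),
    group = "other", stringsAsFactors = FALSE)
  cells$predicted_sign <- -1L
  structure(list(outcome = "difference_score", alpha_sig = 0.05,
                 alpha_marg = 0.09, range_threshold = 10, skew_alpha = 0.05,
                 cells = cells),
            class = "battery_spec")
}

# exhaustive evidence-pattern p-value computed entirely in base R:
# enumerates all combinations of within-sample outcome permutations,
# recomputes every (pearson) cell with cor() and the t-distribution p, and
# counts patterns at least as strong as observed under both the lexicographic
# and the componentwise-dominance ordering.
oracle_exact_p <- function(study, spec, stage = "primary") {
  plan <- battery_plan(study, stage, spec)
  cellp <- function(x, y, sgn) {
    r <- cor(x, y)
    n <- length(x)
    p <- if (abs(r) < 1) 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
    else 0
    dir <- sign(r) == sgn && r != 0
    c(dir = dir, sig = dir && p < spec$alpha_sig)
  }
  pattern_for <- function(ys) {
    d <- 0; s <- 0
    for (i in seq_along(plan$samples)) {
      sm <- plan$samples[[i]]
      for (c in sm$cells) {
        stopifnot(c$method == "pearson")  # oracle covers the pearson case
        fl <- cellp(c$x, ys[[i]][c$idx], c$predicted_sign)
        d <- d + fl["dir"]; s <- s + fl["sig"]
      }
    }
    c(d = unname(d), s = unname(s))
  }
  obs <- pattern_for(lapply(plan$samples, function(s) s$y))
  sizes <- vapply(plan$samples, function(s) length(s$y), 1L)
  perms <- lapply(sizes, perm_all)
  grid <- as.matrix(expand.grid(lapply(perms, function(p) seq_len(nrow(p)))))
  hits_ds <- 0
  hits_lex <- 0
  for (g in seq_len(nrow(grid))) {
    ys <- lapply(seq_along(perms), function(i) {
      plan$samples[[i]]$y[perms[[i]][grid[g, i], ]]
    })
    pat <- pattern_for(ys)
    if (pat["d"] >= obs["d"] && pat["s"] >= obs["s"]) hits_ds <- hits_ds + 1
    if (pat["d"] > obs["d"] ||
        (pat["d"] == obs["d"] && pat["s"] >= obs["s"])) {
      hits_lex <- hits_lex + 1
    }
  }
  list(p_ds = hits_ds / nrow(grid), p_lex = hits_lex / nrow(grid),
       n_total = nrow(grid), observed = obs)
}
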