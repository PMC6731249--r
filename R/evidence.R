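## Evidence patterns and the condition-wise Monte-Carlo test -----------------

#' Encode a battery as an evidence pattern
#'
#' The total evidence for a contact effect at one life stage is summarised by
#' counts over the battery's correlations: `m` cells, `d` in the predicted
#' direction, `s` individually significant (two-tailed p below the battery's
#' alpha, in the predicted direction), `a` approaching significance.
#'
#' @param results a `battery_result` from [run_battery()], or any data.frame
#'   with the flag columns.
#' @return An `evidence_pattern`: list with `m`, `d`, `s`, `a`.
#' @export
encode_pattern <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("empty battery: no correlations to encode")
  }
  structure(list(m = nrow(results),
                 d = sum(results$in_predicted_direction),
                 s = sum(results$significant),
                 a = sum(results$approaching)),
            class = "evidence_pattern")
}

#' @rdname encode_pattern
#' @param m,d,s,a counts (used to build a pattern directly).
#' @export
evidence_pattern <- function(m, d, s, a = 0) {
  stopifnot(d <= m, s + a <= d, s >= 0, a >= 0, d >= 0)
  structure(list(m = m, d = d, s = s, a = a), class = "evidence_pattern")
}

#' @export
print.evidence_pattern <- function(x, ...) {
  cat(sprintf("evidence pattern: %d/%d in predicted direction, %d significant, %d approaching\n",
              x$d, x$m, x$s, x$a))
  invisible(x)
}

#' Is one evidence pattern at least as strong as another?
#'
#' The default ordering `"lex"` is lexicographic on (direction count,
#' significant count): more directions is always stronger, ties are broken by
#' the significant count. It is a total order refining componentwise
#' dominance, so its rejection regions are nested and the resulting
#' permutation p-value is valid (never anti-conservative) — see the methods
#' vignette. `"ds"` is plain componentwise dominance (d' >= d and s' >= s);
#' `"dsa"` additionally requires s' + a' >= s + a. The approaching count is
#' always recorded but only `"dsa"` uses it.
#'
#' @param candidate,observed `evidence_pattern`s with equal `m`.
#' @param ordering `"lex"` (default), `"ds"`, or `"dsa"`.
#' @return Logical.
#' @export
at_least_as_strong <- function(candidate, observed,
                               ordering = c("lex", "ds", "dsa")) {
  ordering <- match.arg(ordering)
  if (candidate$m != observed$m) stop("patterns have different m")
  switch(ordering,
         ds = candidate$d >= observed$d && candidate$s >= observed$s,
         dsa = candidate$d >= observed$d && candidate$s >= observed$s &&
           (candidate$s + candidate$a) >= (observed$s + observed$a),
         lex = candidate$d > observed$d ||
           (candidate$d == observed$d && candidate$s >= observed$s))
}

ordering_code <- function(ordering) {
  c(ds = 0L, dsa = 1L, lex = 2L)[[match.arg(ordering, c("lex", "ds", "dsa"))]]
}

#' One permutation run of the battery null
#'
#' Permutes the outcome uniformly at random within each sample independently
#' (using R's RNG), leaves every contact column untouched, recomputes the
#' battery under the frozen plan — method tags, listwise masks and exclusions
#' exactly as on the observed data — and returns the run's evidence pattern.
#' Mainly a readable single-run reference; [monte_carlo_p()] drives the
#' compiled engine instead.
#'
#' @param plan a [battery_plan()].
#' @param perms optional list of explicit permutations (one integer vector
#'   per sample, in plan order); default random.
#' @return An `evidence_pattern` (with `m` of the included cells).
#' @export
permutation_run <- function(plan, perms = NULL) {
  stopifnot(inherits(plan, "battery_plan"))
  y_perm <- lapply(seq_along(plan$samples), function(i) {
    y <- plan$samples[[i]]$y
    p <- if (is.null(perms)) sample.int(length(y)) else perms[[i]]
    y[p]
  })
  pat <- cpp_pattern_once(plan_to_cpp(plan, y_override = y_perm),
                          plan$spec$alpha_sig, plan$spec$alpha_marg)
  evidence_pattern(pat$m, pat$d, pat$s, pat$a)
}

#' Condition-wise Monte-Carlo p-value for a total evidence pattern
#'
#' Estimates the Type I error rate of the observed evidence pattern at one
#' life stage: the probability of obtaining evidence at least as strong if
#' there were no true contact--outcome relationship. The null keeps the
#' contact scores exactly as observed (preserving their skewed shapes and
#' intercorrelations) and, on each run, randomises the assignment of outcome
#' scores to participants within each sample independently; the full battery
#' is recomputed with frozen method tags, masks and exclusions, and runs
#' producing a pattern at least as strong as the observed one are counted.
#'
#' @param study a [study_table()].
#' @param stage life stage.
#' @param spec a [default_battery_spec()].
#' @param n_runs number of permutation runs (default 1e6; fewer than 1000 is
#'   rejected unless `force = TRUE`).
#' @param seed integer seed for the engine's deterministic counter-based
#'   generator; identical seed and configuration give identical results.
#' @param ordering evidence-strength ordering, see [at_least_as_strong()].
#' @param estimator `"raw"` counts/runs (default) or the add-one
#'   `"(b+1)/(m+1)"` conservative estimator.
#' @param keep_patterns retain the per-run (d, s, a) matrix (memory ~12 bytes
#'   per run).
#' @param force allow `n_runs < 1000`.
#' @param plan optionally a precomputed [battery_plan()].
#' @return An `mc_result`: list with `p_value`, `n_runs`, `n_qualifying`,
#'   `mc_se`, `seed`, `censored` (`TRUE` when no run qualified, in which case
#'   `p_value` is the bound `1/n_runs`), `observed` pattern, `ordering`,
#'   `estimator`, `battery`, and optionally `patterns`.
#' @export
monte_carlo_p <- function(study, stage, spec = default_battery_spec(),
                          n_runs = 1e6, seed = 1L,
                          ordering = c("lex", "ds", "dsa"),
                          estimator = c("raw", "add_one"),
                          keep_patterns = FALSE, force = FALSE, plan = NULL) {
  ordering <- match.arg(ordering)
  estimator <- match.arg(estimator)
  if (n_runs < 1000 && !force) {
    stop("n_runs < 1000 gives an unstable estimate; use force = TRUE")
  }
  if (is.null(plan)) plan <- battery_plan(study, stage, spec)
  battery <- run_battery(study, stage, spec, plan = plan)
  observed <- encode_pattern(battery)
  res <- cpp_mc_evidence(plan_to_cpp(plan), as.integer(n_runs),
                         plan$spec$alpha_sig, plan$spec$alpha_marg,
                         observed$d, observed$s, observed$a,
                         ordering_code(ordering), as.numeric(seed),
                         NULL, keep_patterns)
  b <- res$n_qualifying
  p <- if (estimator == "raw") b / n_runs else (b + 1) / (n_runs + 1)
  censored <- b == 0
  out <- list(p_value = if (censored) 1 / n_runs else p,
              censored = censored, n_runs = as.integer(n_runs),
              n_qualifying = b, mc_se = sqrt(p * (1 - p) / n_runs),
              seed = seed, ordering = ordering, estimator = estimator,
              observed = observed, battery = battery)
  if (keep_patterns) out$patterns <- res$patterns
  structure(out, class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  print(x$observed)
  ptxt <- if (x$censored) sprintf("< %g", 1 / x$n_runs) else
    sprintf("= %.6g", x$p_value)
  cat(sprintf("condition-wise p %s (%d/%d runs, MC SE %.2g, seed %s, ordering %s)\n",
              ptxt, x$n_qualifying, x$n_runs, x$mc_se, format(x$seed),
              x$ordering))
  invisible(x)
}

#' Exhaustive permutation p-value (small cohorts)
#'
#' Enumerates every combination of within-sample outcome permutations and
#' computes the exact probability of an evidence pattern at least as strong
#' as observed. Feasible only for tiny cohorts (the number of runs is the
#' product of per-sample factorials); serves as the oracle the Monte-Carlo
#' estimate must converge to.
#'
#' @param study,stage,spec,ordering as for [monte_carlo_p()].
#' @param max_total cap on the number of enumerated combinations.
#' @return List with `p_exact`, `n_total`, `n_qualifying`, `observed`.
#' @export
exact_permutation_p <- function(study, stage, spec = default_battery_spec(),
                                ordering = c("lex", "ds", "dsa"),
                                max_total = 2e6) {
  ordering <- match.arg(ordering)
  plan <- battery_plan(study, stage, spec)
  battery <- run_battery(study, stage, spec, plan = plan)
  observed <- encode_pattern(battery)
  perm_all <- function(n) {
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- perm_all(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
      cbind(k, sub + (sub >= k))
    }))
  }
  sizes <- vapply(plan$samples, function(s) length(s$y), 1L)
  total <- prod(factorial(sizes))
  if (total > max_total) stop("enumeration too large: ", total, " runs")
  perms <- lapply(sizes, perm_all)
  counts <- vapply(perms, nrow, 1L)
  grid <- as.matrix(expand.grid(lapply(counts, seq_len)))
  pm <- lapply(seq_along(perms), function(i) {
    perms[[i]][grid[, i], , drop = FALSE] - 1L
  })
  res <- cpp_mc_evidence(plan_to_cpp(plan), nrow(grid),
                         plan$spec$alpha_sig, plan$spec$alpha_marg,
                         observed$d, observed$s, observed$a,
                         ordering_code(ordering), 0, pm, FALSE)
  list(p_exact = res$n_qualifying / nrow(grid), n_total = nrow(grid),
       n_qualifying = res$n_qualifying, observed = observed)
}

#' Binomial probability for independent directions
#'
#' Probability of exactly `k` of `n` independent correlations falling in the
#' predicted direction by chance (fair-coin point mass C(n,k)/2^n); this is
#' the naive benchmark that ignores intercorrelation between measures and is
#' what the condition-wise Monte-Carlo p corrects. `tail = TRUE` gives the
#' upper-tail probability P(X >= k) instead.
#'
#' @param k,n integers, 0 <= k <= n.
#' @param tail use the upper tail rather than the point mass.
#' @return Probability.
#' @export
binomial_direction_p <- function(k, n, tail = FALSE) {
  stopifnot(k >= 0, k <= n, n >= 1)
  if (tail) pbinom(k - 1, n, 0.5, lower.tail = FALSE) else dbinom(k, n, 0.5)
}
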