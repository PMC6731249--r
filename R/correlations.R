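## Skew-gated correlation batteries ------------------------------------------

#' D'Agostino skewness test
#'
#' Transforms the sample skewness coefficient g1 to an approximately standard
#' normal z (D'Agostino 1970), two-tailed. Requires n >= 8.
#'
#' @param x numeric vector (NAs dropped).
#' @return List with `z`, `p`, `g1`, `n`.
#' @export
skewness_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop("skewness test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= .Machine$double.eps) stop("no variance")
  g1 <- mean((x - m)^3) / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  list(z = z, p = 2 * pnorm(-abs(z)), g1 = g1, n = n)
}

#' Choose the correlation method for a contact variable
#'
#' Contact distributions are often zero-inflated and right-skewed; following
#' the battery's convention the method is Kendall tau-b when the distribution
#' shows significant skew (two-tailed D'Agostino test at `alpha`) and Pearson
#' r otherwise. The decision is made once per (sample, stage, measure) on the
#' observed contact values and frozen thereafter — permutation runs reuse it
#' unchanged.
#'
#' @param values observed contact values (NAs dropped).
#' @param alpha significance level of the skewness test (default 0.05).
#' @return `"tau_b"` or `"pearson"`.
#' @export
skewness_gate <- function(values, alpha = 0.05) {
  st <- skewness_test(values)
  if (st$p < alpha) "tau_b" else "pearson"
}

#' Correlate two paired vectors with a tagged method
#'
#' Kendall tau-b uses the tie-corrected estimate with a two-tailed p-value
#' from the tie-adjusted normal approximation of the concordance statistic;
#' `exact = TRUE` (n <= 9) replaces it with exhaustive enumeration over all
#' arrangements. Pearson r uses the t-distribution two-tailed p. Listwise
#' deletion of incomplete pairs; the per-correlation n is reported.
#'
#' @param x,y paired numeric vectors.
#' @param method `"tau_b"` or `"pearson"`.
#' @param exact use exact enumeration for the tau-b p-value (n <= 9 only).
#' @return List with `estimate`, `p_two_tailed`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("tau_b", "pearson"), exact = FALSE) {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need n >= 5 complete pairs (have ", n, ")")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("all values tied on one variable")
  }
  if (method == "tau_b") {
    tb <- cpp_tau_b(x, y)
    p <- tb$p
    if (exact) {
      if (n > 9) stop("exact tau p only for n <= 9")
      p <- cpp_tau_b_exact(x, y)$p
    }
    list(estimate = tb$tau, p_two_tailed = p, n = n, method = "tau_b")
  } else {
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    r <- max(-1, min(1, r))
    p <- if (abs(r) < 1) {
      tval <- r * sqrt((n - 2) / (1 - r^2))
      2 * pt(-abs(tval), n - 2)
    } else 0
    list(estimate = r, p_two_tailed = p, n = n, method = "pearson")
  }
}

#' Range-sufficiency gate for a (sample, stage) block
#'
#' A sample contributes correlations for a life stage only when it has
#' sufficient range of other-group contact there, operationalised as a median
#' of at least `threshold` percent other-group classmates (default 10%). A
#' group raised with a median of 0% other-group schoolmates is excluded for
#' the school stages: a null correlation there could not count as evidence of
#' no relationship.
#'
#' @param classmate_values other-group classmates percentages (NAs dropped).
#' @param threshold minimum median, percent (default 10).
#' @return Logical.
#' @export
range_sufficient <- function(classmate_values, threshold = 10) {
  v <- classmate_values[!is.na(classmate_values)]
  if (!length(v)) return(FALSE)
  median(v) >= threshold
}

## Battery specification ------------------------------------------------------

#' Default correlation battery specification
#'
#' Lists, per sample and life stage, the (measure, group) cells to correlate
#' with the outcome and the predicted sign of each correlation. With the
#' difference-score outcome, more other-group contact predicts a smaller
#' ORE/OEE (sign -1) and more own-group contact a larger one (sign +1). With
#' the raw other-group score as outcome only other-group contact is tested,
#' predicted positive. For the prejudice validation, other-group contact at
#' secondary/adult predicts greater willingness to marry an other-race person
#' (sign +1).
#'
#' The default cell list reproduces the study design's bar counts: 20 cells
#' at primary, 16 at secondary, 29 at adult (counting cells before the range
#' gate removes school-stage blocks for the Eastern-raised sample, which has
#' near-zero school-age other-group contact). The other-ethnicity sample
#' contributes classmates and friends cells at primary and adult; months in
#' the West is an adult, other-group cell of the Eastern-raised sample.
#'
#' @param outcome `"difference_score"` (default), `"raw_other_score"`, or
#'   `"prejudice"`.
#' @param alpha_sig two-tailed significance level for a single bar (0.05,
#'   uncorrected — no multiplicity correction, to avoid inflating Type II
#'   error where the prediction is of no correlation).
#' @param alpha_marg margin for "approaching significance" (0.09).
#' @param range_threshold classmates-median inclusion criterion, percent.
#' @param skew_alpha significance level of the skew gate.
#' @return A `battery_spec` list with the above fields and `cells`, a
#'   data.frame (sample, stage, measure, group, predicted_sign).
#' @export
default_battery_spec <- function(outcome = c("difference_score",
                                             "raw_other_score", "prejudice"),
                                 alpha_sig = 0.05, alpha_marg = 0.09,
                                 range_threshold = 10, skew_alpha = 0.05) {
  outcome <- match.arg(outcome)
  full <- c("classmates", "friends", "neighbours", "questionnaire_scale")
  cells <- list()
  add <- function(sample, stage, measure, group) {
    cells[[length(cells) + 1]] <<- data.frame(
      sample = sample, stage = stage, measure = measure, group = group,
      stringsAsFactors = FALSE)
  }
  for (st in fc_stages()) {
    for (smp in c("caucasian_western", "asian_western_raised",
                  "asian_eastern_raised")) {
      for (m in full) for (g in c("own", "other")) add(smp, st, m, g)
    }
    if (st != "secondary") {
      for (m in c("classmates", "friends")) {
        for (g in c("own", "other")) add("northern_european", st, m, g)
      }
    }
  }
  add("asian_eastern_raised", "adult", "time_in_west", "other")
  cells <- do.call(rbind, cells)

  if (outcome == "difference_score") {
    cells$predicted_sign <- ifelse(cells$group == "other", -1L, 1L)
  } else if (outcome == "raw_other_score") {
    cells <- cells[cells$group == "other", , drop = FALSE]
    cells$predicted_sign <- 1L
  } else {
    cells <- cells[cells$group == "other" &
                     cells$stage %in% c("secondary", "adult"), , drop = FALSE]
    cells$predicted_sign <- 1L
  }
  rownames(cells) <- NULL
  structure(list(outcome = outcome, alpha_sig = alpha_sig,
                 alpha_marg = alpha_marg, range_threshold = range_threshold,
                 skew_alpha = skew_alpha, cells = cells),
            class = "battery_spec")
}

outcome_vector <- function(df, outcome) {
  switch(outcome,
         difference_score = diff_score_vec(df),
         raw_other_score = df$other_pct,
         prejudice = df$prejudice,
         stop("unknown outcome: ", outcome))
}

## Frozen analysis plan -------------------------------------------------------

#' Freeze the analysis plan for one life stage
#'
#' Computes, once, on observed data, everything the permutation null must hold
#' fixed: range-gate exclusions of (sample, stage) blocks, per-cell listwise
#' deletion masks, and per-cell method tags from the skew gate. Cells with
#' fewer than 5 complete pairs or a constant contact vector are excluded with
#' a reason; cells with 5--7 pairs default to Pearson (the skew test needs
#' n >= 8).
#'
#' @param study a [study_table()].
#' @param stage life stage to analyse.
#' @param spec a [default_battery_spec()].
#' @return A `battery_plan`: list with `stage`, `spec`, `samples` (per-sample
#'   outcome vector and frozen cell definitions) and `exclusions`
#'   (data.frame of excluded cells/blocks with reasons).
#' @export
battery_plan <- function(study, stage, spec = default_battery_spec()) {
  stopifnot(inherits(study, "study_table"), stage %in% fc_stages(),
            inherits(spec, "battery_spec"))
  cells <- spec$cells[spec$cells$stage == stage, , drop = FALSE]
  exclusions <- data.frame(sample = character(0), stage = character(0),
                           measure = character(0), group = character(0),
                           reason = character(0), stringsAsFactors = FALSE)
  excl <- function(sample, measure, group, reason) {
    exclusions <<- rbind(exclusions, data.frame(
      sample = sample, stage = stage, measure = measure, group = group,
      reason = reason, stringsAsFactors = FALSE))
  }
  samples <- list()
  for (smp in unique(cells$sample)) {
    df <- sample_rows(study, smp)
    y <- outcome_vector(df, spec$outcome)
    keep <- !is.na(y)
    df <- df[keep, , drop = FALSE]
    y <- y[keep]
    sc <- cells[cells$sample == smp, , drop = FALSE]
    # range gate on other-group classmates for school stages
    if (stage %in% c("primary", "secondary")) {
      cm <- df[[contact_col(stage, "classmates", "other")]]
      if (!range_sufficient(cm, spec$range_threshold)) {
        excl(smp, "*", "*", sprintf(
          "other-group classmates median below %g%% (insufficient range)",
          spec$range_threshold))
        next
      }
    }
    plan_cells <- list()
    for (i in seq_len(nrow(sc))) {
      col <- contact_col(stage, sc$measure[i], sc$group[i])
      x <- df[[col]]
      idx <- which(!is.na(x))
      if (length(idx) < 5) {
        excl(smp, sc$measure[i], sc$group[i],
             sprintf("only %d complete pairs", length(idx)))
        next
      }
      xv <- x[idx]
      if (length(unique(xv)) < 2) {
        excl(smp, sc$measure[i], sc$group[i], "constant contact vector")
        next
      }
      method <- if (length(idx) >= 8) {
        skewness_gate(xv, spec$skew_alpha)
      } else "pearson"
      plan_cells[[length(plan_cells) + 1]] <- list(
        measure = sc$measure[i], group = sc$group[i],
        predicted_sign = sc$predicted_sign[i], method = method,
        idx = idx, x = xv)
    }
    if (length(plan_cells)) {
      samples[[smp]] <- list(sample = smp, y = y, cells = plan_cells)
    }
  }
  structure(list(stage = stage, spec = spec, samples = samples,
                 exclusions = exclusions),
            class = "battery_plan")
}

# marshal a battery_plan for the C++ engine (0-based indices)
plan_to_cpp <- function(plan, y_override = NULL) {
  lapply(seq_along(plan$samples), function(i) {
    s <- plan$samples[[i]]
    y <- if (is.null(y_override)) s$y else y_override[[i]]
    list(y = as.numeric(y),
         cells = lapply(s$cells, function(c) {
           list(idx = as.integer(c$idx - 1L), x = as.numeric(c$x),
                method = if (c$method == "tau_b") 1L else 0L,
                sign = as.integer(c$predicted_sign))
         }))
  })
}

## Battery execution ----------------------------------------------------------

#' Run a correlation battery for one life stage
#'
#' One correlation per included (sample, measure, group) cell, with the
#' method frozen by the skew gate, two-tailed p, and the predicted-direction,
#' significant, and approaching flags. Output order (and everything else) is
#' invariant to the row order of the study table.
#'
#' @param study a [study_table()].
#' @param stage life stage.
#' @param spec a [default_battery_spec()].
#' @param plan optionally a precomputed [battery_plan()] (must match
#'   `study`/`stage`/`spec`).
#' @return data.frame of class `battery_result`, one row per cell: sample,
#'   stage, measure, group, method, estimate, p_two_tailed, n,
#'   predicted_sign, in_predicted_direction, significant, approaching; the
#'   plan's exclusions in `attr(, "exclusions")`.
#' @export
run_battery <- function(study, stage, spec = default_battery_spec(),
                        plan = NULL) {
  if (is.null(plan)) plan <- battery_plan(study, stage, spec)
  rows <- list()
  for (s in plan$samples) {
    for (c in s$cells) {
      ct <- correlate(c$x, s$y[c$idx], method = c$method)
      dir <- (c$predicted_sign > 0 && ct$estimate > 0) ||
        (c$predicted_sign < 0 && ct$estimate < 0)
      sig <- dir && ct$p_two_tailed < plan$spec$alpha_sig
      app <- dir && !sig && ct$p_two_tailed < plan$spec$alpha_marg
      rows[[length(rows) + 1]] <- data.frame(
        sample = s$sample, stage = stage, measure = c$measure,
        group = c$group, method = c$method, estimate = ct$estimate,
        p_two_tailed = ct$p_two_tailed, n = ct$n,
        predicted_sign = c$predicted_sign, in_predicted_direction = dir,
        significant = sig, approaching = app, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  class(out) <- c("battery_result", class(out))
  attr(out, "exclusions") <- plan$exclusions
  out
}

#' Stage-dissociation correlation
#'
#' Correlates the same contact measure at two life stages within one sample —
#' the design requires these to be low-to-medium, otherwise childhood and
#' adult contact effects cannot be separated. The method is chosen by the
#' skew gate applied to the more-skewed of the two stage vectors.
#'
#' @param study a [study_table()].
#' @param sample sample label.
#' @param measure contact measure.
#' @param group `"own"` or `"other"`.
#' @param stage_a,stage_b the two stages (default primary vs adult).
#' @param skew_alpha skew-gate level.
#' @return List as from [correlate()], plus `sample`, `measure`, `group`,
#'   `stage_a`, `stage_b`.
#' @export
stage_dissociation <- function(study, sample, measure, group = "other",
                               stage_a = "primary", stage_b = "adult",
                               skew_alpha = 0.05) {
  df <- sample_rows(study, sample)
  xa <- df[[contact_col(stage_a, measure, group)]]
  xb <- df[[contact_col(stage_b, measure, group)]]
  ok <- complete.cases(xa, xb)
  xa <- xa[ok]; xb <- xb[ok]
  if (length(xa) < 8) stop("need n >= 8 complete pairs for the skew gate")
  za <- abs(skewness_test(xa)$z)
  zb <- abs(skewness_test(xb)$z)
  method <- skewness_gate(if (za >= zb) xa else xb, skew_alpha)
  ct <- correlate(xa, xb, method = method)
  c(list(sample = sample, measure = measure, group = group,
         stage_a = stage_a, stage_b = stage_b), ct)
}

#' Stage-dissociation diagnostic table
#'
#' Primary-versus-adult correlations of each other-group contact measure
#' within each sample that has analysable school-stage contact.
#'
#' @param study a [study_table()].
#' @param spec battery spec (used for the cell list and gates).
#' @return data.frame with one row per (sample, measure).
#' @export
dissociation_table <- function(study, spec = default_battery_spec()) {
  cells <- spec$cells[spec$cells$stage == "primary" &
                        spec$cells$group == "other" &
                        spec$cells$measure != "time_in_west", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    res <- tryCatch(
      stage_dissociation(study, cells$sample[i], cells$measure[i], "other",
                         skew_alpha = spec$skew_alpha),
      error = function(e) NULL)
    if (is.null(res)) next
    rows[[length(rows) + 1]] <- data.frame(
      sample = res$sample, measure = res$measure, estimate = res$estimate,
      method = res$method, p_two_tailed = res$p_two_tailed, n = res$n,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
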