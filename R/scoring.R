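## Psychometric scoring: percent correct, difference scores, reliability -----

#' Percent correct on a forced-choice face memory test
#'
#' The face tests present 72 three-alternative forced-choice trials, so chance
#' performance is 33.33%.
#'
#' @param correct_count integer count(s) of correct trials.
#' @param n_trials trials per test (default 72).
#' @return Percentage(s) in \[0, 100\].
#' @export
percent_correct <- function(correct_count, n_trials = 72) {
  if (any(n_trials <= 0)) stop("n_trials must be positive")
  bad <- !is.na(correct_count) &
    (correct_count < 0 | correct_count > n_trials | correct_count %% 1 != 0)
  if (any(bad)) {
    stop("correct_count outside 0..", n_trials, ": ",
         paste(correct_count[bad], collapse = ", "))
  }
  100 * correct_count / n_trials
}

#' ORE/OEE difference score
#'
#' Own-group minus other-group percent correct. Positive values mean worse
#' other-group recognition (an other-race or other-ethnicity effect); the
#' difference score removes shared variance from general cognitive ability,
#' so adding a constant to both components leaves it unchanged.
#'
#' @param own_pct,other_pct percentages in \[0, 100\] (vectorised).
#' @param outcome_name label, `"ORE"` or `"OEE"`.
#' @return data.frame with `value`, `own_pct`, `other_pct`, `outcome_name`.
#' @export
difference_score <- function(own_pct, other_pct, outcome_name = "ORE") {
  rng <- function(v) any(!is.na(v) & (v < 0 | v > 100))
  if (rng(own_pct) || rng(other_pct)) stop("percentages must lie in [0, 100]")
  data.frame(value = own_pct - other_pct, own_pct = own_pct,
             other_pct = other_pct, outcome_name = outcome_name,
             stringsAsFactors = FALSE)
}

# Difference score, computed from counts where both are present so that
# equal count differences tie exactly (tau-b concordance must not depend on
# floating-point artifacts of two separate divisions).
diff_score_vec <- function(df) {
  v <- df$own_pct - df$other_pct
  hasc <- !is.na(df$own_correct) & !is.na(df$other_correct)
  v[hasc] <- (df$own_correct[hasc] - df$other_correct[hasc]) * (100 / 72)
  v
}

#' Attach percent scores and the difference score to a study table
#'
#' @param study a [study_table()].
#' @return The study table with `own_pct`/`other_pct` filled from counts where
#'   needed and an `ore` column (the ORE/OEE difference score).
#' @export
score_study <- function(study) {
  stopifnot(inherits(study, "study_table"))
  study$participants$ore <- diff_score_vec(study$participants)
  study
}

#' Cronbach's alpha and measurement-error intervals
#'
#' Internal reliability of a multi-item test,
#' alpha = k/(k-1) * (1 - sum of item variances / variance of the total),
#' with the standard error of measurement SEM = SD_total * sqrt(1 - alpha).
#' For a difference between two tests with independent measurement errors, a
#' 68% interval on the difference has half-width
#' sqrt(SEM_own^2 + SEM_other^2) — one combined SEM.
#'
#' @param item_matrix numeric matrix, participants x items (0/1 or graded).
#' @return A `reliability_report`: list with `alpha`, `k`, `n`, `sd_total`,
#'   `sem`.
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2) stop("need at least 2 items")
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 complete participants")
  total <- rowSums(m)
  vt <- var(total)
  if (vt <= .Machine$double.eps) stop("zero total variance: alpha undefined")
  k <- ncol(m)
  alpha <- k / (k - 1) * (1 - sum(apply(m, 2, var)) / vt)
  structure(list(alpha = alpha, k = k, n = nrow(m), sd_total = sqrt(vt),
                 sem = sqrt(vt) * sqrt(max(0, 1 - alpha))),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("Cronbach alpha = %.3f (k = %d items, n = %d); SEM = %.2f\n",
              x$alpha, x$k, x$n, x$sem))
  invisible(x)
}

#' 68% measurement-error half-width for a difference score
#'
#' @param sem_own,sem_other standard errors of measurement of the two tests,
#'   in percentage points (from [cronbach_alpha()] or published constants via
#'   `sem_from_alpha()`).
#' @return Half-width, in percentage points, of a +/- 1 SEM (approximate 68%)
#'   interval on an individual difference score.
#' @export
difference_sem <- function(sem_own, sem_other) {
  stopifnot(sem_own >= 0, sem_other >= 0)
  sqrt(sem_own^2 + sem_other^2)
}

#' @rdname difference_sem
#' @param sd_total standard deviation of test scores (percentage points).
#' @param alpha reliability coefficient (e.g. a published Cronbach alpha).
#' @export
sem_from_alpha <- function(sd_total, alpha) {
  stopifnot(sd_total >= 0, alpha <= 1)
  sd_total * sqrt(1 - alpha)
}

## Bivariate outlier replacement --------------------------------------------

#' Flag and replace bivariate outliers
#'
#' Reproducible stand-in for scatterplot inspection: a pair is flagged when
#' its robust Mahalanobis distance (minimum covariance determinant location
#' and scatter) exceeds the chi-squared(2) quantile at `cutoff`. A flagged
#' pair's value on each variable is replaced by the highest value among the
#' remaining observations on that variable — the "next-highest score" rule —
#' so a tied maximum is a no-op and the rank order of unflagged observations
#' never changes. At most `max_replace` pairs are replaced (most extreme
#' first).
#'
#' @param x,y paired numeric vectors, complete pairs only are screened.
#' @param cutoff chi-squared(2) probability for the distance cutoff
#'   (default 0.999).
#' @param max_replace cap on replacements (default 1, as a single problematic
#'   pair is the expected case).
#' @return List with `x`, `y` (possibly modified) and `report`, a data.frame
#'   of flagged indices, distances, and old/new values (zero rows when
#'   nothing was flagged).
#' @export
replace_bivariate_outlier <- function(x, y, cutoff = 0.999, max_replace = 1) {
  stopifnot(length(x) == length(y))
  ok <- which(complete.cases(x, y))
  if (length(ok) < 4) stop("need at least 4 complete pairs")
  xy <- cbind(x[ok], y[ok])
  rob <- tryCatch(MASS::cov.rob(xy, method = "mcd"),
                  error = function(e) MASS::cov.rob(xy, method = "classical"))
  d2 <- stats::mahalanobis(xy, rob$center, rob$cov)
  crit <- qchisq(cutoff, df = 2)
  flagged <- ok[d2 > crit]
  flagged <- flagged[order(-d2[d2 > crit])]
  if (length(flagged) > max_replace) flagged <- flagged[seq_len(max_replace)]
  report <- data.frame(index = integer(0), distance = numeric(0),
                       x_old = numeric(0), x_new = numeric(0),
                       y_old = numeric(0), y_new = numeric(0))
  for (i in flagged) {
    nx <- max(x[setdiff(ok, i)], na.rm = TRUE)
    ny <- max(y[setdiff(ok, i)], na.rm = TRUE)
    report <- rbind(report, data.frame(
      index = i, distance = d2[match(i, ok)],
      x_old = x[i], x_new = nx, y_old = y[i], y_new = ny))
    x[i] <- nx
    y[i] <- ny
  }
  report$criterion <- rep(sprintf("robust Mahalanobis > chisq(2, %.3f)",
                                  cutoff), nrow(report))
  list(x = x, y = y, report = report)
}
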