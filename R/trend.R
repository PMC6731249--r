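## Pooled contact-versus-ORE trend -------------------------------------------

#' Total primary-school other-group contact
#'
#' Unweighted mean of the available other-group primary components
#' (classmates, friends, neighbours). Participants missing some but not all
#' components get a partial average and are flagged; all-absent is `NA`.
#'
#' @param study a [study_table()] (or its participants data.frame).
#' @return data.frame with `participant_id`, `total_primary_contact`,
#'   `n_components`, `partial` (logical flag).
#' @export
total_primary_contact <- function(study) {
  df <- if (inherits(study, "study_table")) study$participants else study
  comp <- cbind(df$primary_classmates_other, df$primary_friends_other,
                df$primary_neighbours_other)
  k <- rowSums(!is.na(comp))
  tot <- rowMeans(comp, na.rm = TRUE)
  tot[k == 0] <- NA_real_
  data.frame(participant_id = df$participant_id,
             total_primary_contact = tot, n_components = k,
             partial = k > 0 & k < 3, stringsAsFactors = FALSE)
}

#' Fit the pooled contact-versus-effect trend
#'
#' Ordinary least squares of the ORE/OEE difference score on total primary
#' contact, pooled over samples (a single trendline, matching the design's
#' pooled plot; set `per_sample_intercept = TRUE` for a sample-fixed-effects
#' variant). The 95% band is the confidence interval for the conditional
#' mean (the trendline), not a prediction interval, and widens away from the
#' mean contact. The zero-crossing is the contact level at which the fitted
#' effect reaches zero, reported only when it falls within the observed
#' contact range, with a CI obtained by inverting the band.
#'
#' @param x contact percentages.
#' @param y difference scores (percentage points).
#' @param level band confidence level (default 0.95).
#' @param per_sample_intercept add sample intercepts; requires `sample`.
#' @param sample sample labels (only with `per_sample_intercept`).
#' @return A `trend_fit`: list with `slope`, `intercept`, `n`, `sigma`
#'   (residual SD), `r_squared`, `band(x)` (function returning fit, lower,
#'   upper), `zero_crossing` (`NA` if the slope is zero or the crossing lies
#'   outside the observed range), `zero_crossing_ci`, `model` (the `lm`).
#' @export
fit_trend <- function(x, y, level = 0.95, per_sample_intercept = FALSE,
                      sample = NULL) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("need n >= 10 complete pairs")
  if (length(unique(x)) < 2) stop("contact is constant: no trend to fit")
  if (per_sample_intercept) {
    if (is.null(sample)) stop("per_sample_intercept requires sample labels")
    sample <- factor(sample[ok])
    fit <- lm(y ~ x + sample)
  } else {
    fit <- lm(y ~ x)
  }
  slope <- unname(coef(fit)["x"])
  intercept <- unname(coef(fit)[1])
  band <- function(at) {
    nd <- data.frame(x = at)
    if (per_sample_intercept) nd$sample <- factor(levels(sample)[1],
                                                  levels = levels(sample))
    pr <- predict(fit, newdata = nd, interval = "confidence", level = level)
    data.frame(x = at, fit = pr[, "fit"], lower = pr[, "lwr"],
               upper = pr[, "upr"])
  }
  zc <- NA_real_
  zc_ci <- c(NA_real_, NA_real_)
  if (abs(slope) > .Machine$double.eps^0.5) {
    cand <- -intercept / slope
    if (cand >= min(x) && cand <= max(x)) {
      zc <- cand
      zc_ci <- zero_crossing_ci(band, range(x))
    }
  }
  sm <- suppressWarnings(summary(fit))  # "perfect fit" warning on exact data
  structure(list(slope = slope, intercept = intercept, n = n,
                 sigma = sm$sigma,
                 r_squared = sm$r.squared,
                 band = band, zero_crossing = zc, zero_crossing_ci = zc_ci,
                 x_range = range(x), level = level, model = fit),
            class = "trend_fit")
}

# invert the confidence band: contact values where the band limits cross zero
zero_crossing_ci <- function(band, xr) {
  grid <- seq(xr[1], xr[2], length.out = 512)
  b <- band(grid)
  cross <- function(v) {
    sgn <- sign(v)
    idx <- which(sgn[-1] * sgn[-length(sgn)] <= 0 & sgn[-1] != sgn[-length(sgn)])
    if (!length(idx)) return(NA_real_)
    i <- idx[1]
    # linear interpolation inside the bracketing interval
    grid[i] + (0 - v[i]) * (grid[i + 1] - grid[i]) / (v[i + 1] - v[i])
  }
  c(cross(b$lower), cross(b$upper))
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("trend: effect = %.3f %+.4f * contact%%  (n = %d, residual SD %.2f)\n",
              x$intercept, x$slope, x$n, x$sigma))
  if (!is.na(x$zero_crossing)) {
    cat(sprintf("fitted effect reaches zero at %.1f%% contact (band inversion: %s)\n",
                x$zero_crossing,
                paste(sprintf("%.1f", x$zero_crossing_ci), collapse = " to ")))
  } else {
    cat("fitted effect does not reach zero within the observed contact range\n")
  }
  invisible(x)
}

#' Pooled trend for a study table
#'
#' Convenience wrapper: total primary other-group contact against the
#' difference score, pooled over all samples with analysable primary contact.
#'
#' @param study a [study_table()].
#' @param ... passed to [fit_trend()].
#' @return A `trend_fit`.
#' @export
study_trend <- function(study, ...) {
  df <- study$participants
  tot <- total_primary_contact(study)$total_primary_contact
  fit_trend(tot, diff_score_vec(df), sample = df$sample, ...)
}
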