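## Gaussian-copula synthetic cohorts -----------------------------------------

#' Synthetic cohort configuration
#'
#' Describes the statistical world the analysis assumes: four independent
#' samples (default sizes 120/72/103/78, total 373, so the pooled
#' secondary-stage N is 223), zero-inflated right-skewed other-group contact
#' marginals (most skewed at primary school, with the Eastern-raised sample's
#' school-age other-group contact almost entirely zero), low-to-medium
#' cross-stage intercorrelation of contact, stage-specific contact effects on
#' the ORE/OEE (nonzero at primary only by default), 72-trial binomial test
#' noise around each participant's latent accuracy, and a contact-prejudice
#' link at secondary/adult.
#'
#' Contact variables share a latent Gaussian copula: each (stage, measure,
#' group) variable loads on its stage's exposure factor (own-group variables
#' with negative loading), `lambda2` is the within-stage latent correlation
#' between two same-group variables and `stage_corr` the factor correlation
#' across stages, so the latent correlation between same-group variables at
#' stages s and t is `lambda2 * stage_corr[s, t]`. For continuous (non
#' zero-inflated) marginals the implied Kendall tau is
#' `(2 / pi) * asin(latent correlation)`.
#'
#' @param n named per-sample sizes.
#' @param lambda2 within-stage latent correlation between same-group contact
#'   variables (default 0.55).
#' @param stage_corr 3x3 correlation matrix of the stage exposure factors
#'   (primary, secondary, adult). The default dissociates primary-school
#'   contact completely from the later stages (correlation 0) — the design's
#'   requirement that childhood and later contact not be confounded, taken
#'   strictly — while secondary and adult contact remain moderately related
#'   (0.45, observable same-measure tau about 0.16). Any degree of contact
#'   stability can be configured instead.
#' @param beta_own,beta_other stage-named contact effects on the difference
#'   score, in ORE points per 100% contact; defaults 24 (other-group) and 12
#'   (own-group) at primary, 0 at secondary and adult, sized to reproduce
#'   battery patterns with most primary cells individually significant at
#'   study-scale n.
#' @param ore_base baseline difference score (points) at zero other-group and
#'   nominal (80%) own-group contact.
#' @param ore_noise_sd SD (points) of latent outcome noise beyond the
#'   binomial trial noise.
#' @param own_mu,own_sd own-group accuracy distribution (percent).
#' @param prejudice_gamma prejudice points (1--9 scale) per unit proportion
#'   of secondary/adult other-group contact; `prejudice_noise_sd` its noise.
#' @param caucasian_primary_n how many Caucasian-sample participants have
#'   primary-stage contact data (the rest are missing, emulating the
#'   later-cohort restriction that gives the smaller primary-cell n).
#' @param marginals optional override of the per-(sample, group, stage)
#'   contact marginal table, see [default_contact_marginals()].
#' @param seed default seed used when [generate_cohort()] is not given one.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n = c(caucasian_western = 120,
                                   asian_eastern_raised = 72,
                                   asian_western_raised = 103,
                                   northern_european = 78),
                             lambda2 = 0.55,
                             stage_corr = default_stage_corr(),
                             beta_own = c(primary = 12, secondary = 0,
                                          adult = 0),
                             beta_other = c(primary = 24, secondary = 0,
                                            adult = 0),
                             ore_base = 12, ore_noise_sd = 7,
                             own_mu = 72, own_sd = 10,
                             prejudice_gamma = 4, prejudice_noise_sd = 1.5,
                             caucasian_primary_n = 57,
                             marginals = default_contact_marginals(),
                             seed = 1L) {
  stopifnot(all(fc_samples() %in% names(n)), all(n > 0),
            lambda2 > 0, lambda2 < 1,
            all(fc_stages() %in% names(beta_own)),
            all(fc_stages() %in% names(beta_other)))
  if (!isTRUE(all.equal(dim(stage_corr), c(3L, 3L)))) {
    stop("stage_corr must be 3x3")
  }
  ev <- eigen(stage_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("stage_corr is not positive definite")
  lat <- lambda2 * stage_corr
  diag(lat) <- 1
  if (min(eigen(lat, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
    stop("implied latent copula matrix is not positive definite")
  }
  structure(list(n = n[fc_samples()], lambda2 = lambda2,
                 stage_corr = stage_corr, beta_own = beta_own,
                 beta_other = beta_other, ore_base = ore_base,
                 ore_noise_sd = ore_noise_sd, own_mu = own_mu,
                 own_sd = own_sd, prejudice_gamma = prejudice_gamma,
                 prejudice_noise_sd = prejudice_noise_sd,
                 caucasian_primary_n = caucasian_primary_n,
                 marginals = marginals, seed = seed),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_stage_corr <- function() {
  matrix(c(1, 0, 0,
           0, 1, 0.45,
           0, 0.45, 1), 3, 3,
         dimnames = list(fc_stages(), fc_stages()))
}

#' Default contact marginal shapes
#'
#' One row per (sample, group, stage): a zero-inflation mass `pi0` and Beta
#' shape parameters for the continuous tail, scaled to 0--100 percent. The
#' defaults emulate the study's demographic shape: other-group contact is
#' right-skewed and most zero-inflated at primary school; the Eastern-raised
#' sample has near-total zero inflation for school-age other-group contact
#' (median 0%, hence excluded by the 10% range gate) but a wide adult range;
#' own-group contact is high and left-skewed; the Western-raised Asian
#' sample's pattern is mirrored (high other-group, lower own-group contact).
#'
#' @return data.frame with columns sample, group, stage, pi0, shape1, shape2.
#' @export
default_contact_marginals <- function() {
  rows <- list()
  add <- function(sample, group, stage, pi0, s1, s2) {
    rows[[length(rows) + 1]] <<- data.frame(
      sample = sample, group = group, stage = stage, pi0 = pi0,
      shape1 = s1, shape2 = s2, stringsAsFactors = FALSE)
  }
  # caucasian_western: other = Asian contact (low, skewed), own high
  add("caucasian_western", "other", "primary",   0.10, 1.5, 5.5)
  add("caucasian_western", "other", "secondary", 0.05, 1.8, 5)
  add("caucasian_western", "other", "adult",     0.00, 3.0, 3.5)
  add("caucasian_western", "own", "primary",     0.00, 6.0, 1.8)
  add("caucasian_western", "own", "secondary",   0.00, 6.0, 1.8)
  add("caucasian_western", "own", "adult",       0.00, 5.0, 2.0)
  # asian_eastern_raised: school-age Caucasian contact ~ zero; adult wide
  add("asian_eastern_raised", "other", "primary",   0.90, 1.0, 8)
  add("asian_eastern_raised", "other", "secondary", 0.85, 1.0, 6)
  add("asian_eastern_raised", "other", "adult",     0.00, 3.0, 2.5)
  add("asian_eastern_raised", "own", "primary",     0.00, 8.0, 1.2)
  add("asian_eastern_raised", "own", "secondary",   0.00, 8.0, 1.2)
  add("asian_eastern_raised", "own", "adult",       0.00, 2.5, 2.5)
  # asian_western_raised: raised among Caucasians
  add("asian_western_raised", "other", "primary",   0.00, 5.0, 1.8)
  add("asian_western_raised", "other", "secondary", 0.00, 5.0, 2.0)
  add("asian_western_raised", "other", "adult",     0.00, 4.0, 2.5)
  add("asian_western_raised", "own", "primary",     0.20, 1.2, 5)
  add("asian_western_raised", "own", "secondary",   0.10, 1.5, 5)
  add("asian_western_raised", "own", "adult",       0.00, 2.0, 4)
  # northern_european: other = Southern-European contact
  add("northern_european", "other", "primary",   0.10, 1.5, 5)
  add("northern_european", "other", "secondary", 0.08, 1.8, 5)
  add("northern_european", "other", "adult",     0.00, 2.5, 4)
  add("northern_european", "own", "primary",     0.00, 5.0, 1.5)
  add("northern_european", "own", "secondary",   0.00, 5.0, 1.5)
  add("northern_european", "own", "adult",       0.00, 5.0, 1.5)
  do.call(rbind, rows)
}

marginal_for <- function(marginals, sample, group, stage) {
  r <- marginals[marginals$sample == sample & marginals$group == group &
                   marginals$stage == stage, , drop = FALSE]
  if (nrow(r) != 1) stop("no marginal for ", sample, "/", group, "/", stage)
  r
}

# latent standard normal -> zero-inflated scaled-Beta percentage
zib_quantile <- function(u, pi0, shape1, shape2) {
  out <- numeric(length(u))
  tail <- u >= pi0
  out[tail] <- 100 * qbeta((u[tail] - pi0) / (1 - pi0), shape1, shape2)
  out
}

#' Generate a synthetic cohort
#'
#' Draws, per participant: stage exposure factors from the stage correlation
#' matrix; contact variables through the Gaussian copula and their
#' zero-inflated scaled-Beta marginals; own-group accuracy from the base
#' ability distribution; a structural difference score from the stage-specific
#' contact effects plus Gaussian noise; own/other correct counts as 72
#' Bernoulli trials around the latent accuracies (so percent-correct scoring
#' and reliability estimates are meaningful by construction); and a 1--9
#' willingness-to-marry prejudice item linked to secondary/adult other-group
#' contact. Fully reproducible from the seed.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param return_trials attach per-trial 0/1 matrices as the `"trials"`
#'   attribute (rows align with participants; counts are their row sums).
#' @return A [study_table()].
#' @export
generate_cohort <- function(config = synthetic_config(),
                            seed = config$seed, return_trials = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(as.integer(seed))
  lam <- sqrt(config$lambda2)
  resid <- sqrt(1 - config$lambda2)
  chol_stage <- chol(config$stage_corr)
  pct_measures <- c("classmates", "friends", "neighbours")
  tabs <- list()
  trials <- list(own = NULL, other = NULL)
  pid <- 0L
  for (smp in fc_samples()) {
    n <- config$n[[smp]]
    f <- matrix(rnorm(n * 3), n, 3) %*% chol_stage  # stage factors
    colnames(f) <- fc_stages()
    df <- data.frame(participant_id = sprintf("P%04d", pid + seq_len(n)),
                     sample = smp, stringsAsFactors = FALSE)
    pid <- pid + n
    other_avg <- matrix(0, n, 3, dimnames = list(NULL, fc_stages()))
    own_avg <- matrix(0, n, 3, dimnames = list(NULL, fc_stages()))
    for (st in fc_stages()) {
      for (g in c("own", "other")) {
        mg <- marginal_for(config$marginals, smp, g, st)
        sgn <- if (g == "other") 1 else -1
        vals <- matrix(NA_real_, n, length(pct_measures))
        for (k in seq_along(pct_measures)) {
          z <- sgn * lam * f[, st] + resid * rnorm(n)
          vals[, k] <- zib_quantile(pnorm(z), mg$pi0, mg$shape1, mg$shape2)
          df[[contact_col(st, pct_measures[k], g)]] <- vals[, k]
        }
        if (g == "other") other_avg[, st] <- rowMeans(vals)
        else own_avg[, st] <- rowMeans(vals)
        # questionnaire contact scale, 1-7, sharing the stage factor
        zq <- sgn * lam * f[, st] + resid * rnorm(n)
        qshape <- if (g == "other") c(1.5, 4) else c(4, 1.5)
        df[[contact_col(st, "questionnaire_scale", g)]] <-
          1 + 6 * qbeta(pnorm(zq), qshape[1], qshape[2])
      }
    }
    if (smp == "asian_eastern_raised") {
      zt <- 0.3 * f[, "adult"] + sqrt(1 - 0.09) * rnorm(n)
      months <- 1 + stats::qgamma(pnorm(zt), shape = 1.6, scale = 10)
      df$adult_time_in_west_other <- pmin(61, round(months, 1))
    }
    # structural difference score and test scores
    eff <- config$ore_base +
      colSums(config$beta_own[fc_stages()] * t(own_avg / 100 - 0.8)) -
      colSums(config$beta_other[fc_stages()] * t(other_avg / 100))
    ore_latent <- eff + rnorm(n, 0, config$ore_noise_sd)
    own_acc <- pmin(98, pmax(36, rnorm(n, config$own_mu, config$own_sd)))
    other_acc <- pmin(98, pmax(34, own_acc - ore_latent))
    tr_own <- matrix(rbinom(n * 72, 1, rep(own_acc / 100, each = 72)),
                     n, 72, byrow = TRUE)
    tr_other <- matrix(rbinom(n * 72, 1, rep(other_acc / 100, each = 72)),
                       n, 72, byrow = TRUE)
    df$own_correct <- rowSums(tr_own)
    df$other_correct <- rowSums(tr_other)
    if (return_trials) {
      trials$own <- rbind(trials$own, tr_own)
      trials$other <- rbind(trials$other, tr_other)
    }
    # prejudice: more secondary/adult other-group contact -> more willing
    base <- if (smp == "asian_western_raised") 4.5 else 3.5
    lp <- base + config$prejudice_gamma *
      (other_avg[, "secondary"] + other_avg[, "adult"]) / 200 +
      rnorm(n, 0, config$prejudice_noise_sd)
    df$prejudice <- pmin(9L, pmax(1L, as.integer(round(lp))))
    df$age_years <- round(pmin(45, pmax(17, rnorm(n, 21.1, 3.9))), 1)
    df$sex <- sample(c("female", "male"), n, replace = TRUE)
    tabs[[smp]] <- df
  }
  all_df <- do.call(rbind, lapply(tabs, function(d) {
    for (col in setdiff(canonical_cols(), names(d))) d[[col]] <- NA_real_
    d[, canonical_cols(), drop = FALSE]
  }))
  rownames(all_df) <- NULL
  # primary-cell restriction: only caucasian_primary_n Caucasians report
  # primary contact (emulates the later-cohort inclusion of that sample)
  cauc <- which(all_df$sample == "caucasian_western")
  n_missing <- length(cauc) - config$caucasian_primary_n
  if (n_missing > 0) {
    drop <- sample(cauc, n_missing)
    pcols <- grep("^primary_", canonical_cols(), value = TRUE)
    all_df[drop, pcols] <- NA_real_
  }
  out <- study_table(all_df, reject = FALSE)
  out <- score_study(out)
  if (return_trials) attr(out, "trials") <- trials
  out
}

#' Generate a null cohort
#'
#' As [generate_cohort()] but with every contact effect and the prejudice
#' link forced to zero: contact keeps its marginal shapes and
#' intercorrelations, the outcome is pure ability plus noise. Used for
#' calibration of the Monte-Carlo test.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @param ... passed to [generate_cohort()].
#' @return A [study_table()].
#' @export
null_cohort <- function(config = synthetic_config(), seed = config$seed,
                        ...) {
  z <- c(primary = 0, secondary = 0, adult = 0)
  config$beta_own <- z
  config$beta_other <- z
  config$prejudice_gamma <- 0
  generate_cohort(config, seed = seed, ...)
}
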