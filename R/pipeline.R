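## End-to-end pipeline --------------------------------------------------------

#' Pipeline configuration
#'
#' @param input path to a participant CSV/TSV, or `NULL` to simulate a
#'   cohort from `sim_config`.
#' @param schema optional schema mapping for `input`, see [read_schema()].
#' @param sim_config a [synthetic_config()] used when `input` is `NULL`.
#' @param stages life stages to analyse.
#' @param outcome battery outcome, see [default_battery_spec()].
#' @param n_runs Monte-Carlo runs per stage.
#' @param seed master seed: recorded in every output; stage s uses
#'   `seed + index(s)` for its Monte-Carlo stream.
#' @param ordering evidence ordering, see [at_least_as_strong()].
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, schema = NULL,
                       sim_config = synthetic_config(),
                       stages = fc_stages(),
                       outcome = "difference_score",
                       n_runs = 1e5, seed = 1L, ordering = "lex",
                       out_dir = NULL) {
  if (!is.null(input) && !file.exists(input)) {
    stop("input file not found: ", input)
  }
  stopifnot(all(stages %in% fc_stages()))
  structure(list(input = input, schema = schema, sim_config = sim_config,
                 stages = stages, outcome = outcome, n_runs = n_runs,
                 seed = as.integer(seed), ordering = ordering,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Reads (or simulates) a cohort, then per requested stage: runs the
#' skew-gated correlation battery, encodes the evidence pattern, and computes
#' the condition-wise Monte-Carlo p-value; adds the stage-dissociation
#' diagnostic table, the pooled primary-contact trend fit, and the
#' contact-prejudice validation battery. Deterministic given the seed. When
#' `out_dir` is set, writes per-stage battery CSVs, an `evidence.json`, a
#' dissociation CSV, a trend JSON and a plain-text log.
#'
#' @param config a [run_config()].
#' @return A `report_bundle`: list with `study`, `batteries`, `evidence`
#'   (per-stage `mc_result`s), `dissociation`, `trend`, `prejudice`,
#'   `config`, `log`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  say("facecontact %s | seed %d | %s",
      as.character(utils::packageVersion("facecontact")), config$seed,
      format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  study <- if (is.null(config$input)) {
    say("simulating cohort (seed %d)", config$seed)
    generate_cohort(config$sim_config, seed = config$seed)
  } else {
    say("reading %s", config$input)
    score_study(read_study_table(config$input, schema = config$schema))
  }
  say("cohort: %d participants in %d samples", nrow(study$participants),
      length(unique(study$participants$sample)))

  spec <- default_battery_spec(outcome = config$outcome)
  batteries <- list(); evidence <- list()
  for (st in config$stages) {
    plan <- battery_plan(study, st, spec)
    if (!length(plan$samples)) {
      say("stage %s: no analysable cells", st)
      next
    }
    mc <- monte_carlo_p(study, st, spec, n_runs = config$n_runs,
                        seed = config$seed + match(st, fc_stages()),
                        ordering = config$ordering, plan = plan)
    batteries[[st]] <- mc$battery
    evidence[[st]] <- mc
    for (i in seq_len(nrow(plan$exclusions))) {
      say("stage %s: excluded %s %s/%s: %s", st, plan$exclusions$sample[i],
          plan$exclusions$measure[i], plan$exclusions$group[i],
          plan$exclusions$reason[i])
    }
    say("stage %s: pattern %d/%d direction, %d significant, %d approaching; p %s%g (%d runs)",
        st, mc$observed$d, mc$observed$m, mc$observed$s, mc$observed$a,
        if (mc$censored) "< " else "= ", mc$p_value, mc$n_runs)
  }

  dissoc <- dissociation_table(study)
  trend <- tryCatch(study_trend(study), error = function(e) {
    say("trend fit skipped: %s", conditionMessage(e)); NULL
  })
  prejudice <- tryCatch({
    pspec <- default_battery_spec(outcome = "prejudice")
    do.call(rbind, lapply(intersect(c("secondary", "adult"), config$stages),
                          function(st) run_battery(study, st, pspec)))
  }, error = function(e) {
    say("prejudice validation skipped: %s", conditionMessage(e)); NULL
  })

  bundle <- structure(list(study = study, batteries = batteries,
                           evidence = evidence, dissociation = dissoc,
                           trend = trend, prejudice = prejudice,
                           config = config, log = log),
                      class = "report_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

evidence_as_list <- function(mc) {
  list(observed = mc$observed[c("m", "d", "s", "a")],
       p_value = mc$p_value, censored = mc$censored,
       n_runs = mc$n_runs, n_qualifying = mc$n_qualifying,
       mc_se = mc$mc_se, seed = mc$seed, ordering = mc$ordering)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (st in names(bundle$batteries)) {
    write_table(bundle$batteries[[st]],
                file.path(dir, paste0("battery_", st, ".csv")))
  }
  ev <- lapply(bundle$evidence, evidence_as_list)
  ev$seed <- bundle$config$seed
  jsonlite::write_json(ev, file.path(dir, "evidence.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(bundle$dissociation)) {
    write_table(bundle$dissociation, file.path(dir, "dissociation.csv"))
  }
  if (!is.null(bundle$trend)) {
    tr <- bundle$trend
    jsonlite::write_json(
      list(slope = tr$slope, intercept = tr$intercept, n = tr$n,
           sigma = tr$sigma, r_squared = tr$r_squared,
           zero_crossing = tr$zero_crossing,
           zero_crossing_ci = tr$zero_crossing_ci,
           x_range = tr$x_range, level = tr$level),
      file.path(dir, "trend.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  if (!is.null(bundle$prejudice)) {
    write_table(bundle$prejudice, file.path(dir, "prejudice.csv"))
  }
  writeLines(bundle$log, file.path(dir, "pipeline.log"))
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  for (st in names(x$evidence)) {
    mc <- x$evidence[[st]]
    cat(sprintf("  %-9s m=%2d d=%2d s=%2d a=%2d  p %s%g\n", st,
                mc$observed$m, mc$observed$d, mc$observed$s, mc$observed$a,
                if (mc$censored) "< " else "= ", mc$p_value))
  }
  if (!is.null(x$trend)) {
    cat(sprintf("  trend: slope %.3f, intercept %.2f (n=%d)\n",
                x$trend$slope, x$trend$intercept, x$trend$n))
  }
  invisible(x)
}
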