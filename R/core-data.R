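## Domain vocabulary ---------------------------------------------------------

#' Study vocabulary: samples, life stages, contact measures
#'
#' The design compares four independent observer samples, three life stages at
#' which social contact is self-reported, and five contact measures. Classmates
#' and friends require individuation of faces; neighbourhood exposure is
#' incidental; the questionnaire scale is a multi-item contact score; months in
#' the West exists only as adult other-group contact of observers raised in a
#' majority-own-race country.
#'
#' @return Character vector of level names, in canonical order.
#' @export
fc_samples <- function() {
  c("caucasian_western", "asian_eastern_raised",
    "asian_western_raised", "northern_european")
}

#' @rdname fc_samples
#' @export
fc_stages <- function() c("primary", "secondary", "adult")

#' @rdname fc_samples
#' @export
fc_measures <- function() {
  c("classmates", "friends", "neighbours", "questionnaire_scale",
    "time_in_west")
}

#' Canonical contact column name
#'
#' The on-disk layout is wide, one column per (stage, measure, group) triple,
#' named `<stage>_<measure>_<group>`, e.g. `primary_classmates_other`.
#'
#' @param stage life stage, see [fc_stages()].
#' @param measure contact measure, see [fc_measures()].
#' @param group `"own"` or `"other"` group relation.
#' @return Character vector of column names.
#' @export
contact_col <- function(stage, measure, group) {
  stopifnot(all(stage %in% fc_stages()), all(measure %in% fc_measures()),
            all(group %in% c("own", "other")))
  bad <- measure == "time_in_west" & !(stage == "adult" & group == "other")
  if (any(bad)) {
    stop("time_in_west exists only for adult stage, other-group relation")
  }
  paste(stage, measure, group, sep = "_")
}

all_contact_cols <- function() {
  cols <- character(0)
  for (st in fc_stages()) {
    for (m in setdiff(fc_measures(), "time_in_west")) {
      for (g in c("own", "other")) cols <- c(cols, paste(st, m, g, sep = "_"))
    }
  }
  c(cols, "adult_time_in_west_other")
}

score_cols <- function() c("own_correct", "other_correct", "own_pct", "other_pct")

canonical_cols <- function() {
  c("participant_id", "sample", score_cols(), all_contact_cols(),
    "prejudice", "age_years", "sex")
}

## Sample metadata -----------------------------------------------------------

#' Default sample-level metadata
#'
#' Which face-memory variant is the own-group versus other-group test for each
#' sample, and whether the difference score is called an other-race effect
#' (ORE) or other-ethnicity effect (OEE).
#'
#' @return A data.frame with one row per sample.
#' @export
default_sample_meta <- function() {
  data.frame(
    sample = fc_samples(),
    outcome_name = c("ORE", "ORE", "ORE", "OEE"),
    own_test = c("cfmt_australian", "cfmt_chinese", "cfmt_chinese",
                 "cfmt_australian"),
    other_test = c("cfmt_chinese", "cfmt_australian", "cfmt_australian",
                   "cfmt_original"),
    stringsAsFactors = FALSE
  )
}

## StudyTable ----------------------------------------------------------------

#' Construct a validated study table
#'
#' A `study_table` holds one row per participant in the canonical wide layout
#' plus sample-level metadata. Hard invariant violations (counts outside
#' 0--72, percentages outside 0--100, prejudice outside 1--9, unknown sample,
#' duplicated id) reject the offending row with a per-row diagnostic; missing
#' values stay missing and are handled listwise per analysis, never imputed.
#'
#' @param participants data.frame in canonical wide layout; missing canonical
#'   columns are added as `NA`.
#' @param meta sample-level metadata, see [default_sample_meta()].
#' @param reject if `TRUE` (default) invalid rows are dropped and reported in
#'   the `"rejected"` attribute; if `FALSE` any invalid row is an error.
#' @return An object of class `study_table`: a list with elements
#'   `participants` (data.frame) and `meta`, plus a `"rejected"` attribute
#'   (data.frame of row index and diagnostic message, possibly empty).
#' @export
study_table <- function(participants, meta = default_sample_meta(),
                        reject = TRUE) {
  stopifnot(is.data.frame(participants))
  df <- as.data.frame(participants, stringsAsFactors = FALSE)
  if (!"participant_id" %in% names(df)) stop("participant_id column required")
  if (!"sample" %in% names(df)) stop("sample column required")
  df$participant_id <- as.character(df$participant_id)
  if (anyDuplicated(df$participant_id)) {
    stop("duplicated participant_id: ",
         paste(unique(df$participant_id[duplicated(df$participant_id)]),
               collapse = ", "))
  }
  for (col in setdiff(canonical_cols(), names(df))) {
    df[[col]] <- if (col == "sex") NA_character_ else NA_real_
  }
  extra <- setdiff(names(df), canonical_cols())
  df <- df[, c(canonical_cols(), extra), drop = FALSE]
  # stable column types regardless of source (all-NA columns parse as logical)
  for (col in setdiff(canonical_cols(), c("participant_id", "sample", "sex"))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$sample <- as.character(df$sample)
  df$sex <- as.character(df$sex)

  # derive percentages from counts where absent
  for (side in c("own", "other")) {
    cnt <- df[[paste0(side, "_correct")]]
    pct <- df[[paste0(side, "_pct")]]
    fill <- is.na(pct) & !is.na(cnt)
    df[[paste0(side, "_pct")]][fill] <- 100 * cnt[fill] / 72
  }

  diag <- validate_rows(df)
  if (nrow(diag) > 0 && !reject) {
    stop("invalid rows: ", paste(diag$message, collapse = "; "))
  }
  if (nrow(diag) > 0) df <- df[-diag$row, , drop = FALSE]
  rownames(df) <- NULL
  out <- structure(list(participants = df, meta = meta),
                   class = "study_table")
  attr(out, "rejected") <- diag
  out
}

validate_rows <- function(df) {
  msgs <- character(0); rows <- integer(0)
  flag <- function(bad, text) {
    bad <- which(!is.na(bad) & bad)
    if (length(bad)) {
      rows <<- c(rows, bad)
      msgs <<- c(msgs, sprintf("row %d [%s]: %s", bad, df$participant_id[bad],
                               text))
    }
  }
  flag(!df$sample %in% fc_samples(), "unknown sample label")
  for (col in c("own_correct", "other_correct")) {
    v <- df[[col]]
    flag(v < 0 | v > 72 | (v %% 1 != 0), paste(col, "outside 0..72"))
  }
  for (col in c("own_pct", "other_pct")) {
    flag(df[[col]] < 0 | df[[col]] > 100, paste(col, "outside 0..100"))
  }
  pct_cols <- setdiff(all_contact_cols(),
                      grep("time_in_west|questionnaire", all_contact_cols(),
                           value = TRUE))
  for (col in pct_cols) {
    flag(df[[col]] < 0 | df[[col]] > 100, paste(col, "outside 0..100"))
  }
  flag(df$adult_time_in_west_other < 0, "time in West negative")
  flag(df$prejudice < 1 | df$prejudice > 9 | (df$prejudice %% 1 != 0),
       "prejudice outside 1..9")
  if (length(rows)) {
    d <- data.frame(row = rows, message = msgs, stringsAsFactors = FALSE)
    d <- d[!duplicated(d$row), , drop = FALSE]
    d[order(d$row), , drop = FALSE]
  } else {
    data.frame(row = integer(0), message = character(0))
  }
}

#' @export
print.study_table <- function(x, ...) {
  n <- table(factor(x$participants$sample, levels = fc_samples()))
  cat("<study_table> ", nrow(x$participants), " participants\n", sep = "")
  for (s in names(n)) cat("  ", s, ": n = ", n[[s]], "\n", sep = "")
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej) > 0) {
    cat("  (", nrow(rej), " rows rejected at validation)\n", sep = "")
  }
  invisible(x)
}

#' Per-sample participant subsets
#'
#' @param study a [study_table()].
#' @param sample sample label.
#' @return data.frame of participants in that sample.
#' @export
sample_rows <- function(study, sample) {
  stopifnot(inherits(study, "study_table"), sample %in% fc_samples())
  study$participants[study$participants$sample == sample, , drop = FALSE]
}

## I/O -----------------------------------------------------------------------

#' Read a schema mapping file
#'
#' Flat `canonical = source_column` key-value text (INI style; `#` comments).
#' Used to map arbitrary source layouts — including the deposited per-stage
#' spreadsheets, whatever their headers — onto the canonical wide layout.
#'
#' @param path file path.
#' @return Named character vector: names are canonical columns, values the
#'   source column names.
#' @export
read_schema <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=:]+)[=:](.+)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed schema line: ", lines[bad][1])
  out <- vapply(kv, function(m) trimws(m[3]), "")
  names(out) <- vapply(kv, function(m) trimws(m[2]), "")
  unknown <- setdiff(names(out), canonical_cols())
  if (length(unknown)) {
    stop("schema maps unknown canonical columns: ",
         paste(unknown, collapse = ", "))
  }
  out
}

#' Read participant data into a study table
#'
#' Reads CSV/TSV (delimiter inferred from the extension, `.tsv` means tab)
#' with empty cells and `"NA"` both treated as missing. An optional schema
#' maps source column names onto the canonical layout; percentages may be
#' supplied directly or derived from counts of correct trials out of 72.
#'
#' @param path file path.
#' @param schema `NULL` for already-canonical headers, a named character
#'   vector as returned by [read_schema()], or a path to a schema file.
#' @param meta sample-level metadata.
#' @param reject drop-and-report invalid rows (default) or error.
#' @return A [study_table()]; rejected rows are in `attr(, "rejected")`.
#' @export
read_study_table <- function(path, schema = NULL,
                             meta = default_sample_meta(), reject = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"), check.names = FALSE)
  if (is.character(schema) && length(schema) == 1 && is.null(names(schema))) {
    schema <- read_schema(schema)
  }
  if (!is.null(schema)) {
    missing_src <- setdiff(unname(schema), names(df))
    if (length(missing_src)) {
      stop("schema references absent columns: ",
           paste(missing_src, collapse = ", "))
    }
    df <- df[, unname(schema), drop = FALSE]
    names(df) <- names(schema)
  }
  study_table(df, meta = meta, reject = reject)
}

#' Write a study table or results table to CSV
#'
#' Stable canonical column order for study tables; RFC-4180-style quoting;
#' missing values written as empty cells so they survive a round trip.
#'
#' @param x a [study_table()] or plain data.frame.
#' @param path output path (`.tsv` extension writes tab-separated).
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  df <- if (inherits(x, "study_table")) x$participants else as.data.frame(x)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  # round-trip-exact numeric formatting (17 significant digits)
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      v <- sprintf("%.17g", df[[col]])
      v[is.na(df[[col]])] <- NA_character_
      df[[col]] <- v
    }
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, row.names = FALSE, na = "",
                       qmethod = "double")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}
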