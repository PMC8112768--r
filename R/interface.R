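# Input validation with actionable guidance, and results output.

report_entry <- function(severity, code, message, rows = integer()) {
  data.frame(severity = severity, code = code, message = message,
             rows = paste(utils::head(rows, 20), collapse = ","),
             stringsAsFactors = FALSE)
}

#' Validate a recall dataset before analysis
#'
#' Checks the dataset for the problems that would invalidate the model:
#' missing required columns, non-positive weights, negative or missing
#' intakes, duplicated recall indices, too many zero person-days for a
#' "nearly-daily" component, inconsistent replicate weights, person-level
#' columns varying within person, and (when a reference table is supplied)
#' persons with no matching reference row. Every failure carries a
#' corrective hint. The function always returns a report; the pipeline
#' refuses to run when `passed` is `FALSE`.
#'
#' @param data a [recall_data()] (construction already enforces the hard
#'   invariants; this reports the soft ones too). To validate a raw
#'   data.frame, build the object first — constructor errors are the same
#'   checks with the same messages.
#' @param refs optional [reference_table()] to check coverage against.
#' @param zero_threshold maximum tolerated share of zero-intake person-days
#'   (default 0.05).
#' @param sex_col,age_col,status_col columns used for reference matching.
#' @return list of class `validation_report` with `entries` (data.frame of
#'   severity/code/message/rows) and `passed`.
#' @export
validate_input <- function(data, refs = NULL, zero_threshold = 0.05,
                           sex_col = "sex", age_col = "age",
                           status_col = NULL) {
  stopifnot(inherits(data, "recall_data"))
  df <- data$recalls
  v <- data$vars
  entries <- list()
  add <- function(e) entries[[length(entries) + 1]] <<- e

  neg <- which(df[[v$intake]] < 0)
  if (length(neg))
    add(report_entry("error", "negative_intake",
                     "negative intakes found; correct or remove these rows",
                     neg))
  zero_share <- mean(df[[v$intake]] == 0)
  if (zero_share > zero_threshold)
    add(report_entry("error", "not_nearly_daily", sprintf(
      paste0("%.1f%% of person-days report zero intake (threshold %.1f%%). ",
             "This component is episodically consumed and cannot be ",
             "analysed with the amount-only model; restrict to nearly-",
             "daily components or use an episodic two-part model."),
      100 * zero_share, 100 * zero_threshold)))
  else if (zero_share > 0)
    add(report_entry("warning", "some_zero_days", sprintf(
      paste0("%.1f%% zero person-days; an offset of half the smallest ",
             "positive intake will be applied before transforming."),
      100 * zero_share)))

  if (!is.null(v$weight)) {
    bad_w <- which(!is.finite(df[[v$weight]]) | df[[v$weight]] <= 0)
    if (length(bad_w))
      add(report_entry("error", "nonpositive_weight",
                       "survey weights must be strictly positive", bad_w))
  } else {
    add(report_entry("warning", "no_weights",
                     "no survey-weight column declared; equal weights assumed"))
  }

  # person-level columns must be constant within person
  pl_cols <- c(v$weight, v$stratum, v$psu, v$repweights)
  for (cc in pl_cols) {
    nvals <- tapply(df[[cc]], df[[v$person]],
                    function(x) length(unique(x)))
    if (any(nvals > 1))
      add(report_entry("error", "varying_person_column", paste0(
        "column '", cc, "' varies within person; person-level columns ",
        "must be constant across a person's recalls")))
  }

  if (!is.null(v$repweights)) {
    rw <- person_table(data)[v$repweights]
    if (any(!is.finite(as.matrix(rw))) || any(as.matrix(rw) < 0))
      add(report_entry("error", "bad_replicate_weights",
                       "replicate weights must be finite and >= 0"))
  }

  if (!is.null(refs)) {
    pt <- person_table(data)
    if (!all(c(sex_col, age_col) %in% names(pt))) {
      add(report_entry("error", "missing_reference_columns", paste0(
        "reference matching needs columns '", sex_col, "' and '", age_col,
        "' on the dataset")))
    } else {
      hit <- tryCatch({
        match_reference(pt[[sex_col]], pt[[age_col]], refs,
                        status = if (!is.null(status_col)) pt[[status_col]])
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(hit))
        add(report_entry("error", "reference_coverage", paste0(
          hit, " — add rows to the reference table or correct the ",
          "person attributes")))
    }
  }

  rec_per_person <- tabulate(factor(df[[v$person]]))
  if (max(rec_per_person) < 2L)
    add(report_entry("warning", "single_day_only", paste0(
      "every person has a single recall; the repeated-recall model cannot ",
      "run — supply an external within:between variance ratio and use the ",
      "one-day mode")))

  entries <- if (length(entries)) do.call(rbind, entries) else
    data.frame(severity = character(), code = character(),
               message = character(), rows = character(),
               stringsAsFactors = FALSE)
  structure(list(entries = entries,
                 passed = !any(entries$severity == "error")),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", if (x$passed) "PASS" else "FAIL", "\n",
      sep = "")
  if (nrow(x$entries)) {
    for (i in seq_len(nrow(x$entries))) {
      e <- x$entries[i, ]
      cat(sprintf("  [%s] %s: %s", toupper(e$severity), e$code, e$message))
      if (nzchar(e$rows)) cat(" (rows ", e$rows, ")", sep = "")
      cat("\n")
    }
  } else cat("  no findings\n")
  invisible(x)
}

#' Write a results table to CSV
#'
#' Writes two files: the rounded report at `path` (1 decimal for
#' percentages, `intake_digits` decimals for intake-scale statistics) and a
#' raw full-precision companion at `<path minus .csv>_raw.csv`. Columns are
#' fixed: `scenario`, `subgroup`, `statistic`, `estimate`, `se`, `ci_lo`,
#' `ci_hi`; SE/CI cells are empty (not zero) when no replication ran.
#'
#' @param results a `results_table` from [run_with_uncertainty()], or a
#'   [distribution_summary()] (converted, with empty SE columns).
#' @param path output CSV path.
#' @param intake_digits decimals for intake-scale values (default 1).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, intake_digits = 1) {
  if (inherits(results, "distribution_summary")) {
    df <- as.data.frame(results)
    stat_cols <- setdiff(names(df), c("subgroup", "n"))
    long <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
      data.frame(scenario = "base", subgroup = df$subgroup[i],
                 statistic = c("n", stat_cols),
                 estimate = c(df$n[i], unlist(df[i, stat_cols])),
                 se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                 stringsAsFactors = FALSE)
    }))
    results <- long
  }
  stopifnot(is.data.frame(results), nrow(results) > 0,
            all(c("scenario", "subgroup", "statistic", "estimate", "se",
                  "ci_lo", "ci_hi") %in% names(results)))
  raw_path <- sub("\\.csv$", "_raw.csv", path)
  if (identical(raw_path, path)) raw_path <- paste0(path, "_raw.csv")
  utils::write.csv(as.data.frame(results), raw_path, row.names = FALSE)
  rounded <- as.data.frame(results)
  is_pct <- grepl("(_pct$)|(^below_)|(^above_)", rounded$statistic)
  for (cc in c("estimate", "se", "ci_lo", "ci_hi")) {
    rounded[[cc]] <- ifelse(is_pct, round(rounded[[cc]], 1),
                            round(rounded[[cc]], intake_digits))
  }
  utils::write.csv(rounded, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Records full provenance of a run: root seed, selected transform,
#' variance components, pseudo-person count, quadrature nodes and scenario
#' labels.
#'
#' @param fit a `usual_intake_fit`.
#' @param path output JSON path.
#' @param scenarios optional scenario list to record.
#' @export
write_manifest <- function(fit, path, scenarios = list()) {
  stopifnot(inherits(fit, "usual_intake_fit"))
  manifest <- list(
    seed = fit$seed,
    lambda = fit$transform$lambda,
    offset = fit$transform$offset,
    sigma2_between = fit$model$sigma2_between,
    sigma2_within = fit$model$sigma2_within,
    variance_ratio_used = fit$model$variance_ratio_used,
    m = fit$m,
    n_nodes = fit$n_nodes,
    converged = fit$model$converged,
    scenarios = vapply(scenarios, function(x) x$label, character(1)),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
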