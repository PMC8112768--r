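# Recall-survey data container: one row per person-recall, with per-person
# survey weights, design identifiers and optional replicate weights.

#' Construct a recall dataset
#'
#' Bundles a person-recall table (one row per 24-h recall) with the column
#' roles the estimation pipeline needs: the person identifier, the recall
#' sequence number, the nutrient intake, the survey weight, model covariates,
#' design identifiers and optional fortifiable-vehicle and replicate-weight
#' columns. Person-level columns (weight, covariates, stratum, PSU, replicate
#' weights) must be constant within person.
#'
#' @param recalls data.frame with at least the person, recall and intake
#'   columns. Missing intake rows are not allowed.
#' @param person,recall,intake names of the identifier, recall-index and
#'   intake columns.
#' @param weight name of the survey-weight column, or `NULL` for equal
#'   weights.
#' @param covariates character vector of covariate column names available to
#'   the model (person-level, or recall-level such as a weekend flag).
#' @param stratum,psu names of the design-identifier columns (optional; used
#'   by balanced repeated replication).
#' @param vehicles names of fortifiable-vehicle columns (grams/day).
#' @param repweights names of pre-computed replicate-weight columns, or
#'   `NULL`.
#' @return an object of class `recall_data`.
#' @export
recall_data <- function(recalls, person = "person_id", recall = "recall_index",
                        intake = "intake", weight = NULL,
                        covariates = character(), stratum = NULL, psu = NULL,
                        vehicles = character(), repweights = NULL) {
  stopifnot(is.data.frame(recalls))
  recalls <- as.data.frame(recalls, stringsAsFactors = FALSE)
  needed <- c(person, recall, intake, weight, covariates, stratum, psu,
              vehicles, repweights)
  missing_cols <- setdiff(needed, names(recalls))
  if (length(missing_cols))
    stop("recall table is missing column(s): ",
         paste(missing_cols, collapse = ", "),
         ". Expected headers include person, recall index, intake and any ",
         "declared weight/covariate/design columns.", call. = FALSE)
  if (anyNA(recalls[[intake]]))
    stop("missing intake values in rows: ",
         paste(utils::head(which(is.na(recalls[[intake]])), 10), collapse = ", "),
         call. = FALSE)
  x <- structure(list(
    recalls = recalls,
    vars = list(person = person, recall = recall, intake = intake,
                weight = weight, covariates = covariates,
                stratum = stratum, psu = psu, vehicles = vehicles,
                repweights = repweights)
  ), class = "recall_data")
  check_recall_data(x)
  x
}

# hard invariants; richer diagnostics live in validate_input()
check_recall_data <- function(x) {
  df <- x$recalls; v <- x$vars
  if (nrow(df) == 0L) stop("recall table has no rows", call. = FALSE)
  if (any(!is.finite(df[[v$intake]])) || any(df[[v$intake]] < 0))
    stop("intakes must be finite and non-negative; offending rows: ",
         paste(utils::head(which(!is.finite(df[[v$intake]]) |
                                   df[[v$intake]] < 0), 10), collapse = ", "),
         call. = FALSE)
  dup <- duplicated(df[c(v$person, v$recall)])
  if (any(dup))
    stop("recall_index is not unique within person; duplicated rows: ",
         paste(utils::head(which(dup), 10), collapse = ", "), call. = FALSE)
  if (!is.null(v$weight)) {
    w <- person_table(x)[[v$weight]]
    if (any(!is.finite(w)) || any(w <= 0))
      stop("survey weights must be strictly positive", call. = FALSE)
  }
  invisible(x)
}

#' Number of persons and recalls
#' @param x a `recall_data` object.
#' @return integer count.
#' @export
n_persons <- function(x) length(unique(x$recalls[[x$vars$person]]))

#' @rdname n_persons
#' @export
n_recalls <- function(x) nrow(x$recalls)

#' One row per person (first recall), carrying person-level columns
#' @noRd
person_table <- function(x) {
  df <- x$recalls
  v <- x$vars
  o <- order(df[[v$person]], df[[v$recall]])
  df <- df[o, , drop = FALSE]
  df[!duplicated(df[[v$person]]), , drop = FALSE]
}

#' Per-person survey weights (equal weights when none declared)
#' @noRd
person_weights <- function(x) {
  pt <- person_table(x)
  if (is.null(x$vars$weight)) rep(1, nrow(pt)) else pt[[x$vars$weight]]
}

#' Replace the per-person survey weight (used by replication)
#'
#' Persons assigned zero weight (classical BRR drops, bootstrap
#' non-selections) are removed from the replicate dataset.
#' @noRd
set_person_weights <- function(x, w, ids = NULL) {
  v <- x$vars
  pt <- person_table(x)
  ids <- ids %||% pt[[v$person]]
  stopifnot(length(w) == length(ids))
  if (is.null(v$weight)) {
    x$vars$weight <- ".weight"
    v <- x$vars
  }
  x$recalls[[v$weight]] <- w[match(x$recalls[[v$person]], ids)]
  keep <- x$recalls[[v$weight]] > 0
  x$recalls <- x$recalls[keep, , drop = FALSE]
  x
}

#' @export
print.recall_data <- function(x, ...) {
  v <- x$vars
  cat("<recall_data> ", n_persons(x), " persons, ", n_recalls(x),
      " recalls\n", sep = "")
  cat("  intake column: ", v$intake,
      if (!is.null(v$weight)) paste0(" | weights: ", v$weight), "\n", sep = "")
  if (length(v$covariates))
    cat("  covariates: ", paste(v$covariates, collapse = ", "), "\n", sep = "")
  if (!is.null(v$stratum))
    cat("  design: stratum = ", v$stratum, ", psu = ",
        v$psu %||% "<none>", "\n", sep = "")
  if (length(v$repweights))
    cat("  replicate weights: ", length(v$repweights), " columns\n", sep = "")
  invisible(x)
}

#' Read a recall dataset from CSV
#'
#' Expects one row per person-recall with a header; columns `person_id`,
#' `recall_index`, `intake` by default, fortifiable vehicles as
#' `vehicle_<name>`, replicate weights as `repw_1 ... repw_R`, and any
#' declared covariate/design columns. Empty cells are treated as missing.
#'
#' @inheritParams recall_data
#' @param path CSV file path.
#' @return a `recall_data` object.
#' @export
read_recalls <- function(path, person = "person_id", recall = "recall_index",
                         intake = "intake", weight = NULL,
                         covariates = character(), stratum = NULL, psu = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  vehicles <- grep("^vehicle_", names(df), value = TRUE)
  repw <- grep("^repw_[0-9]+$", names(df), value = TRUE)
  if (length(repw))
    repw <- repw[order(as.integer(sub("^repw_", "", repw)))]
  if (is.null(weight) && "weight" %in% names(df)) weight <- "weight"
  if (is.null(stratum) && "stratum" %in% names(df)) stratum <- "stratum"
  if (is.null(psu) && "psu" %in% names(df)) psu <- "psu"
  recall_data(df, person = person, recall = recall, intake = intake,
              weight = weight, covariates = covariates, stratum = stratum,
              psu = psu, vehicles = vehicles,
              repweights = if (length(repw)) repw else NULL)
}

#' Write a recall dataset to CSV (round-trips through [read_recalls()])
#' @param x a `recall_data` object.
#' @param path output file.
#' @export
write_recalls <- function(x, path) {
  utils::write.csv(x$recalls, path, row.names = FALSE)
  invisible(path)
}
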