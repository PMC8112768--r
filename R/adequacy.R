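# Prevalence of inadequate / excessive intake: EAR cut-point method with
# person-specific reference values, and the full-probability method with
# tabulated (possibly asymmetric) requirement distributions.

#' Reference table of EARs and ULs
#'
#' One row per sex / age-interval / physiological-status group. Age
#' intervals are half-open `(age_min, age_max]`: a row with
#' `age_min = 50, age_max = 150` matches ">50 y" and a 55-year-old falls in
#' it, while `age_min = 18, age_max = 50` matches "19-50 y (<=50)". Intervals
#' within a sex/status must not overlap, and `ear < ul` wherever both are
#' present (`ul` may be `NA` for nutrients without an upper level).
#'
#' @param df data.frame with columns `sex`, `age_min`, `age_max`, `status`,
#'   `ear` and optionally `ul` (intake units/day).
#' @return data.frame of class `reference_table`.
#' @export
reference_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sex", "age_min", "age_max", "ear")
  if (!all(need %in% names(df)))
    stop("reference table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"status" %in% names(df)) df$status <- "none"
  if (!"ul" %in% names(df)) df$ul <- NA_real_
  stopifnot(all(df$age_min < df$age_max), all(df$ear > 0))
  bad <- !is.na(df$ul) & df$ul <= df$ear
  if (any(bad))
    stop("ul must exceed ear; offending rows: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  for (key in split(seq_len(nrow(df)), paste(df$sex, df$status))) {
    if (length(key) < 2) next
    iv <- df[key, c("age_min", "age_max")]
    iv <- iv[order(iv$age_min), ]
    if (any(iv$age_min[-1] < iv$age_max[-nrow(iv)]))
      stop("overlapping age intervals within a sex/status group",
           call. = FALSE)
  }
  class(df) <- c("reference_table", "data.frame")
  df
}

#' @rdname reference_table
#' @param path CSV with the reference-table columns.
#' @export
read_reference_table <- function(path) {
  reference_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Match persons to reference rows (sex, age, status)
#'
#' @param sex,age,status person attributes (vectors of equal length; `status`
#'   defaults to "none").
#' @param refs a [reference_table()].
#' @return data.frame with columns `ear`, `ul`, one row per person.
#' @export
match_reference <- function(sex, age, refs, status = NULL) {
  stopifnot(inherits(refs, "reference_table"))
  n <- length(age)
  status <- status %||% rep("none", n)
  idx <- rep(NA_integer_, n)
  for (j in seq_len(nrow(refs))) {
    hit <- sex == refs$sex[j] & status == refs$status[j] &
      age > refs$age_min[j] & age <= refs$age_max[j]
    idx[hit & is.na(idx)] <- j
  }
  if (anyNA(idx)) {
    miss <- unique(paste0("(sex=", sex[is.na(idx)], ", age=", age[is.na(idx)],
                          ", status=", status[is.na(idx)], ")"))
    stop("no reference row for: ",
         paste(utils::head(miss, 10), collapse = "; "), call. = FALSE)
  }
  data.frame(ear = refs$ear[idx], ul = refs$ul[idx])
}

#' Prevalence of inadequate and excessive intake by the EAR cut-point method
#'
#' Weighted share of the pseudo-population with `total_intake` strictly
#' below the person-specific EAR (inadequate) and strictly above the
#' person-specific UL (excessive), as percentages. Valid when requirement
#' distributions are symmetric and intake and requirement are independent;
#' for nutrients with skewed requirements (iron in menstruating women) use
#' [prevalence_full_probability()].
#'
#' @param pseudo a `pseudo_pop` carrying `sex`, `age` (and optionally
#'   `status`) columns, or pass explicit column names.
#' @param refs a [reference_table()].
#' @param by subgroup column name or `NULL`.
#' @param sex_col,age_col,status_col column names on the pseudo-population.
#' @return data.frame with columns `subgroup`, `n`, `inadequate_pct`,
#'   `excessive_pct`.
#' @export
prevalence_cut_point <- function(pseudo, refs, by = NULL, sex_col = "sex",
                                 age_col = "age", status_col = NULL) {
  stopifnot(inherits(pseudo, "pseudo_pop"), nrow(pseudo) > 0)
  mr <- match_reference(pseudo[[sex_col]], pseudo[[age_col]], refs,
                        status = if (!is.null(status_col)) pseudo[[status_col]])
  groups <- if (is.null(by)) rep("overall", nrow(pseudo))
            else as.character(pseudo[[by]])
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    sel <- groups == g
    w <- pseudo$weight_share[sel]
    x <- pseudo$total_intake[sel]
    data.frame(subgroup = g,
               n = length(unique(pseudo$source_person_id[sel])),
               inadequate_pct = 100 * wmean(x < mr$ear[sel], w),
               excessive_pct = 100 * wmean(!is.na(mr$ul[sel]) &
                                             x > mr$ul[sel], w),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Tabulated distribution of absorbed requirements
#'
#' Holds the cumulative distribution of the *absorbed* daily requirement for
#' one sex/age/status group as `(p, q)` pairs, both strictly increasing,
#' together with the absorption fraction applied to ingested intake. The
#' default absorption is 0.18 (18%), the fractional iron absorption assumed
#' for mixed diets; users may substitute their own estimate.
#'
#' @param p cumulative probabilities in (0, 1), strictly increasing. A
#'   single row is allowed and represents a point mass at `q`.
#' @param q absorbed requirements (mg/day), strictly increasing.
#' @param absorption fraction in (0, 1].
#' @param interpolation `"linear"` (default) or `"loglinear"` interpolation
#'   of the CDF in `q` between tabulated points; outside the table the CDF
#'   is 0 below and 1 above.
#' @return object of class `requirement_distribution`.
#' @export
requirement_distribution <- function(p, q, absorption = 0.18,
                                     interpolation = c("linear", "loglinear")) {
  interpolation <- match.arg(interpolation)
  stopifnot(length(p) == length(q), length(p) >= 1,
            all(p > 0), all(p < 1) || length(p) == 1L,
            is.numeric(absorption), absorption > 0, absorption <= 1)
  if (length(p) > 1 && (any(diff(p) <= 0) || any(diff(q) <= 0)))
    stop("requirement table must be strictly increasing in both p and q",
         call. = FALSE)
  structure(list(p = p, q = q, absorption = absorption,
                 interpolation = interpolation),
            class = "requirement_distribution")
}

#' @rdname requirement_distribution
#' @param path CSV with columns `p`, `q_absorbed`.
#' @export
read_requirement_distribution <- function(path, absorption = 0.18,
                                          interpolation = "linear") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("p", "q_absorbed") %in% names(df)))
  requirement_distribution(df$p, df$q_absorbed, absorption = absorption,
                           interpolation = interpolation)
}

# CDF of the absorbed requirement at absorbed intake z (vectorised)
req_cdf <- function(dist, z) {
  p <- dist$p; q <- dist$q
  if (length(p) == 1L) return(as.numeric(z >= q))  # point mass
  if (dist$interpolation == "loglinear") {
    stopifnot(all(q > 0))
    f <- stats::approx(log(q), p, xout = log(pmax(z, .Machine$double.xmin)),
                       rule = 1)$y
  } else {
    f <- stats::approx(q, p, xout = z, rule = 1)$y
  }
  f[z < q[1]] <- 0
  f[z > q[length(q)]] <- 1
  f
}

#' Probability that a usual intake fails to meet the requirement
#'
#' Full-probability risk: `1 - F_req(a * y)` where `F_req` is the
#' interpolated tabulated CDF of the absorbed requirement and `a` the
#' absorption fraction. Below the tabulated range the risk is 1, above it 0;
#' the result is non-increasing in both `y` and `a`.
#'
#' @param y usual intake(s), ingested units/day, >= 0.
#' @param dist a [requirement_distribution()].
#' @return risk(s) in \[0, 1\].
#' @export
risk_of_inadequacy <- function(y, dist) {
  stopifnot(inherits(dist, "requirement_distribution"), all(y >= 0))
  pmin(1, pmax(0, 1 - req_cdf(dist, dist$absorption * y)))
}

#' Prevalence of inadequacy by the full-probability method
#'
#' Weighted mean of [risk_of_inadequacy()] over the pseudo-population, as a
#' percentage. Needed when the requirement distribution is asymmetric (the
#' EAR cut-point method assumes symmetry, which fails for iron in
#' menstruating women).
#'
#' @param pseudo a `pseudo_pop`.
#' @param dists a single [requirement_distribution()] applied to everyone,
#'   or a named list keyed by the values of `group`.
#' @param group column on the pseudo-population mapping persons to
#'   requirement groups (required when `dists` is a list).
#' @param by subgroup column or `NULL`.
#' @return data.frame with columns `subgroup`, `n`, `inadequate_pct`.
#' @export
prevalence_full_probability <- function(pseudo, dists, group = NULL,
                                        by = NULL) {
  stopifnot(inherits(pseudo, "pseudo_pop"))
  if (nrow(pseudo) == 0) stop("empty pseudo-population", call. = FALSE)
  if (inherits(dists, "requirement_distribution")) {
    risk <- risk_of_inadequacy(pseudo$total_intake, dists)
  } else {
    stopifnot(is.list(dists), !is.null(group))
    g <- as.character(pseudo[[group]])
    missing_g <- setdiff(unique(g), names(dists))
    if (length(missing_g))
      stop("no requirement distribution for group(s): ",
           paste(missing_g, collapse = ", "), call. = FALSE)
    risk <- numeric(nrow(pseudo))
    for (gg in unique(g)) {
      sel <- g == gg
      risk[sel] <- risk_of_inadequacy(pseudo$total_intake[sel], dists[[gg]])
    }
  }
  groups <- if (is.null(by)) rep("overall", nrow(pseudo))
            else as.character(pseudo[[by]])
  out <- do.call(rbind, lapply(unique(groups), function(gv) {
    sel <- groups == gv
    data.frame(subgroup = gv,
               n = length(unique(pseudo$source_person_id[sel])),
               inadequate_pct = 100 * wmean(risk[sel],
                                            pseudo$weight_share[sel]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
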