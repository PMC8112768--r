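# Uncertainty by whole-pipeline replication: Balanced Repeated Replication
# (two PSUs per stratum, Fay adjustment) or within-stratum person bootstrap.
# Every reported statistic is recomputed per replicate by re-running the
# full transform -> model -> simulate -> summarise chain on perturbed
# weights, then SEs come from the spread of the replicate estimates.

# Sylvester-construction Hadamard matrix; n must be a power of two.
hadamard_sylvester <- function(n) {
  stopifnot(n >= 1, bitwAnd(n, n - 1L) == 0L)
  H <- matrix(1, 1, 1)
  while (nrow(H) < n) H <- rbind(cbind(H, H), cbind(H, -H))
  H
}

#' Construct BRR replicate weights
#'
#' Requires exactly two PSUs per stratum. Replicate `r` multiplies the base
#' weight of the PSU selected by a Hadamard column by `2 - fay` and the
#' other PSU's by `fay`; over a full balanced set each person's replicate
#' weights average back to the base weight. The number of replicates is the
#' smallest power of two exceeding the number of strata (minimum 4), using
#' Hadamard rows other than the all-ones row so the set is balanced.
#'
#' @param data a [recall_data()] with `stratum` and `psu` declared.
#' @param fay Fay coefficient `F` in \[0, 1); `F = 0` is classical BRR
#'   (double one PSU, zero the other). Default 0.3.
#' @param R requested number of replicates; must be a power of two
#'   `> n_strata`, or `NULL` for the smallest admissible value.
#' @return list with `weights` (matrix, persons x R), `ids` (person ids in
#'   row order) and `fay`.
#' @export
make_brr_replicates <- function(data, fay = 0.3, R = NULL) {
  stopifnot(inherits(data, "recall_data"))
  if (fay < 0 || fay >= 1) stop("fay must lie in [0, 1)", call. = FALSE)
  v <- data$vars
  if (is.null(v$stratum) || is.null(v$psu))
    stop("BRR needs stratum and psu columns declared on the dataset",
         call. = FALSE)
  pt <- person_table(data)
  w <- person_weights(data)
  strata <- as.character(pt[[v$stratum]])
  psu <- as.character(pt[[v$psu]])
  sl <- unique(strata)
  bad <- sl[vapply(sl, function(s) length(unique(psu[strata == s])) != 2L,
                   logical(1))]
  if (length(bad))
    stop("BRR requires exactly 2 PSUs per stratum; offending strata: ",
         paste(bad, collapse = ", "), call. = FALSE)
  n_str <- length(sl)
  Rmin <- 4L
  while (Rmin <= n_str) Rmin <- Rmin * 2L   # need a non-constant row per stratum
  if (is.null(R)) R <- Rmin
  if (bitwAnd(R, R - 1L) != 0L || R <= n_str)
    stop("R must be a power of two greater than the number of strata ",
         "(smallest admissible: ", Rmin, ")", call. = FALSE)
  H <- hadamard_sylvester(R)[-1L, , drop = FALSE]   # drop all-ones row
  first_psu <- vapply(sl, function(s) sort(unique(psu[strata == s]))[1],
                      character(1))
  is_first <- psu == first_psu[match(strata, sl)]
  hrow <- match(strata, sl)                          # stratum -> Hadamard row
  W <- matrix(NA_real_, nrow(pt), R)
  for (r in seq_len(R)) {
    sel <- H[hrow, r] == 1                           # per person: PSU1 selected?
    factor <- ifelse(sel == is_first, 2 - fay, fay)
    W[, r] <- w * factor
  }
  list(weights = W, ids = pt[[v$person]], fay = fay)
}

#' Construct bootstrap replicate weights
#'
#' Person-level resampling with replacement within strata (one stratum when
#' none is declared); replicate weights are base weights times resampling
#' multiplicities.
#'
#' @inheritParams make_brr_replicates
#' @param R number of replicates (default 200).
#' @param seed root seed for the resampling draws.
#' @return list with `weights`, `ids`, `fay = 0`.
#' @export
make_bootstrap_replicates <- function(data, R = 200, seed = 1) {
  stopifnot(inherits(data, "recall_data"), R >= 1)
  pt <- person_table(data)
  v <- data$vars
  w <- person_weights(data)
  strata <- if (is.null(v$stratum)) rep("all", nrow(pt))
            else as.character(pt[[v$stratum]])
  W <- matrix(NA_real_, nrow(pt), R)
  for (r in seq_len(R)) {
    mult <- integer(nrow(pt))
    for (s in unique(strata)) {
      idx <- which(strata == s)
      draw <- with_seed(derive_seed(seed, paste0("boot:", r, ":", s)),
                        sample.int(length(idx), length(idx), replace = TRUE))
      tab <- tabulate(draw, nbins = length(idx))
      mult[idx] <- tab
    }
    W[, r] <- w * mult
  }
  list(weights = W, ids = pt[[v$person]], fay = 0)
}

#' Standard error from replicate estimates
#'
#' BRR with Fay coefficient `F`:
#' `SE = sqrt( sum_r (theta_r - theta0)^2 / (R * (1 - F)^2) )`.
#' Bootstrap: sample standard deviation of the replicate estimates. A
#' single-replicate bootstrap has no spread information; its SE is reported
#' as 0 with a warning that it is unreliable.
#'
#' @param theta0 point estimate.
#' @param theta_r replicate estimates (finite; `NA`s dropped with a warning
#'   upstream).
#' @param method `"brr"` or `"bootstrap"`.
#' @param fay Fay coefficient used to build the BRR weights.
#' @return non-negative SE.
#' @export
replicate_se <- function(theta0, theta_r, method = c("brr", "bootstrap"),
                         fay = 0) {
  method <- match.arg(method)
  if (length(theta_r) == 0) stop("no replicate estimates", call. = FALSE)
  stopifnot(is.finite(theta0), all(is.finite(theta_r)))
  if (method == "brr") {
    sqrt(sum((theta_r - theta0)^2) / (length(theta_r) * (1 - fay)^2))
  } else {
    if (length(theta_r) == 1L) {
      warning("bootstrap SE with a single replicate is unreliable; ",
              "reporting 0", call. = FALSE)
      return(0)
    }
    stats::sd(theta_r)
  }
}

# One full pipeline pass under given person weights; returns a named vector
# of statistics across all cumulative scenario stages.
pipeline_stats <- function(data, opts, seed) {
  scen <- opts$scenarios %||% list()
  stage_names <- "base"
  if (length(scen))
    stage_names <- c(stage_names, paste0("+", cumsum_labels(scen)))
  out <- c()
  for (s in 0:length(scen)) {
    specs <- if (s == 0) list() else scen[seq_len(s)]
    forts <- Filter(function(x) x$kind == "fortification", specs)
    adds <- Filter(function(x) x$kind != "fortification", specs)
    d2 <- data
    for (f in forts) d2 <- apply_fortification(d2, f)
    tr <- opts$transform %||%
      fit_transform(d2$recalls[[d2$vars$intake]], grid = opts$lambda_grid)
    model <- if (!is.null(opts$variance_ratio)) {
      fit_one_day(d2, opts$variance_ratio, opts$covariates, tr)
    } else {
      fit_mixed_model(d2, opts$covariates, tr)
    }
    pseudo <- simulate_pseudo_population(model, d2, m = opts$m, seed = seed,
                                         n_nodes = opts$n_nodes)
    pseudo <- apply_additive_specs(pseudo, adds, seed = seed)
    summ <- distribution_summary(pseudo, percentiles = opts$percentiles,
                                 cutoffs_below = opts$cutoffs_below,
                                 cutoffs_above = opts$cutoffs_above,
                                 by = opts$by)
    res <- as.data.frame(summ)
    if (!is.null(opts$refs)) {
      cp <- prevalence_cut_point(pseudo, opts$refs, by = opts$by,
                                 sex_col = opts$sex_col %||% "sex",
                                 age_col = opts$age_col %||% "age",
                                 status_col = opts$status_col)
      res <- merge(res, cp[c("subgroup", "inadequate_pct", "excessive_pct")],
                   by = "subgroup", sort = FALSE)
    }
    if (!is.null(opts$req_dists)) {
      fp <- prevalence_full_probability(pseudo, opts$req_dists,
                                        group = opts$req_group, by = opts$by)
      names(fp)[names(fp) == "inadequate_pct"] <- "fullprob_inadequate_pct"
      res <- merge(res, fp[c("subgroup", "fullprob_inadequate_pct")],
                   by = "subgroup", sort = FALSE)
    }
    stat_cols <- setdiff(names(res), "subgroup")
    for (i in seq_len(nrow(res))) {
      vals <- unlist(res[i, stat_cols])
      names(vals) <- paste(stage_names[s + 1], res$subgroup[i], stat_cols,
                           sep = "|")
      out <- c(out, vals)
    }
  }
  out
}

cumsum_labels <- function(specs) {
  labs <- vapply(specs, function(x) x$label, character(1))
  vapply(seq_along(labs), function(k) paste(labs[seq_len(k)], collapse = "+"),
         character(1))
}

#' Full-pipeline estimates with replication standard errors
#'
#' Computes every pipeline statistic (means, percentiles, prevalences, under
#' every cumulative scenario stage) on the base weights, then re-runs the
#' whole pipeline once per replicate-weight column and derives an SE and a
#' normal-approximation CI for each statistic. Replicate model failures are
#' caught, logged and counted; the run aborts when more than
#' `max_failure_rate` of replicates fail.
#'
#' @inheritParams estimate_usual_intake
#' @param refs optional [reference_table()] for cut-point prevalences
#'   (requires `sex`/`age` columns among the covariate/design columns).
#' @param req_dists optional [requirement_distribution()] (or named list
#'   with `req_group`) for full-probability prevalence.
#' @param req_group grouping column for `req_dists` lists.
#' @param sex_col,age_col,status_col column names for reference matching.
#' @param scenarios ordered list of [fortification()] / [supplement_program()]
#'   / [fixed_addition()] specs; results are reported cumulatively (base,
#'   then each scenario added in turn). Fortification always re-enters
#'   before model fitting, additive scenarios after simulation, regardless
#'   of list order.
#' @param method `"brr"` (needs a two-PSU-per-stratum design or pre-supplied
#'   `repw_*` columns) or `"bootstrap"`.
#' @param R replicate count (`NULL`: BRR minimum or bootstrap default 200).
#' @param fay Fay coefficient for BRR (default 0.3).
#' @param conf_level CI coverage for the normal approximation (default 0.95).
#' @param max_failure_rate abort threshold for replicate failures.
#' @return data.frame of class `results_table`: one row per
#'   scenario x subgroup x statistic with `estimate`, `se`, `ci_lo`,
#'   `ci_hi`; attribute `n_failed` counts failed replicates.
#' @export
run_with_uncertainty <- function(data, covariates = character(),
                                 transform = NULL,
                                 lambda_grid = seq(0.01, 1, by = 0.01),
                                 variance_ratio = NULL, m = 100, n_nodes = 9,
                                 percentiles = c(25, 50, 75),
                                 cutoffs_below = numeric(),
                                 cutoffs_above = numeric(), by = NULL,
                                 refs = NULL, req_dists = NULL,
                                 req_group = NULL, sex_col = "sex",
                                 age_col = "age", status_col = NULL,
                                 scenarios = list(),
                                 method = c("brr", "bootstrap"), R = NULL,
                                 fay = 0.3, seed = 1, conf_level = 0.95,
                                 max_failure_rate = 0.1) {
  method <- match.arg(method)
  opts <- list(covariates = covariates, transform = transform,
               lambda_grid = lambda_grid, variance_ratio = variance_ratio,
               m = m, n_nodes = n_nodes, percentiles = percentiles,
               cutoffs_below = cutoffs_below, cutoffs_above = cutoffs_above,
               by = by, refs = refs, req_dists = req_dists,
               req_group = req_group, sex_col = sex_col, age_col = age_col,
               status_col = status_col, scenarios = scenarios)
  theta0 <- pipeline_stats(data, opts, seed)

  v <- data$vars
  if (method == "brr" && !is.null(v$repweights)) {
    pt <- person_table(data)
    rep_des <- list(weights = as.matrix(pt[v$repweights]),
                    ids = pt[[v$person]], fay = fay)
  } else if (method == "brr") {
    rep_des <- make_brr_replicates(data, fay = fay, R = R)
  } else {
    rep_des <- make_bootstrap_replicates(data, R = R %||% 200, seed = seed)
  }
  Rn <- ncol(rep_des$weights)
  theta_r <- matrix(NA_real_, length(theta0), Rn,
                    dimnames = list(names(theta0), NULL))
  failures <- character()
  for (r in seq_len(Rn)) {
    dr <- set_person_weights(data, rep_des$weights[, r], ids = rep_des$ids)
    res <- tryCatch(pipeline_stats(dr, opts, seed = bitwXor(seed, r)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r,
                                      conditionMessage(res)))
    } else {
      theta_r[names(res), r] <- res
    }
  }
  if (length(failures) > max_failure_rate * Rn)
    stop("replicate failure rate ", length(failures), "/", Rn,
         " exceeds threshold; diagnostics:\n",
         paste(utils::head(failures, 5), collapse = "\n"), call. = FALSE)
  if (length(failures))
    message(length(failures), " replicate(s) failed and were dropped")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- vapply(seq_along(theta0), function(i) {
    tr <- theta_r[i, ]
    tr <- tr[is.finite(tr)]
    replicate_se(theta0[i], tr, method = method, fay = rep_des$fay)
  }, numeric(1))
  parts <- do.call(rbind, strsplit(names(theta0), "|", fixed = TRUE))
  out <- data.frame(scenario = parts[, 1], subgroup = parts[, 2],
                    statistic = parts[, 3], estimate = unname(theta0),
                    se = se, ci_lo = unname(theta0) - z * se,
                    ci_hi = unname(theta0) + z * se,
                    stringsAsFactors = FALSE)
  attr(out, "n_failed") <- length(failures)
  attr(out, "n_replicates") <- Rn
  attr(out, "method") <- method
  attr(out, "fay") <- rep_des$fay
  class(out) <- c("results_table", "data.frame")
  out
}

#' @export
print.results_table <- function(x, ...) {
  cat("<results_table> ", attr(x, "method"), " SEs, ",
      attr(x, "n_replicates"), " replicates (",
      attr(x, "n_failed"), " failed)\n", sep = "")
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}
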