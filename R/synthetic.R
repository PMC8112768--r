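# Synthetic recall surveys generated under the model's own structure
# (g(intake) = x'beta + u_i + e_ij), with closed-form population truths for
# the identity and log transforms. Defaults describe a survey of 2000
# persons with 2 recalls each over a stratified two-PSU design.

#' Specification of a synthetic recall survey
#'
#' The generator simulates the assumed data-generating process exactly:
#' transformed daily intakes are `x'beta + u_i + e_ij` with normal person
#' effects and residuals, inverted back to the intake scale. Survey weights
#' are inverse inclusion probabilities over strata with controllable
#' dispersion (so weighted and unweighted estimates differ detectably);
#' fortifiable-vehicle consumption is zero-inflated gamma (consumers and
#' non-consumers both occur); supplement usage takes one of a small set of
#' discrete dosages (real-world supplement amounts cluster around a few
#' dose levels) with a usage probability.
#'
#' @param n_persons number of persons (default 2000).
#' @param n_recalls recalls per person (default 2).
#' @param lambda,offset Box-Cox transform of the generating model.
#' @param beta0 intercept on the transformed scale.
#' @param sigma2_u,sigma2_e between- / within-person variances (transformed
#'   scale).
#' @param n_strata number of design strata, each with 2 PSUs.
#' @param weight_cv coefficient of variation of the survey weights (0 =
#'   self-weighting).
#' @param sex_effect additive transformed-scale effect of `sex = "F"`
#'   (default 0 keeps the model intercept-only; set non-zero to exercise
#'   covariates).
#' @param vehicle_zero_prob,vehicle_shape,vehicle_mean zero-inflated gamma
#'   parameters of daily vehicle consumption (grams/day).
#' @param supplement_dosages discrete dosage values (units/day).
#' @param supplement_prob probability a person uses a supplement.
#' @param seed generator seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_persons = 2000, n_recalls = 2, lambda = 1,
                           offset = 0, beta0 = 10, sigma2_u = 1,
                           sigma2_e = 2, n_strata = 4, weight_cv = 0.3,
                           sex_effect = 0, vehicle_zero_prob = 0.3,
                           vehicle_shape = 2, vehicle_mean = 10,
                           supplement_dosages = numeric(),
                           supplement_prob = 0, seed = 1) {
  stopifnot(n_persons >= 1, n_recalls >= 1, sigma2_u >= 0, sigma2_e >= 0,
            lambda >= 0, lambda <= 1, offset >= 0,
            vehicle_zero_prob >= 0, vehicle_zero_prob <= 1,
            supplement_prob >= 0, supplement_prob <= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic recall survey with known truth
#'
#' Draws per-person covariates, design membership and weights, then recalls
#' `intake_ij = g_inv(x'beta + u_i + e_ij)` (clamped at zero where the
#' inverse transform's domain requires it). The returned truth record
#' carries the generating parameters and, for `lambda` 0 or 1, the
#' closed-form population mean of usual intake.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `data` (a [recall_data()]) and `truth` (list of
#'   generating parameters, per-person true usual intakes and closed forms
#'   where available).
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_persons < 1 || spec$n_recalls < 1)
    stop("need at least one person and one recall", call. = FALSE)
  s <- spec
  tr <- transform_spec(s$lambda, s$offset)
  with_seed(s$seed, {
    n <- s$n_persons
    sex <- sample(c("F", "M"), n, replace = TRUE)
    age <- round(stats::runif(n, 19, 70))
    stratum <- sample(paste0("S", seq_len(s$n_strata)), n, replace = TRUE)
    psu <- paste0(stratum, "-P", sample(1:2, n, replace = TRUE))
    w <- if (s$weight_cv > 0) {
      # lognormal inclusion-probability dispersion, mean 1
      stats::rlnorm(n, -s$weight_cv^2 / 2, s$weight_cv)
    } else rep(1, n)
    u <- stats::rnorm(n, 0, sqrt(s$sigma2_u))
    xb <- s$beta0 + ifelse(sex == "F", s$sex_effect, 0)
    eps <- matrix(stats::rnorm(n * s$n_recalls, 0, sqrt(s$sigma2_e)),
                  n, s$n_recalls)
    veh <- ifelse(stats::runif(n) < s$vehicle_zero_prob, 0,
                  stats::rgamma(n, shape = s$vehicle_shape,
                                scale = s$vehicle_mean / s$vehicle_shape))
    supp <- if (length(s$supplement_dosages) && s$supplement_prob > 0) {
      ifelse(stats::runif(n) < s$supplement_prob,
             s$supplement_dosages[sample.int(length(s$supplement_dosages),
                                             n, replace = TRUE)], 0)
    } else rep(0, n)
    df <- data.frame(
      person_id = rep(sprintf("p%05d", seq_len(n)), each = s$n_recalls),
      recall_index = rep(seq_len(s$n_recalls), times = n),
      intake = bc_inverse(tr, as.vector(t(xb + u + eps))),
      vehicle_oil = rep(veh, each = s$n_recalls),
      sex = rep(sex, each = s$n_recalls),
      age = rep(age, each = s$n_recalls),
      stratum = rep(stratum, each = s$n_recalls),
      psu = rep(psu, each = s$n_recalls),
      weight = rep(w, each = s$n_recalls),
      supplement_daily = rep(supp, each = s$n_recalls),
      stringsAsFactors = FALSE)
    data <- recall_data(df, weight = "weight",
                        covariates = c("sex", "age"),
                        stratum = "stratum", psu = "psu",
                        vehicles = "vehicle_oil")
    true_usual <- backtransform_mean(xb + u, tr, s$sigma2_e, n_nodes = 21)
    truth <- list(spec = s,
                  true_usual = true_usual,
                  weighted_mean_usual = wmean(true_usual, w))
    if (s$lambda %in% c(0, 1) && s$offset == 0 && s$sex_effect == 0) {
      truth$closed_form_mean <- closed_form_truth(s)$mean
    }
    list(data = data, truth = truth)
  })
}

#' Closed-form truths of the usual-intake distribution
#'
#' For intercept-only generating models with offset 0:
#' * `lambda = 1`: usual intake is `N(beta0 + 1, sigma2_u)`; prevalence
#'   below `c` is `pnorm((c - beta0 - 1) / sigma_u)`.
#' * `lambda = 0`: usual intake is `exp(beta0 + sigma2_e / 2 + u)`; its mean
#'   is `exp(beta0 + sigma2_u / 2 + sigma2_e / 2)` and prevalence below `c`
#'   is `pnorm((log(c) - beta0 - sigma2_e / 2) / sigma_u)`.
#'
#' Other lambdas have no closed form here; use a Monte-Carlo oracle.
#'
#' @param spec a [synthetic_spec()] with `lambda` 0 or 1.
#' @param cutoff optional cutoff(s) for prevalence-below.
#' @return list with `mean`, `median`, and `prevalence_below` (% scale) per
#'   cutoff.
#' @export
closed_form_truth <- function(spec, cutoff = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  s <- spec
  if (!s$lambda %in% c(0, 1))
    stop("closed-form truth only available for lambda 0 or 1; use a ",
         "Monte-Carlo oracle for other transforms", call. = FALSE)
  stopifnot(s$offset == 0, s$sex_effect == 0)
  su <- sqrt(s$sigma2_u)
  if (s$lambda == 1) {
    mu <- s$beta0 + 1
    out <- list(mean = mu, median = mu)
    if (!is.null(cutoff)) {
      out$prevalence_below <- if (su > 0) 100 * stats::pnorm((cutoff - mu) / su)
                              else 100 * as.numeric(cutoff > mu)
    }
  } else {
    lmu <- s$beta0 + s$sigma2_e / 2
    out <- list(mean = exp(lmu + s$sigma2_u / 2), median = exp(lmu))
    if (!is.null(cutoff)) {
      out$prevalence_below <- if (su > 0) 100 * stats::pnorm((log(cutoff) - lmu) / su)
                              else 100 * as.numeric(cutoff > exp(lmu))
    }
  }
  out
}

#' Write a truth record as a JSON sidecar
#' @param truth the `truth` element of [generate_population()].
#' @param path output JSON path.
#' @export
write_truth <- function(truth, path) {
  truth$spec <- unclass(truth$spec)
  truth$true_usual <- NULL  # per-person vector omitted from the sidecar
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
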