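# Person-level measurement-error model on the transformed scale:
#   g(intake_ij) = x_ij' beta + u_i + e_ij,
#   u_i ~ N(0, sigma2_u) between persons, e_ij ~ N(0, sigma2_e) within.
# Estimated by survey-weighted profile REML (Woodbury identities for the
# compound-symmetric person blocks), with a weighted one-way-ANOVA
# method-of-moments estimator as starting value and fallback.

# Design matrix with a stored encoding so replicate refits reuse identical
# dummy coding (categoricals one-hot, first level reference).
make_design <- function(df, covariates, spec = NULL) {
  if (!length(covariates)) {
    X <- matrix(1, nrow(df), 1L, dimnames = list(NULL, "(Intercept)"))
    return(list(X = X, spec = list(covariates = character(), xlev = list())))
  }
  if (is.null(spec)) {
    xlev <- lapply(df[covariates], function(col)
      if (is.character(col) || is.factor(col)) levels(factor(col)) else NULL)
    xlev <- Filter(Negate(is.null), xlev)
  } else {
    xlev <- spec$xlev
  }
  f <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
  for (nm in names(xlev)) df[[nm]] <- factor(df[[nm]], levels = xlev[[nm]])
  X <- stats::model.matrix(f, stats::model.frame(f, df, na.action = stats::na.fail))
  list(X = X, spec = list(covariates = covariates, xlev = xlev))
}

check_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
}

# Weighted GLS profile pieces for fixed variance components.
# Returns beta, the REML information matrix, and the -2 pseudo-log-likelihood.
gls_profile <- function(y, X, pid, w_person, ni, s2u, s2e, reml = TRUE) {
  a <- s2e + ni * s2u                      # per-person |V| factor
  wrow <- w_person[pid]
  Sx <- rowsum(X * wrow, pid, reorder = TRUE)          # sum w x per person
  Sy <- rowsum(y * wrow, pid, reorder = TRUE)[, 1L]
  # XtViX = sum_i w_i [X_i'X_i/s2e - s2u/(s2e a_i) (sum x)(sum x)']
  # with w folded into the row sums once (w enters linearly).
  XtX <- crossprod(X * sqrt(wrow))
  cvec <- s2u / (s2e * a)
  XtViX <- XtX / s2e - crossprod(Sx * sqrt(cvec / w_person))
  Xty <- crossprod(X, y * wrow)[, 1L] / s2e - colSums(Sx * (cvec / w_person) * Sy)
  beta <- solve(XtViX, Xty)
  r <- y - drop(X %*% beta)
  Sr <- rowsum(r * wrow, pid, reorder = TRUE)[, 1L]
  quad <- sum(r^2 * wrow) / s2e - sum(cvec / w_person * Sr^2)
  logdet <- sum(w_person * ((ni - 1) * log(s2e) + log(a)))
  m2ll <- logdet + quad
  if (reml) m2ll <- m2ll + determinant(XtViX, logarithm = TRUE)$modulus[1]
  list(beta = beta, m2ll = m2ll, XtViX = XtViX)
}

# Weighted one-way ANOVA method of moments on OLS residuals.
mom_components <- function(y, X, pid, w_person, ni) {
  wrow <- w_person[pid]
  fit <- stats::lm.wfit(X, y, wrow)
  e <- fit$residuals
  ebar <- rowsum(e * wrow, pid, reorder = TRUE)[, 1L] /
    rowsum(wrow, pid, reorder = TRUE)[, 1L]
  ssw <- sum(wrow * (e - ebar[pid])^2)
  dfw <- sum(w_person * (ni - 1))
  s2e <- if (dfw > 0) ssw / dfw else 0
  N <- length(ni)
  wn <- w_person * ni
  gm <- sum(wn * ebar) / sum(wn)
  msb <- sum(wn * (ebar - gm)^2) / (N - 1)
  n0 <- (sum(wn) - sum(w_person * ni^2) / sum(wn)) / (N - 1)
  s2u <- if (n0 > 0) max(0, (msb - s2e) / n0) else 0
  list(beta = fit$coefficients, s2e = s2e, s2u = s2u)
}

new_amount_model <- function(transform, beta, s2u, s2e, design_spec,
                             person_id, xb, n_persons, n_recalls, converged,
                             method, variance_ratio_used = NULL) {
  structure(list(
    transform = transform, beta = beta,
    sigma2_between = s2u, sigma2_within = s2e,
    design_spec = design_spec,
    variance_ratio_used = variance_ratio_used,
    person_id = person_id, xb = xb,
    n_persons = n_persons, n_recalls = n_recalls,
    converged = converged, method = method
  ), class = "amount_model")
}

#' @export
print.amount_model <- function(x, ...) {
  cat("<amount_model> (", x$method, ")\n", sep = "")
  cat("  transform: lambda = ", format(x$transform$lambda),
      ", offset = ", format(x$transform$offset), "\n", sep = "")
  cat("  persons: ", x$n_persons, ", recalls: ", x$n_recalls, "\n", sep = "")
  cat("  sigma2 between = ", format(x$sigma2_between),
      ", within = ", format(x$sigma2_within), "\n", sep = "")
  if (!is.null(x$variance_ratio_used))
    cat("  external within:between ratio = ",
        format(x$variance_ratio_used), "\n", sep = "")
  cat("  coefficients:\n")
  print(x$beta)
  if (!x$converged) cat("  WARNING: optimiser did not converge\n")
  invisible(x)
}

# Per-person covariate-based prediction x'beta on the transformed scale,
# evaluated at each person's first-recall covariate values.
person_predictions <- function(data, beta, covariates, design_spec) {
  pt <- person_table(data)
  Xp <- make_design(pt, covariates, design_spec)$X
  list(person_id = pt[[data$vars$person]], xb = drop(Xp %*% beta), pt = pt)
}

#' Fit the transformed-scale mixed model to repeated recalls
#'
#' Maximises the survey-weighted (restricted) likelihood of
#' `g(intake) = X beta + u_i + e_ij` with independent normal person effects
#' and residuals. Weights enter as per-person multipliers of the likelihood
#' contributions (normalised to mean one), so point estimates are
#' design-consistent; standard errors come from the replication module, not
#' from the model.
#'
#' @param data a [recall_data()] object; at least a subsample of persons must
#'   have two or more recalls.
#' @param covariates covariate names for the prediction function (an
#'   intercept is always included). Categorical covariates are one-hot
#'   encoded against their first level.
#' @param transform a [transform_spec()]; typically from [fit_transform()].
#' @param method `"reml"` (default) or `"ml"`.
#' @return an `amount_model` with coefficients `beta`, variance components
#'   `sigma2_between` (`u`) and `sigma2_within` (`e`), the design encoding,
#'   per-person predictions, and an honest `converged` flag (method-of-
#'   moments fallback estimates are reported with `converged = FALSE` only
#'   when the optimiser failed).
#' @export
fit_mixed_model <- function(data, covariates = character(), transform,
                            method = c("reml", "ml")) {
  method <- match.arg(method)
  stopifnot(inherits(data, "recall_data"), inherits(transform, "transform_spec"))
  df <- data$recalls
  v <- data$vars
  pid_f <- factor(df[[v$person]])
  ni_all <- tabulate(pid_f)
  if (max(ni_all) < 2L)
    stop("no person has repeated recalls: the between/within decomposition ",
         "is not identifiable. For single-recall surveys use fit_one_day() ",
         "with an external within:between variance ratio.", call. = FALSE)
  y <- bc_transform(transform, df[[v$intake]])
  des <- make_design(df, covariates)
  check_rank(des$X)
  pid <- as.integer(pid_f)
  o <- order(pid)
  y <- y[o]; X <- des$X[o, , drop = FALSE]; pid <- pid[o]
  ni <- ni_all
  w <- person_weights(data)[match(levels(pid_f), person_table(data)[[v$person]])]
  w <- w / mean(w)

  mom <- mom_components(y, X, pid, w, ni)
  tot <- mom$s2e + mom$s2u
  converged <- TRUE
  if (mom$s2e <= 1e-12 * max(tot, 1e-12)) {
    # degenerate: no within-person variation; between = variance of the
    # person-mean residuals
    s2e <- 0
    fit <- stats::lm.wfit(X, y, w[pid])
    e <- fit$residuals
    ebar <- rowsum(e * w[pid], pid)[, 1L] / rowsum(w[pid], pid)[, 1L]
    s2u <- sum(w * ebar^2) / sum(w)
    beta <- fit$coefficients
  } else {
    start <- log(pmax(c(mom$s2u, mom$s2e), 1e-6 * tot))
    obj <- function(par) {
      gls_profile(y, X, pid, w, ni, exp(par[1]), exp(par[2]),
                  reml = method == "reml")$m2ll
    }
    opt <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-12))
    converged <- opt$convergence == 0L
    if (converged) {
      s2u <- exp(opt$par[1]); s2e <- exp(opt$par[2])
      beta <- gls_profile(y, X, pid, w, ni, s2u, s2e,
                          reml = method == "reml")$beta
    } else {
      s2u <- mom$s2u; s2e <- mom$s2e; beta <- mom$beta
    }
    if (s2u < 1e-10 * s2e) s2u <- 0  # boundary estimate
  }
  names(beta) <- colnames(X)
  pred <- person_predictions(data, beta, covariates, des$spec)
  new_amount_model(transform, beta, s2u, s2e, des$spec,
                   pred$person_id, pred$xb,
                   n_persons = nlevels(pid_f), n_recalls = nrow(df),
                   converged = converged, method = method)
}

#' Fit the one-day model with an external within:between variance ratio
#'
#' For surveys with a single 24-h recall per person the within- and
#' between-person components cannot be separated internally. This fit runs a
#' survey-weighted regression on the transformed scale and splits the total
#' residual variance using an externally supplied ratio
#' `r = sigma2_within / sigma2_between`:
#' `sigma2_between = s2_tot / (1 + r)`, `sigma2_within = s2_tot * r / (1 + r)`.
#' The split is exact: the two components always sum to `s2_tot`. Because a
#' misspecified external ratio biases the usual-intake distribution,
#' sensitivity analyses over a range of plausible ratios are recommended.
#'
#' @inheritParams fit_mixed_model
#' @param variance_ratio external ratio `r >= 0` (finite).
#' @return an `amount_model` with `variance_ratio_used` recorded.
#' @export
fit_one_day <- function(data, variance_ratio, covariates = character(),
                        transform) {
  stopifnot(inherits(data, "recall_data"), inherits(transform, "transform_spec"))
  if (missing(variance_ratio) || is.null(variance_ratio))
    stop("single-day analysis requires an external within:between variance ",
         "ratio; supply `variance_ratio` (and run sensitivity analyses over ",
         "a range of plausible external ratios).", call. = FALSE)
  if (!is.finite(variance_ratio) || variance_ratio < 0)
    stop("`variance_ratio` must be finite and >= 0", call. = FALSE)
  df <- data$recalls
  v <- data$vars
  y <- bc_transform(transform, df[[v$intake]])
  des <- make_design(df, covariates)
  check_rank(des$X)
  pid_f <- factor(df[[v$person]])
  w <- person_weights(data)[match(levels(pid_f), person_table(data)[[v$person]])]
  w <- w / mean(w)
  wrow <- w[as.integer(pid_f)]
  fit <- stats::lm.wfit(des$X, y, wrow)
  beta <- fit$coefficients
  names(beta) <- colnames(des$X)
  s2tot <- sum(wrow * fit$residuals^2) / sum(wrow)
  s2u <- s2tot / (1 + variance_ratio)
  s2e <- s2tot * variance_ratio / (1 + variance_ratio)
  pred <- person_predictions(data, beta, covariates, des$spec)
  new_amount_model(transform, beta, s2u, s2e, des$spec,
                   pred$person_id, pred$xb,
                   n_persons = nlevels(pid_f), n_recalls = nrow(df),
                   converged = TRUE, method = "one_day",
                   variance_ratio_used = variance_ratio)
}
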