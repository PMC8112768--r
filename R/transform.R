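# Box-Cox power transformation to approximate normality, selected by grid
# search on the profile log-likelihood.

#' Box-Cox transformation specification
#'
#' `g(r; lambda) = ((r + offset)^lambda - 1) / lambda` for `lambda > 0` and
#' `log(r + offset)` for `lambda = 0`; strictly increasing on the data's
#' support. The inverse clamps at zero where it would fall below the
#' transform's domain boundary, since intakes are non-negative.
#'
#' @param lambda power in \(0, 1\], or 0 for the log transform.
#' @param offset additive shift applied before transforming (>= 0); used when
#'   a small share of person-days has zero intake.
#' @return object of class `transform_spec` with fields `lambda`, `offset`.
#' @export
transform_spec <- function(lambda, offset = 0) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            lambda >= 0, lambda <= 1, is.numeric(offset), offset >= 0)
  structure(list(lambda = lambda, offset = offset), class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
  cat("<transform_spec> lambda = ", format(x$lambda),
      if (x$lambda == 0) " (log)", ", offset = ", format(x$offset), "\n",
      sep = "")
  invisible(x)
}

#' Apply a transform to the original (intake) scale
#' @param spec a `transform_spec`.
#' @param r intakes (>= 0 after offset handling).
#' @return transformed values.
#' @export
bc_transform <- function(spec, r) {
  z <- r + spec$offset
  if (any(z <= 0))
    stop("non-positive values after offset; offending rows: ",
         paste(utils::head(which(z <= 0), 10), collapse = ", "), call. = FALSE)
  if (spec$lambda == 0) log(z) else (z^spec$lambda - 1) / spec$lambda
}

#' Inverse transform back to the intake scale, clamped at zero
#' @param spec a `transform_spec`.
#' @param y transformed-scale values.
#' @export
bc_inverse <- function(spec, y) {
  if (spec$lambda == 0) {
    pmax(0, exp(y) - spec$offset)
  } else {
    base <- pmax(spec$lambda * y + 1, 0)  # below the domain boundary -> 0
    pmax(0, base^(1 / spec$lambda) - spec$offset)
  }
}

# Analytic continuation of the inverse, used inside the quadrature
# back-transformation: where 1/lambda is an integer the power law extends
# below the domain boundary as a polynomial (linear for lambda = 1,
# quadratic for lambda = 0.5), which keeps the quadrature exact for
# polynomial inverses; elsewhere the base is floored at zero. The final
# expectation, not each node, is clamped at zero.
bc_inverse_continued <- function(spec, y) {
  if (spec$lambda == 0) return(exp(y) - spec$offset)
  base <- spec$lambda * y + 1
  k <- 1 / spec$lambda
  if (abs(k - round(k)) < 1e-9) {
    k <- round(k)
    out <- abs(base)^k
    if (k %% 2 == 1) out <- out * sign(base)
    out - spec$offset
  } else {
    pmax(base, 0)^k - spec$offset
  }
}

# Box-Cox profile log-likelihood (up to a constant), Jacobian included:
# -n/2 log(sigma2_hat(lambda)) + (lambda - 1) * sum(log(x))
boxcox_loglik <- function(x, lambda) {
  n <- length(x)
  y <- if (lambda == 0) log(x) else (x^lambda - 1) / lambda
  s2 <- sum((y - mean(y))^2) / n
  -n / 2 * log(s2) + (lambda - 1) * sum(log(x))
}

#' Select a Box-Cox transform by profile likelihood over a grid
#'
#' Evaluates the Box-Cox profile log-likelihood (including the Jacobian term)
#' at every candidate `lambda` and returns the maximiser; deterministic for
#' fixed input and grid.
#'
#' Zero intakes are handled by the "nearly-daily" rule: when the share of
#' zero person-days exceeds `zero_threshold` the component is treated as
#' episodically consumed and an error is raised (episodic components are out
#' of this model's scope); below the threshold an offset of half the smallest
#' positive intake is applied before transforming.
#'
#' @param intakes non-negative intake values (>= 10 strictly positive values
#'   required after offset handling).
#' @param grid candidate lambdas; default `seq(0.01, 1, by = 0.01)`. Include
#'   0 to allow the log transform.
#' @param offset additive shift; `NULL` (default) selects 0 for all-positive
#'   data and half the minimum positive value when zeros are present.
#' @param zero_threshold maximum tolerated share of zero person-days
#'   (default 0.05).
#' @return a `transform_spec` with attribute `loglik` (profile log-likelihood
#'   over the grid).
#' @export
fit_transform <- function(intakes, grid = seq(0.01, 1, by = 0.01),
                          offset = NULL, zero_threshold = 0.05) {
  stopifnot(is.numeric(intakes), all(is.finite(intakes)))
  if (any(intakes < 0))
    stop("negative intakes in rows: ",
         paste(utils::head(which(intakes < 0), 10), collapse = ", "),
         call. = FALSE)
  zero_share <- mean(intakes == 0)
  if (is.null(offset)) {
    if (zero_share > zero_threshold)
      stop(sprintf(paste0(
        "%.1f%% of person-days have zero intake (threshold %.1f%%): this ",
        "component is not consumed nearly daily and cannot be analysed by ",
        "the amount-only model; an episodic (probability x amount) model ",
        "would be required."), 100 * zero_share, 100 * zero_threshold),
        call. = FALSE)
    offset <- if (zero_share > 0) min(intakes[intakes > 0]) / 2 else 0
  }
  x <- intakes + offset
  if (any(x <= 0))
    stop("non-positive values with offset ", offset, " in rows: ",
         paste(utils::head(which(x <= 0), 10), collapse = ", "), call. = FALSE)
  if (sum(intakes > 0) < 10)
    stop("need at least 10 strictly positive intakes to fit a transform",
         call. = FALSE)
  if (stats::var(x) == 0)
    stop("intakes have no variance; cannot select a transformation",
         call. = FALSE)
  ll <- vapply(grid, function(l) boxcox_loglik(x, l), numeric(1))
  spec <- transform_spec(grid[which.max(ll)], offset)
  attr(spec, "loglik") <- stats::setNames(ll, format(grid))
  spec
}
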