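#' Marginal yield series of a trial
#'
#' Builds the per-interval marginal yield, the yield increase per kg of
#' nutrient between adjacent application rates:
#' `dY/dX ~ (Y[i+1] - Y[i]) / (X[i+1] - X[i])`. Each difference quotient is
#' assigned to the upper endpoint X[i+1] of its interval; this assignment is
#' the one under which least-squares fits of the series reproduce the
#' published marginal-model coefficients for the bundled rice trials (with a
#' midpoint or lower-endpoint assignment the fitted intercept shifts by
#' b*dX/2 or b*dX for equally spaced rates).
#'
#' @param trial a [fertilizer_trial()].
#' @return An object of class `"marginal_series"`: a data frame with columns
#'   `x` (assigned rate, kg/hm2) and `dydx` (kg yield per kg nutrient), with
#'   the source trial id in attribute `"trial_id"`.
#' @examples
#' marginal_series(builtin_trials("rice")$rice_N_datian)
#' @seealso [fit_marginal()]
#' @export
marginal_series <- function(trial) {
  stopifnot(inherits(trial, "fertilizer_trial"))
  s <- data.frame(x = trial$rates[-1],
                  dydx = diff(trial$yields) / diff(trial$rates))
  attr(s, "trial_id") <- trial$trial_id
  class(s) <- c("marginal_series", "data.frame")
  s
}

#' Fit a marginal yield model
#'
#' Fits the yield-increase-per-unit-nutrient series from [marginal_series()]
#' with one of two models:
#'
#' * `"linear"`: y = a + b*X by ordinary least squares (the differential of
#'   the quadratic polynomial response, with b1 = a and 2*b2 = b);
#' * `"exponential"`: dY/dX = A\[1 - c(s0 + X)\]e^(-cX), the differential of
#'   the non-structural response model, fitted by the same variable
#'   projection used in [fit_response()]: for fixed c the model is linear in
#'   (u, v) = (A(1 - c*s0), A*c) on basis (e^(-cX), -X e^(-cX)); the profiled
#'   SSE is minimized over c, and A = v/c, s0 = 1/c - u/v are recovered.
#'
#' @param series a [marginal_series()].
#' @param model `"exponential"` or `"linear"`.
#' @param c_bounds,grid_size profile-search settings as in [fit_response()].
#' @return An object of class `c("exp_marginal_fit", "fert_fit")` or
#'   `c("linear_marginal_fit", "fert_fit")`. For the linear model the
#'   parameters are `a`, `b`; for the exponential model `A`, `c`, `s0`.
#' @examples
#' m <- marginal_series(builtin_trials("rice")$rice_N_datian)
#' coef(fit_marginal(m, "linear"))       # a ~ 23.97, b ~ -0.120
#' coef(fit_marginal(m, "exponential"))  # A ~ 52.8, c ~ 3.13e-3, s0 ~ 131
#' @export
fit_marginal <- function(series, model = c("exponential", "linear"),
                         c_bounds = c(1e-5, 5e-2), grid_size = 400L) {
  stopifnot(inherits(series, "marginal_series"))
  model <- match.arg(model)
  x <- series$x; d <- series$dydx
  cl <- match.call()
  if (model == "linear") {
    if (length(x) < 3L) stop("linear marginal fit needs at least 3 points")
    if (length(unique(x)) < 2L) stop("singular design: all x identical")
    ols <- stats::lm(d ~ x)
    params <- c(a = unname(coef(ols)[1]), b = unname(coef(ols)[2]))
    fit <- new_fert_fit("linear_marginal_fit", "linear_marginal", params,
                        fit_statistics(d, unname(stats::fitted(ols)), 2L),
                        NULL, x, d, unname(stats::fitted(ols)),
                        character(0), cl)
  } else {
    if (length(x) < 4L) stop("exponential marginal fit needs at least 4 points")
    vp <- varpro_fit(x, d, c_bounds = c_bounds, grid_size = grid_size)
    u <- vp$p; v <- -vp$q
    if (v <= 0)
      stop("fit rejected: recovered A = v/c is not positive ",
           "(series is not decaying)")
    flags <- character(0)
    if (vp$at_bound) {
      warning("profiled optimum of c lies at a search bound")
      flags <- c(flags, "c_at_bound")
    }
    params <- nsfm_params(A = v / vp$c, c = vp$c, s0 = 1 / vp$c - u / v)
    fit <- new_fert_fit("exp_marginal_fit", "exp_marginal", params,
                        fit_statistics(d, vp$fitted, 3L), NULL, x, d,
                        vp$fitted, flags, cl)
  }
  fit$trial_id <- attr(series, "trial_id")
  fit
}

#' Predicted marginal yield of the non-structural model
#'
#' dY/dX = A\[1 - c(s0 + X)\]e^(-cX), used both as the exponential marginal
#' model and as the analytic derivative behind the economic-rate optimality
#' check (at the economic optimum dY/dX equals the price ratio beta).
#'
#' @param params an [nsfm_params()] object.
#' @param X application rate(s), kg/hm2.
#' @return Marginal yield, kg yield per kg nutrient.
#' @export
predict_marginal_nsfm <- function(params, X) {
  p <- as.list(params)
  p$A * (1 - p$c * (p$s0 + X)) * exp(-p$c * X)
}
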