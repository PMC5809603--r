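#' Parameter containers for the two response models
#'
#' `nsfm_params()` holds the parameters of the non-structural response model
#' Y = A(s0+X)e^(-cX): `A`, the soil-fertility-to-yield conversion
#' coefficient (kg yield per kg soil-equivalent nutrient); `c`, the yield
#' response coefficient (hm2/kg); and `s0`, the indigenous soil nutrient
#' supply expressed in fertilizer-equivalent kg/hm2. The antiderivative's
#' integration constant is identically zero, so Y -> 0 as (s0+X) -> 0.
#'
#' `qpfm_params()` holds the quadratic polynomial model Y = b0 + b1*X + b2*X^2.
#' Sign conditions on b1, b2 are diagnosed by [classify_typicality()], not
#' enforced here.
#'
#' @param A,c,s0 non-structural model parameters; `c` must be positive and a
#'   positive `A` is required of any accepted fit.
#' @param b0,b1,b2 polynomial coefficients.
#' @return A named numeric vector of class `"nsfm_params"` or `"qpfm_params"`.
#' @examples
#' predict_nsfm(nsfm_params(47.596, 0.003740, 105.12), 150)
#' @export
nsfm_params <- function(A, c, s0) {
  stopifnot(is.finite(A), is.finite(c), is.finite(s0))
  if (c <= 0) stop("c must be positive")
  if (A <= 0) stop("A must be positive")
  structure(c(A = A, c = c, s0 = s0), class = "nsfm_params")
}

#' @rdname nsfm_params
#' @export
qpfm_params <- function(b0, b1, b2) {
  stopifnot(is.finite(b0), is.finite(b1), is.finite(b2))
  structure(c(b0 = b0, b1 = b1, b2 = b2), class = "qpfm_params")
}

#' Predict yield from model parameters
#'
#' @param params an [nsfm_params()] / [qpfm_params()] object (a named vector
#'   or list with the right components also works).
#' @param X application rate(s), kg/hm2, non-negative.
#' @return Predicted yield(s), kg/hm2.
#' @export
predict_nsfm <- function(params, X) {
  p <- as.list(params)
  p$A * (p$s0 + X) * exp(-p$c * X)
}

#' @rdname predict_nsfm
#' @export
predict_qpfm <- function(params, X) {
  p <- as.list(params)
  p$b0 + p$b1 * X + p$b2 * X^2
}

#' Goodness-of-fit statistics
#'
#' Computes the statistics reported alongside every fit: the residual sum of
#' squares SSE, total sum of squares SST (about the mean), goodness of fit
#' R2 = 1 - SSE/SST, the regression-versus-residual F statistic
#' F = (R2/(1-R2)) (n-p)/(p-1) on (p-1, n-p) degrees of freedom, and the
#' residual standard deviation S = sqrt(SSE/(n-p)). Significance stars mark
#' the 0.05 (*) and 0.01 (**) F quantiles.
#'
#' @param observed,predicted numeric vectors of equal length n > p.
#' @param p number of fitted parameters.
#' @return An object of class `"fit_statistics"`: a list with elements `n`,
#'   `p`, `sse`, `sst`, `r2`, `f`, `s`, `p_value`, `stars`.
#' @examples
#' fit_statistics(c(1, 2, 3, 5), c(1.1, 1.9, 3.2, 4.8), p = 2)
#' @export
fit_statistics <- function(observed, predicted, p) {
  n <- length(observed)
  if (length(predicted) != n) stop("observed and predicted differ in length")
  p <- as.integer(p)
  if (n <= p) stop("need n > p (n = ", n, ", p = ", p, ")")
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  f <- if (!is.na(r2) && r2 < 1) (r2 / (1 - r2)) * (n - p) / (p - 1) else Inf
  p_value <- stats::pf(f, p - 1, n - p, lower.tail = FALSE)
  stars <- if (is.na(p_value)) "" else
    if (p_value < 0.01) "**" else if (p_value < 0.05) "*" else ""
  structure(list(n = n, p = p, sse = sse, sst = sst, r2 = r2, f = f,
                 s = sqrt(sse / (n - p)), p_value = p_value, stars = stars),
            class = "fit_statistics")
}

#' @export
print.fit_statistics <- function(x, ...) {
  cat(sprintf("n = %d, p = %d, SSE = %.6g, R2 = %.4f, F = %.4g%s, S = %.4g\n",
              x$n, x$p, x$sse, x$r2, x$f, x$stars, x$s))
  invisible(x)
}

#' Fit a yield response model to a fertilizer trial
#'
#' Fits either the non-structural model Y = A(s0+X)e^(-cX) (`model = "nsfm"`)
#' or the quadratic polynomial Y = b0 + b1*X + b2*X^2 (`model = "qpfm"`) to a
#' [fertilizer_trial()].
#'
#' The quadratic model is ordinary least squares on regressors (1, X, X^2)
#' through a QR decomposition. The non-structural model is estimated by
#' separable nonlinear least squares (variable projection): for fixed c the
#' model Y = (A*s0 + A*X)e^(-cX) is linear in (A*s0, A), so the profiled SSE
#' is scanned over a log-spaced grid of c in `c_bounds` and refined by
#' Brent's method; this is deterministic, global over the searched interval,
#' and needs no starting values. The Taylor-map seed c0 = -2*b2/b1 from a
#' quadratic pre-fit is checked to lie inside `c_bounds` (a `"c_seed_outside
#' _bounds"` flag is raised otherwise). A fit whose profiled optimum has
#' A <= 0 is rejected; an optimum at the edge of `c_bounds` raises the
#' `"c_at_bound"` flag.
#'
#' @param trial a [fertilizer_trial()].
#' @param model `"nsfm"` or `"qpfm"`.
#' @param c_bounds search interval for c, hm2/kg. The default
#'   `c(1e-5, 5e-2)` covers the 1.9e-3 to 7.4e-3 range typical of N/P/K
#'   response in grain crops with wide margin.
#' @param grid_size number of grid points in the profile scan.
#' @return An object of class `c("nsfm_fit", "fert_fit")` or
#'   `c("qpfm_fit", "fert_fit")` with components `params`, `stats`
#'   ([fit_statistics()]), `trial`, `flags`; use `coef()`, `predict()`,
#'   `fitted()`, `residuals()`, `summary()`, `plot()` and (for nsfm)
#'   `simulate()` on it.
#' @examples
#' tr <- builtin_trials("rice")$rice_N_datian
#' fit <- fit_response(tr, "nsfm")
#' coef(fit)
#' recommend(fit)
#' @seealso [fit_marginal()], [recommend()], [compare_trials()]
#' @export
fit_response <- function(trial, model = c("nsfm", "qpfm"),
                         c_bounds = c(1e-5, 5e-2), grid_size = 400L) {
  stopifnot(inherits(trial, "fertilizer_trial"))
  model <- match.arg(model)
  X <- trial$rates; Y <- trial$yields
  cl <- match.call()
  if (model == "qpfm") {
    qr_ok <- qr(cbind(1, X, X^2))$rank == 3L
    if (!qr_ok) stop("rank-deficient design: need at least 3 distinct rates")
    ols <- stats::lm(Y ~ X + I(X^2))
    params <- qpfm_params(unname(coef(ols)[1]), unname(coef(ols)[2]),
                          unname(coef(ols)[3]))
    fitted_y <- unname(stats::fitted(ols))
    flags <- character(0)
    out <- new_fert_fit("qpfm_fit", model, params,
                        fit_statistics(Y, fitted_y, 3L), trial, X, Y,
                        fitted_y, flags, cl)
    return(out)
  }
  vp <- varpro_fit(X, Y, c_bounds = c_bounds, grid_size = grid_size)
  if (vp$q <= 0)
    stop("fit rejected: conversion coefficient A = ", signif(vp$q, 4),
         " is not positive at the profiled optimum")
  flags <- character(0)
  if (vp$at_bound) {
    warning("profiled optimum of c lies at a search bound; widen c_bounds")
    flags <- c(flags, "c_at_bound")
  }
  # Taylor-map seed from a quadratic pre-fit must fall in the searched grid
  b <- unname(coef(stats::lm(Y ~ X + I(X^2))))
  c_seed <- -2 * b[3] / b[2]
  if (is.finite(c_seed) && c_seed > 0 &&
      (c_seed < c_bounds[1] || c_seed > c_bounds[2])) {
    warning("quadratic-seeded c0 = ", signif(c_seed, 4),
            " lies outside c_bounds")
    flags <- c(flags, "c_seed_outside_bounds")
  }
  params <- nsfm_params(A = vp$q, c = vp$c, s0 = vp$p / vp$q)
  if (params[["s0"]] < 0) flags <- c(flags, "negative_s0")
  new_fert_fit("nsfm_fit", model, params, fit_statistics(Y, vp$fitted, 3L),
               trial, X, Y, vp$fitted, flags, cl,
               extra = list(c_bounds = c_bounds, grid_size = grid_size))
}

new_fert_fit <- function(subclass, model, params, stats, trial, x, y,
                         fitted, flags, call, extra = NULL) {
  obj <- list(model = model, params = params, stats = stats, trial = trial,
              x = x, y = y, fitted = fitted, residuals = y - fitted,
              flags = flags, call = call)
  if (!is.null(extra)) obj <- c(obj, extra)
  structure(obj, class = c(subclass, "fert_fit"))
}

#' Quadratic expansion of a non-structural model
#'
#' First-order Taylor expansion of the exponential (e^x = 1 + x + remainder)
#' turns Y = A(s0+X)e^(-cX) into the quadratic
#' Y = A*s0 + A(1 - c*s0)X - A*c*X^2, i.e. the quadratic polynomial model is
#' the truncation of the non-structural model. The truncation remainder
#' (x^2/2! + ...) is not computed; the map is exact only in the limit
#' c*X -> 0.
#'
#' @param params an [nsfm_params()] object.
#' @return The corresponding [qpfm_params()].
#' @examples
#' taylor_expand(nsfm_params(47.596, 0.003740, 105.12))
#' @export
taylor_expand <- function(params) {
  p <- as.list(params)
  qpfm_params(b0 = p$A * p$s0, b1 = p$A * (1 - p$c * p$s0), b2 = -p$A * p$c)
}
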