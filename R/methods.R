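# S3 methods shared by all fit classes.

#' @export
coef.fert_fit <- function(object, ...) unclass(object$params)

#' @export
fitted.fert_fit <- function(object, ...) object$fitted

#' @export
residuals.fert_fit <- function(object, ...) object$residuals

model_label <- function(model) {
  switch(model,
         nsfm = "non-structural response model Y = A(s0+X)exp(-cX)",
         qpfm = "quadratic polynomial response model Y = b0 + b1*X + b2*X^2",
         exp_marginal = "exponential marginal model dY/dX = A[1-c(s0+X)]exp(-cX)",
         linear_marginal = "linear marginal model y = a + b*X",
         model)
}

#' @export
print.fert_fit <- function(x, digits = 5, ...) {
  cat(model_label(x$model), "\n", sep = "")
  id <- if (!is.null(x$trial)) x$trial$trial_id else x$trial_id
  if (!is.null(id)) cat("data: ", id, "\n", sep = "")
  print(signif(unclass(x$params), digits))
  print(x$stats)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.fert_fit <- function(object, ...) {
  structure(object, class = c("summary.fert_fit", class(object)))
}

#' @export
print.summary.fert_fit <- function(x, digits = 6, ...) {
  cat(model_label(x$model), "\n", sep = "")
  id <- if (!is.null(x$trial)) x$trial$trial_id else x$trial_id
  if (!is.null(id)) cat("data: ", id, "\n", sep = "")
  cat("\nCoefficients:\n")
  print(signif(unclass(x$params), digits))
  s <- x$stats
  cat(sprintf(paste0("\nn = %d, parameters = %d\nSSE = %.6g, SST = %.6g\n",
                     "R2 = %.4f\nF(%d, %d) = %.4g%s (p = %.3g)\n",
                     "residual SD S = %.4g\n"),
              s$n, s$p, s$sse, s$sst, s$r2, s$p - 1L, s$n - s$p, s$f,
              s$stars, s$p_value, s$s))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  if (inherits(x, "nsfm_fit")) {
    p <- as.list(x$params)
    cat(sprintf("agronomic maximum rate 1/c - s0 = %.4g kg/hm2\n",
                1 / p$c - p$s0))
  }
  invisible(x)
}

#' Predict method for fitted response and marginal models
#'
#' @param object a fit from [fit_response()] or [fit_marginal()].
#' @param newdata application rates (numeric vector), or a data frame with a
#'   `rate_kg_hm2` (or `x`) column; defaults to the rates the model was
#'   fitted at.
#' @param ... unused.
#' @return Predicted yield (response fits) or marginal yield (marginal fits).
#' @export
predict.fert_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- if (is.data.frame(newdata)) {
    col <- intersect(c("rate_kg_hm2", "x", "rate"), names(newdata))[1]
    if (is.na(col)) stop("newdata needs a rate_kg_hm2 (or x) column")
    newdata[[col]]
  } else as.numeric(newdata)
  switch(object$model,
         nsfm = predict_nsfm(object$params, X),
         qpfm = predict_qpfm(object$params, X),
         exp_marginal = predict_marginal_nsfm(object$params, X),
         linear_marginal = object$params[["a"]] + object$params[["b"]] * X)
}

#' Plot a fitted dose-response or marginal model
#'
#' Observed points (with +-1 SD bars when the trial carries replicate SDs)
#' and the fitted curve on a fine rate grid.
#'
#' @param x a `fert_fit`.
#' @param n_grid number of points for the curve.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fert_fit <- function(x, n_grid = 200L, ...) {
  marginal <- x$model %in% c("exp_marginal", "linear_marginal")
  ylab <- if (marginal) "marginal yield (kg/kg)" else "yield (kg/hm2)"
  grid <- seq(min(x$x), max(x$x), length.out = n_grid)
  curve_y <- predict(x, grid)
  ylim <- range(x$y, curve_y)
  if (!marginal && !is.null(x$trial$yield_sd))
    ylim <- range(ylim, x$y + x$trial$yield_sd, x$y - x$trial$yield_sd)
  graphics::plot(x$x, x$y, xlab = "application rate (kg/hm2)", ylab = ylab,
                 ylim = ylim, pch = 19, ...)
  if (!marginal && !is.null(x$trial$yield_sd))
    graphics::arrows(x$x, x$y - x$trial$yield_sd, x$x, x$y + x$trial$yield_sd,
                     angle = 90, code = 3, length = 0.03)
  graphics::lines(grid, curve_y)
  invisible(x)
}

#' Simulate trials from a fitted non-structural model
#'
#' Draws new trials from the fitted curve at the original design rates with
#' homoscedastic Gaussian plot noise; the noise SD defaults to the fit's
#' residual standard deviation.
#'
#' @param object an `nsfm_fit`.
#' @param nsim number of trials to draw.
#' @param seed integer seed (required: simulation is always explicit about
#'   its entropy).
#' @param noise_sd,n_reps passed to [simulate_trial()].
#' @param ... unused.
#' @return A list of `nsim` [fertilizer_trial()] objects.
#' @export
simulate.nsfm_fit <- function(object, nsim = 1, seed = NULL,
                              noise_sd = object$stats$s,
                              n_reps = 3L, ...) {
  if (is.null(seed)) stop("simulate() needs an explicit integer seed")
  lapply(seq_len(nsim), function(i)
    simulate_trial(object$params, rates = object$x, noise_sd = noise_sd,
                   n_reps = n_reps, seed = seed + i - 1L,
                   trial_id = sprintf("sim_%d", i)))
}
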