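#' Nutrient and product prices
#'
#' Carries the price ratio beta = Px/Py (kg product per kg nutrient) used by
#' the economic-optimum rate: at the economic rate the marginal yield dY/dX
#' equals beta. Give either both unit prices or beta directly.
#'
#' @param px price per kg nutrient (currency/kg).
#' @param py price per kg product (currency/kg).
#' @param beta the ratio px/py; alternative to giving the two prices.
#' @return An object of class `"price_context"` with elements `px`, `py`,
#'   `beta`.
#' @examples
#' price_context(px = 6, py = 2.4)  # beta = 2.5
#' price_context(beta = 5)
#' @export
price_context <- function(px = NULL, py = NULL, beta = NULL) {
  if (is.null(beta)) {
    if (is.null(px) || is.null(py)) stop("give px and py, or beta")
    if (px <= 0 || py <= 0) stop("prices must be positive")
    beta <- px / py
  } else {
    if (beta < 0) stop("beta must be non-negative")
  }
  structure(list(px = px, py = py, beta = beta), class = "price_context")
}

#' Recommended fertilization rates
#'
#' Computes the agronomic-maximum rate (the rate maximizing predicted yield)
#' and, when prices are supplied, the economic-optimum rate (the rate at
#' which the marginal yield equals the nutrient/product price ratio beta).
#'
#' For the non-structural model the maximum rate is the closed form
#' X_max = 1/c - s0, and the economic rate solves
#' X_eco = 1/(c + beta/Y_eco) - s0, where Y_eco, the yield at the economic
#' rate, is itself unknown. It is resolved by fixed-point iteration started
#' from Y_max: X_k = 1/(c + beta/Y_{k-1}) - s0, Y_k = Y(X_k), stopping when
#' successive rates move by less than `tol`; the fixed point satisfies
#' dY/dX = beta exactly. Three to five iterations typically suffice;
#' `max_iter` is a generous safety margin. For the quadratic model both
#' rates are closed forms: X_max = -b1/(2 b2) (requires b2 < 0) and
#' X_eco = (beta - b1)/(2 b2), clipped at zero (with a flag) when negative.
#'
#' A negative X_max (soil supply alone past the optimum, as in high-fertility
#' paddies) is reported as-is with a `"negative_x_max"` flag rather than
#' clipped, so the signal is preserved.
#'
#' @param object a fit from [fit_response()], or an [nsfm_params()] /
#'   [qpfm_params()] object.
#' @param prices a [price_context()], or `NULL` for the agronomic maximum
#'   only. With `beta = 0` the economic rate equals the maximum rate exactly.
#' @param tol convergence tolerance on the rate, kg/hm2 (0.01 is far below
#'   agronomic relevance).
#' @param max_iter iteration cap; exceeding it is an error carrying the
#'   iterate trace (condition class `"fertresp_nonconvergence"`).
#' @param ... passed between methods.
#' @return An object of class `"recommendation"`: a list with `x_max`,
#'   `y_max`, and when prices are given `x_eco`, `y_eco`, `beta`,
#'   `n_iterations`, `converged`, `trace`; plus `flags` and `model`.
#' @examples
#' p <- nsfm_params(47.596, 0.003740, 105.12)
#' recommend(p)                            # x_max ~ 162.3
#' recommend(p, price_context(beta = 5))   # x_eco < x_max
#' @export
recommend <- function(object, ...) UseMethod("recommend")

#' @rdname recommend
#' @export
recommend.nsfm_params <- function(object, prices = NULL, tol = 0.01,
                                  max_iter = 50L, ...) {
  p <- as.list(object)
  flags <- character(0)
  x_max <- 1 / p$c - p$s0
  y_max <- predict_nsfm(object, x_max)
  if (x_max < 0) flags <- c(flags, "negative_x_max")
  rec <- list(model = "nsfm", x_max = x_max, y_max = y_max, flags = flags)
  if (!is.null(prices)) {
    beta <- prices$beta
    rec$beta <- beta
    if (beta == 0) {
      rec$x_eco <- x_max; rec$y_eco <- y_max
      rec$n_iterations <- 1L; rec$converged <- TRUE; rec$trace <- x_max
    } else {
      y <- y_max; x_prev <- x_max; trace <- numeric(0)
      converged <- FALSE; k <- 0L
      while (k < max_iter) {
        k <- k + 1L
        x_new <- 1 / (p$c + beta / y) - p$s0
        y <- predict_nsfm(object, x_new)
        trace <- c(trace, x_new)
        if (abs(x_new - x_prev) < tol) { converged <- TRUE; break }
        x_prev <- x_new
      }
      if (!converged)
        stop(structure(class = c("fertresp_nonconvergence", "error",
                                 "condition"),
                       list(message = paste0("economic-rate iteration did ",
                                             "not converge in ", max_iter,
                                             " steps"),
                            call = sys.call(-1), trace = trace)))
      rec$x_eco <- x_new; rec$y_eco <- y
      rec$n_iterations <- k; rec$converged <- TRUE; rec$trace <- trace
      if (x_new < 0) rec$flags <- c(rec$flags, "negative_x_eco")
    }
  }
  structure(rec, class = "recommendation")
}

#' @rdname recommend
#' @export
recommend.qpfm_params <- function(object, prices = NULL, ...) {
  p <- as.list(object)
  if (p$b2 >= 0)
    stop("no interior maximum: quadratic coefficient b2 = ", signif(p$b2, 4),
         " is not negative")
  flags <- character(0)
  x_max <- -p$b1 / (2 * p$b2)
  if (x_max < 0) flags <- c(flags, "negative_x_max")
  rec <- list(model = "qpfm", x_max = x_max,
              y_max = predict_qpfm(object, x_max), flags = flags)
  if (!is.null(prices)) {
    beta <- prices$beta
    x_eco <- (beta - p$b1) / (2 * p$b2)
    if (x_eco < 0) {
      x_eco <- 0
      rec$flags <- c(rec$flags, "x_eco_clipped_to_zero")
    }
    rec$beta <- beta
    rec$x_eco <- x_eco
    rec$y_eco <- predict_qpfm(object, x_eco)
    rec$n_iterations <- 1L
    rec$converged <- TRUE
  }
  structure(rec, class = "recommendation")
}

#' @rdname recommend
#' @export
recommend.fert_fit <- function(object, prices = NULL, ...) {
  if (!inherits(object$params, c("nsfm_params", "qpfm_params")))
    stop("recommendation needs a yield-model fit (nsfm or qpfm)")
  rec <- recommend(object$params, prices = prices, ...)
  rec$trial_id <- if (!is.null(object$trial)) object$trial$trial_id
  rec
}

#' @export
print.recommendation <- function(x, ...) {
  cat(sprintf("%s recommendation%s\n", x$model,
              if (!is.null(x$trial_id)) paste0(" for ", x$trial_id) else ""))
  cat(sprintf("  agronomic maximum: X_max = %.2f kg/hm2, Y_max = %.1f kg/hm2\n",
              x$x_max, x$y_max))
  if (!is.null(x$x_eco))
    cat(sprintf(paste0("  economic optimum (beta = %.3g): X_eco = %.2f ",
                       "kg/hm2, Y_eco = %.1f kg/hm2 (%d iteration%s)\n"),
                x$beta, x$x_eco, x$y_eco, x$n_iterations,
                if (x$n_iterations == 1L) "" else "s"))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Typicality diagnosis of a quadratic response fit
#'
#' A quadratic polynomial response fit is "typical" (conforms to the general
#' fertilizer-efficiency rule) when all four conditions hold: (1) the
#' monomial coefficient b1 is positive; (2) the quadratic coefficient b2 is
#' negative; (3) the fitted maximum lies within the tested range; (4) the
#' recommended rates derived by the marginal-product method (the maximum
#' rate and, when prices are given, the economic rate) fall within the range
#' of rates in the trial design. Conditions (3) and (4) are both evaluated
#' against the design rate range `[min(rates), max(rates)]`.
#'
#' @param fit a `qpfm_fit` from [fit_response()].
#' @param prices optional [price_context()]; when given the economic rate
#'   enters condition (4).
#' @return An object of class `"typicality_report"`: logical flags
#'   `monomial_positive`, `quadratic_negative`, `max_in_range`,
#'   `rates_in_design`, and their conjunction `typical`, plus the rates used.
#' @examples
#' fit <- fit_response(builtin_trials("rice")$rice_N_datian, "qpfm")
#' classify_typicality(fit)
#' @export
classify_typicality <- function(fit, prices = NULL) {
  stopifnot(inherits(fit, "qpfm_fit"))
  p <- as.list(fit$params)
  rng <- range(fit$trial$rates)
  monomial_positive <- p$b1 > 0
  quadratic_negative <- p$b2 < 0
  x_max <- if (quadratic_negative) -p$b1 / (2 * p$b2) else NA_real_
  max_in_range <- isTRUE(x_max >= rng[1] && x_max <= rng[2])
  rates_in_design <- max_in_range
  x_eco <- NA_real_
  if (!is.null(prices) && quadratic_negative) {
    rec <- recommend(fit$params, prices = prices)
    x_eco <- rec$x_eco
    rates_in_design <- rates_in_design &&
      isTRUE(x_eco >= rng[1] && x_eco <= rng[2])
  }
  structure(list(monomial_positive = monomial_positive,
                 quadratic_negative = quadratic_negative,
                 max_in_range = max_in_range,
                 rates_in_design = rates_in_design,
                 typical = monomial_positive && quadratic_negative &&
                   max_in_range && rates_in_design,
                 x_max = x_max, x_eco = x_eco, design_range = rng),
            class = "typicality_report")
}

#' @export
print.typicality_report <- function(x, ...) {
  ok <- function(b) if (b) "yes" else "NO"
  cat("typicality of quadratic response fit:\n")
  cat("  (1) b1 > 0:                 ", ok(x$monomial_positive), "\n")
  cat("  (2) b2 < 0:                 ", ok(x$quadratic_negative), "\n")
  cat("  (3) maximum within design:  ", ok(x$max_in_range), "\n")
  cat("  (4) recommended rates in design:", ok(x$rates_in_design), "\n")
  cat("  => ", if (x$typical) "typical" else "non-typical", "\n")
  invisible(x)
}
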