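#' Pearson correlation with validity checks
#'
#' Thin, checked surface over [stats::cor()]: requires at least 3 pairs and
#' nonzero variance in both vectors.
#'
#' @param x,y numeric vectors of equal length.
#' @return The sample Pearson correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in x or y")
  stats::cor(x, y)
}

#' Fit both response models across a set of trials
#'
#' Fits the non-structural and the quadratic model to each trial, derives
#' the recommended rates, and flags significance of each fit at the 0.05
#' F-quantile. Per-trial fit errors become a row-level `error` record, not a
#' batch abort.
#'
#' @param trials a list of [fertilizer_trial()] objects.
#' @param prices optional [price_context()]; adds economic rates.
#' @param c_bounds,grid_size passed to [fit_response()].
#' @return A data frame of class `"comparison_table"`, one row per trial:
#'   coefficients and statistics of both fits, `x_max_nsfm`, `x_max_qpfm`
#'   (and `x_eco_*` when prices given), significance flags, and `error`
#'   (NA on success).
#' @examples
#' compare_trials(builtin_trials("rice"))
#' @export
compare_trials <- function(trials, prices = NULL, c_bounds = c(1e-5, 5e-2),
                           grid_size = 400L) {
  rows <- lapply(trials, function(tr) {
    base <- data.frame(trial_id = tr$trial_id, nutrient = tr$nutrient,
                       n = length(tr$rates), stringsAsFactors = FALSE)
    out <- tryCatch({
      nf <- fit_response(tr, "nsfm", c_bounds = c_bounds,
                         grid_size = grid_size)
      qf <- fit_response(tr, "qpfm")
      nrec <- recommend(nf$params, prices = prices)
      qrec <- tryCatch(recommend(qf$params, prices = prices),
                       error = function(e) NULL)
      row <- cbind(base,
                   data.frame(A = nf$params[["A"]], c = nf$params[["c"]],
                              s0 = nf$params[["s0"]], nsfm_f = nf$stats$f,
                              nsfm_r2 = nf$stats$r2, nsfm_s = nf$stats$s,
                              nsfm_significant = nf$stats$p_value < 0.05,
                              b0 = qf$params[["b0"]], b1 = qf$params[["b1"]],
                              b2 = qf$params[["b2"]], qpfm_f = qf$stats$f,
                              qpfm_r2 = qf$stats$r2, qpfm_s = qf$stats$s,
                              qpfm_significant = qf$stats$p_value < 0.05,
                              x_max_nsfm = nrec$x_max,
                              x_max_qpfm = if (is.null(qrec)) NA_real_
                                           else qrec$x_max))
      if (!is.null(prices)) {
        row$x_eco_nsfm <- nrec$x_eco
        row$x_eco_qpfm <- if (is.null(qrec)) NA_real_ else qrec$x_eco
      }
      row$error <- NA_character_
      row
    }, error = function(e) {
      base$error <- conditionMessage(e)
      base
    })
    out
  })
  if (length(rows) == 0L) {
    empty <- data.frame(trial_id = character(0), nutrient = character(0),
                        n = integer(0), error = character(0),
                        stringsAsFactors = FALSE)
    class(empty) <- c("comparison_table", "data.frame")
    return(empty)
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (col in setdiff(all_cols, names(r))) r[[col]] <- NA
    r[all_cols]
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("comparison_table", "data.frame")
  res
}

#' Published reference coefficients for the bundled trials
#'
#' The coefficient tables published for the bundled field experiments:
#' `"rice"` has 18 rows (N/P2O5/K2O rice experiments; both models with their
#' F, R2, S and significance stars; only rows 1, 4 and 7 correspond to
#' trials whose raw yields are bundled), `"wheat"` has 9 rows matching
#' `builtin_trials("wheat")`, and `"marginal"` has the marginal-model
#' (exponential and linear) coefficients for the three rice series.
#'
#' In the wheat table the `rate_factor` column records the rate basis of the
#' published coefficients: trials fertilized with a carrier product (urea,
#' calcium superphosphate) were fitted on rates converted to nutrient basis
#' (0.46 kg N per kg urea, 0.12 kg P2O5 per kg superphosphate); refitting
#' the bundled product-basis rates reproduces the published statistics
#' exactly and the published coefficients after the scale map
#' (A, c, s0) -> (A/k, c/k, k*s0).
#'
#' @param which `"rice"`, `"wheat"` or `"marginal"`.
#' @return A data frame; `c` is in hm2/kg (natural units, not the printed
#'   c*10^3), significance columns hold `"**"`, `"*"` or `""`.
#' @export
builtin_coefficients <- function(which = c("rice", "wheat", "marginal")) {
  which <- match.arg(which)
  file <- system.file("extdata", paste0(which, "_coefficients.csv"),
                      package = "fertresp", mustWork = TRUE)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  for (col in intersect(c("nsfm_sig", "qpfm_sig", "exp_sig", "lin_sig"),
                        names(df)))
    df[[col]][is.na(df[[col]])] <- ""
  df
}

#' Correlation of recommended rates between the two models
#'
#' For each coefficient pair computes the recommended rate (maximum or
#' economic) under both the non-structural and the quadratic model, and
#' returns the Pearson correlation of the paired rates. Accepts published
#' coefficient tables directly ([builtin_coefficients()]) so reference
#' comparisons need no raw data.
#'
#' @param coeffs a data frame with columns `A`, `c`, `s0`, `b1`, `b2` (and
#'   `b0` when `which = "eco"`), one row per experiment.
#' @param which `"max"` or `"eco"` (the latter requires `prices`).
#' @param prices a [price_context()], required for `which = "eco"`.
#' @return An object of class `"correlation_summary"`: `r`, `n`, `which`,
#'   and the paired rates in `$rates`.
#' @examples
#' rice <- builtin_coefficients("rice")
#' recommendation_correlation(rice[rice$qpfm_sig != "", ])
#' @export
recommendation_correlation <- function(coeffs, which = c("max", "eco"),
                                       prices = NULL) {
  which <- match.arg(which)
  if (which == "eco" && is.null(prices))
    stop("which = \"eco\" requires prices")
  if (nrow(coeffs) < 3L) stop("need at least 3 coefficient pairs")
  rate_one <- function(i) {
    np <- nsfm_params(coeffs$A[i], coeffs$c[i], coeffs$s0[i])
    qp <- qpfm_params(if ("b0" %in% names(coeffs)) coeffs$b0[i] else 0,
                      coeffs$b1[i], coeffs$b2[i])
    if (which == "max")
      c(recommend(np)$x_max, recommend(qp)$x_max)
    else
      c(recommend(np, prices = prices)$x_eco,
        recommend(qp, prices = prices)$x_eco)
  }
  rates <- t(vapply(seq_len(nrow(coeffs)), rate_one, numeric(2)))
  df <- data.frame(x_nsfm = rates[, 1], x_qpfm = rates[, 2])
  if ("no" %in% names(coeffs)) df <- cbind(no = coeffs$no, df)
  structure(list(r = pearson_r(df$x_nsfm, df$x_qpfm), n = nrow(df),
                 which = which, rates = df),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf("Pearson r of %s-rate recommendations (nsfm vs qpfm): %.4f (n = %d)\n",
              x$which, x$r, x$n))
  invisible(x)
}

#' Per-nutrient ratio of recommended rates
#'
#' Summarizes, per nutrient group, how much lower (or higher) the
#' non-structural model's recommended rate is than the quadratic model's.
#' Both natural aggregations are available: the mean of per-trial ratios
#' (default) and the ratio of group means.
#'
#' @param rows a data frame with columns `nutrient`, `x_<which>_nsfm`,
#'   `x_<which>_qpfm` — e.g. the output of [compare_trials()], or rates
#'   derived from [builtin_coefficients()].
#' @param which `"max"` or `"eco"`.
#' @param method `"mean_of_ratios"` or `"ratio_of_means"`.
#' @return A data frame with columns `nutrient`, `n`, `ratio` (NSFM rate as
#'   a fraction of the QPFM rate). Empty groups are dropped with a warning.
#' @export
ratio_summary <- function(rows, which = c("max", "eco"),
                          method = c("mean_of_ratios", "ratio_of_means")) {
  which <- match.arg(which)
  method <- match.arg(method)
  cn <- paste0("x_", which, "_nsfm"); cq <- paste0("x_", which, "_qpfm")
  if (!all(c("nutrient", cn, cq) %in% names(rows)))
    stop("rows must have columns nutrient, ", cn, ", ", cq)
  keep <- !is.na(rows[[cn]]) & !is.na(rows[[cq]])
  dropped <- unique(rows$nutrient[!keep])
  rows <- rows[keep, ]
  if (length(dropped) && !any(rows$nutrient %in% dropped))
    warning("group(s) without both recommendations omitted: ",
            paste(dropped, collapse = ", "))
  groups <- split(rows, rows$nutrient)
  out <- do.call(rbind, lapply(groups, function(g) {
    ratio <- if (method == "mean_of_ratios") mean(g[[cn]] / g[[cq]])
             else mean(g[[cn]]) / mean(g[[cq]])
    data.frame(nutrient = g$nutrient[1], n = nrow(g), ratio = ratio,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
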