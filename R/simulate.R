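# Trial simulation from the generative non-structural model, and
# parameter-recovery experiments for the estimator.

with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a fertilizer trial from the non-structural model
#'
#' Generates one trial: at each design rate, `n_reps` plot yields are drawn
#' from N(A(s0+X)e^(-cX), noise_sd^2); the trial stores their mean and
#' sample SD. The draw is fully determined by `seed`. The default noise SD
#' of 150 kg/hm2 sits in the middle of the replicate SDs observed in the
#' bundled 8-level rice trials (33 to 379 kg/hm2); noise is homoscedastic
#' Gaussian on plot yields, with no block or spatial effects.
#'
#' @param params an [nsfm_params()] object (the true curve).
#' @param rates design rates, kg/hm2 (must satisfy the trial invariants).
#' @param noise_sd plot-level Gaussian SD, kg/hm2 (0 gives the exact curve).
#' @param n_reps replicates per rate (>= 1; the SD is stored only when
#'   `n_reps >= 2`).
#' @param seed integer seed; required.
#' @param trial_id,crop,nutrient passed to the trial constructor.
#' @return A [fertilizer_trial()].
#' @examples
#' simulate_trial(nsfm_params(47.6, 0.00374, 105),
#'                rates = seq(0, 262.5, 37.5), noise_sd = 150, seed = 1)
#' @export
simulate_trial <- function(params, rates, noise_sd = 150, n_reps = 3L,
                           seed, trial_id = "sim", crop = "rice",
                           nutrient = "N") {
  stopifnot(noise_sd >= 0, n_reps >= 1L)
  if (missing(seed)) stop("simulate_trial() requires an explicit seed")
  mu <- predict_nsfm(params, rates)
  draws <- with_seed(seed,
    matrix(stats::rnorm(length(rates) * n_reps, mean = rep(mu, each = n_reps),
                        sd = noise_sd),
           nrow = n_reps))
  means <- colMeans(draws)
  sds <- if (n_reps >= 2L) apply(draws, 2, stats::sd)
  fertilizer_trial(trial_id, rates = rates, yields = means, crop = crop,
                   nutrient = nutrient, yield_sd = sds, n_reps = n_reps,
                   metadata = list(true_params = unclass(params),
                                   noise_sd = noise_sd, seed = seed))
}

#' Parameter-recovery experiment for the non-structural estimator
#'
#' Repeats simulate-then-fit `n_sims` times (per-replicate seeds are
#' `seed, seed+1, ...`) and reports, for A, c, s0 and the derived maximum
#' rate X_max = 1/c - s0, the mean estimate, bias and root-mean-square error
#' against the generating values. Individual fit failures are counted, not
#' fatal.
#'
#' @inheritParams simulate_trial
#' @param n_sims number of simulated trials.
#' @param c_bounds,grid_size passed to [fit_response()].
#' @return An object of class `"recovery_report"`: a list with the summary
#'   data frame `$summary` (columns `parameter`, `true`, `mean_est`, `bias`,
#'   `rmse`), `$estimates` (one row per successful fit), `n_sims`,
#'   `n_failed`.
#' @examples
#' recovery_experiment(nsfm_params(47.6, 0.00374, 105),
#'                     rates = seq(0, 262.5, 37.5), noise_sd = 150,
#'                     seed = 1, n_sims = 20)
#' @export
recovery_experiment <- function(params, rates, noise_sd = 150, n_reps = 3L,
                                seed, n_sims = 100L,
                                c_bounds = c(1e-5, 5e-2), grid_size = 400L) {
  stopifnot(n_sims >= 1L)
  if (missing(seed)) stop("recovery_experiment() requires an explicit seed")
  ests <- vector("list", n_sims)
  n_failed <- 0L
  for (i in seq_len(n_sims)) {
    ests[[i]] <- tryCatch({
      tr <- simulate_trial(params, rates, noise_sd = noise_sd,
                           n_reps = n_reps, seed = seed + i - 1L,
                           trial_id = sprintf("sim_%d", i))
      fit <- fit_response(tr, "nsfm", c_bounds = c_bounds,
                          grid_size = grid_size)
      est <- coef(fit)
      data.frame(A = est[["A"]], c = est[["c"]], s0 = est[["s0"]],
                 x_max = 1 / est[["c"]] - est[["s0"]])
    }, error = function(e) NULL)
    if (is.null(ests[[i]])) n_failed <- n_failed + 1L
  }
  est <- do.call(rbind, ests)
  if (is.null(est) || nrow(est) == 0L)
    stop("all ", n_sims, " simulated fits failed")
  p <- as.list(params)
  truth <- c(A = p$A, c = p$c, s0 = p$s0, x_max = 1 / p$c - p$s0)
  summ <- do.call(rbind, lapply(names(truth), function(nm) {
    e <- est[[nm]]
    data.frame(parameter = nm, true = truth[[nm]], mean_est = mean(e),
               bias = mean(e) - truth[[nm]],
               rmse = sqrt(mean((e - truth[[nm]])^2)),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, estimates = est, n_sims = n_sims,
                 n_failed = n_failed, noise_sd = noise_sd, rates = rates,
                 seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, digits = 4, ...) {
  cat(sprintf("parameter recovery over %d simulations (%d failed), noise SD %.4g\n",
              x$n_sims, x$n_failed, x$noise_sd))
  s <- x$summary
  s[-1] <- lapply(s[-1], signif, digits)
  print(s, row.names = FALSE)
  invisible(x)
}
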