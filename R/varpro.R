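# Separable least squares for curves of the form y = (p + q*x) * exp(-c*x).
#
# Both response surfaces fitted by this package are linear in two parameters
# once the decay constant c is fixed:
#   yield curve     Y     = (A*s0 + A*X) e^{-cX}          (p = A*s0, q = A)
#   marginal curve  dY/dX = (u - v*X) e^{-cX}             (p = u, q = -v)
# so the 3-parameter nonlinear problem reduces to a 1-D profile over c:
# for each c solve the 2-column OLS on basis (e^{-cx}, x e^{-cx}) by QR,
# then minimize the profiled SSE over c. The profile is scanned on a
# log-spaced grid and refined with Brent's method on log(c); this is
# deterministic and needs no starting values.
#
# Returns c, the linear coefficients (p, q), the SSE, fitted values, and a
# flag when the optimum sits at a search bound.
varpro_fit <- function(x, y, c_bounds = c(1e-5, 5e-2), grid_size = 400L) {
  stopifnot(length(x) == length(y), length(x) >= 4L,
            length(c_bounds) == 2L, c_bounds[1] > 0,
            c_bounds[2] > c_bounds[1], grid_size >= 10L)
  profile_sse <- function(log_c) {
    cc <- exp(log_c)
    e <- exp(-cc * x)
    sum(stats::lm.fit(cbind(e, x * e), y)$residuals^2)
  }
  log_grid <- seq(log(c_bounds[1]), log(c_bounds[2]), length.out = grid_size)
  sse_grid <- vapply(log_grid, profile_sse, numeric(1))
  i <- which.min(sse_grid)
  lo <- log_grid[max(1L, i - 2L)]
  hi <- log_grid[min(grid_size, i + 2L)]
  opt <- stats::optimize(profile_sse, c(lo, hi), tol = 1e-10)
  c_hat <- exp(opt$minimum)
  e <- exp(-c_hat * x)
  ols <- stats::lm.fit(cbind(e, x * e), y)
  at_bound <- i == 1L || i == grid_size ||
    c_hat / c_bounds[1] < 1.001 || c_bounds[2] / c_hat < 1.001
  list(c = c_hat,
       p = unname(ols$coefficients[1]),
       q = unname(ols$coefficients[2]),
       sse = sum(ols$residuals^2),
       fitted = as.vector(cbind(e, x * e) %*% ols$coefficients),
       at_bound = at_bound)
}
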