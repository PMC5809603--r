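# Shared fixtures and independent oracles, all built in code.

# a clean synthetic trial lying exactly on a non-structural curve
noiseless_trial <- function(A = 60, c = 0.005, s0 = 90,
                            rates = seq(0, 262.5, by = 37.5)) {
  fertilizer_trial("noiseless", rates = rates,
                   yields = predict_nsfm(nsfm_params(A, c, s0), rates))
}

# brute-force grid argmax of an objective over [0, upper]
grid_argmax <- function(f, upper, step = 0.05) {
  x <- seq(0, upper, by = step)
  x[which.max(f(x))]
}

# profiled SSE of the separable model (p + q x)e^{-cx} at a fixed c,
# written independently of the package internals
profile_sse_at <- function(c, x, y) {
  e <- exp(-c * x)
  B <- cbind(e, x * e)
  beta <- solve(crossprod(B), crossprod(B, y))
  sum((y - B %*% beta)^2)
}

trials_csv <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(c("trial_id,site,crop,nutrient,rate_kg_hm2,yield_kg_hm2,yield_sd_kg_hm2",
               lines), file)
  file
}
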