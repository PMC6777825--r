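# Independent oracles used across the suite.  These deliberately do not
# share code with the package internals they check.

R_KCAL <- 1.9872e-3

# Analytic derivative of the closed-form noiseless melt curve
# (baseline + sum of logistic components, no quench):
# dF/dT = b1 + sum_i A_i (dH_i / (R T_K^2)) f_i (1 - f_i)
analytic_dfdt <- function(temp_C, transitions, baseline_slope = 0.005) {
  TK <- temp_C + 273.15
  d <- rep(baseline_slope, length(temp_C))
  for (tr in transitions) {
    TmK <- tr$tm_true + 273.15
    f <- 1 / (1 + exp((tr$dh_vh / R_KCAL) * (1 / TK - 1 / TmK)))
    d <- d + tr$amplitude * (tr$dh_vh / (R_KCAL * TK^2)) * f * (1 - f)
  }
  d
}

# Numeric root-finder on the implicit Schellman relation
# dTm = Tm*T0*R/dH0 * ln(1 + L/Kd), Tm = T0 + dTm
schellman_tm_root <- function(L, kd, dh0, t0) {
  g <- function(tm) (tm - t0) - tm * t0 * R_KCAL / dh0 * log1p(L / kd)
  uniroot(g, c(t0, t0 + 60), tol = 1e-12)$root
}

# Brute-force Pearson correlation via the covariance formula
pearson_bruteforce <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# Construct a bare melt_curve object without the simulator
make_curve <- function(temperature_C, fluorescence, well_id = "X",
                       ligand_id = "buffer", conc_uM = 0) {
  structure(list(well_id = well_id, ligand_id = ligand_id,
                 conc_uM = conc_uM, temperature_C = temperature_C,
                 fluorescence = fluorescence),
            class = "melt_curve")
}
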