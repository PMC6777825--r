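#' Predict the ligand-shifted melting temperature (Schellman model)
#'
#' Forward form of the two-state reversible-unfolding link between ligand
#' concentration and melting-point elevation,
#' \deqn{\Delta T_m = T_m - T_0 = \frac{T_m T_0 R}{\Delta H^0}
#'       \ln\!\left(1 + \frac{[L]}{K_{d\mathrm{-app}}}\right),}
#' solved in closed form for \eqn{T_m}:
#' \deqn{T_m = \frac{T_0}{1 - T_0 R \ln(1 + [L]/K_d)/\Delta H^0}.}
#'
#' The model assumes reversible unfolding, a concentration-independent
#' \eqn{K_d} over the shift range, and no heat-capacity term.
#'
#' @param L ligand concentration(s), uM.  Zero is allowed and returns `t0`.
#' @param kd_app apparent dissociation constant, uM.
#' @param dh0 van 't Hoff unfolding enthalpy at `t0`, kcal mol^-1.
#' @param t0 melting temperature without ligand, K.
#' @return Predicted Tm in kelvin, vectorized over `L`.
#' @examples
#' predict_tm(300, kd_app = 30.9, dh0 = 72.1, t0 = 326.2) - 326.2  # ~7.11 K
#' @seealso [estimate_kd_single_point()] for the inverse,
#'   [fit_dose_series()] for fitting.
#' @export
predict_tm <- function(L, kd_app, dh0, t0) {
  stopifnot(all(L >= 0), kd_app > 0, dh0 > 0, t0 > 0)
  denom <- 1 - t0 * GAS_CONSTANT_KCAL * log1p(L / kd_app) / dh0
  if (any(denom <= 0)) {
    stop(sprintf(paste0(
      "infeasible shift: t0*R*ln(1 + L/kd_app)/dh0 = %.4g >= 1 at ",
      "L = %g uM; the predicted transition runs away beyond the model's ",
      "validity"), max(t0 * GAS_CONSTANT_KCAL * log1p(L / kd_app) / dh0),
      L[which.max(log1p(L / kd_app))]))
  }
  t0 / denom
}

# Guarded variant used inside optimizers: clamps the denominator instead of
# erroring so that infeasible trial parameters yield huge (penalising)
# residuals rather than an exception.
predict_tm_guarded <- function(L, kd_app, dh0, t0) {
  denom <- 1 - t0 * GAS_CONSTANT_KCAL * log1p(L / kd_app) / dh0
  t0 / pmax(denom, 1e-6)
}

#' Fit a Tm dose series to the Schellman model
#'
#' Unweighted nonlinear least squares of replicate-averaged Tm against
#' [predict_tm()] with `t0` fixed, estimating the apparent dissociation
#' constant and the unfolding enthalpy.  Positivity of both parameters is
#' enforced by fitting on the log scale; a small multistart over initial
#' enthalpies guards against local minima.  Standard errors are delta-method
#' transforms of the log-scale covariance at the optimum.
#'
#' @param series data.frame with columns `conc_uM` and `mean_tm_K` (one row
#'   per concentration; use [summarize_replicates()] to average replicates
#'   first), optionally `sem_tm_K` when `weighted = TRUE`.
#' @param t0 fixed no-ligand melting temperature, K.
#' @param weighted if `TRUE`, weight points by `1/sem_tm_K^2`.  Off by
#'   default: the reference analysis fits plain averaged Tm values.
#' @param dh0_starts multistart grid of initial enthalpies, kcal mol^-1.
#' @return An object of class `schellman_fit`: a list with `kd_app_uM`,
#'   `dh0_kcal`, `se_kd_uM`, `se_dh0_kcal`, `t0_K`, `converged`,
#'   `residual_rms_K`, `n_points` and the underlying `nls` fit.
#' @examples
#' s <- data.frame(conc_uM = c(1, 3, 10, 30, 100, 300, 1000, 3000),
#'                 mean_tm_K = predict_tm(c(1, 3, 10, 30, 100, 300, 1000, 3000),
#'                                        131, 72.1, 326.2))
#' fit_dose_series(s, t0 = 326.2)
#' @export
fit_dose_series <- function(series, t0, weighted = FALSE,
                            dh0_starts = c(40, 70, 100)) {
  stopifnot(is.data.frame(series),
            all(c("conc_uM", "mean_tm_K") %in% names(series)),
            t0 > 0)
  series <- series[order(series$conc_uM), , drop = FALSE]
  if (anyDuplicated(series$conc_uM))
    stop("duplicate concentrations; average replicates first")
  if (any(series$conc_uM <= 0))
    stop("fitting requires concentrations > 0")
  if (nrow(series) < 4)
    stop("at least 4 concentration points are required for fitting")

  dtm <- series$mean_tm_K - t0
  if (max(dtm) < 0.5)
    stop("flat dose series (max delta-Tm < 0.5 K): nothing to fit")

  # kd start: concentration whose shift is nearest half-maximal
  kd0 <- series$conc_uM[which.min(abs(dtm - max(dtm) / 2))]
  w <- NULL
  if (weighted) {
    stopifnot("sem_tm_K" %in% names(series), all(series$sem_tm_K > 0))
    w <- 1 / series$sem_tm_K^2
  }

  dat <- data.frame(L = series$conc_uM, tm = series$mean_tm_K)
  best <- NULL
  for (dh_start in dh0_starts) {
    args <- list(
      tm ~ predict_tm_guarded(L, exp(lkd), exp(ldh), t0),
      data = dat,
      start = list(lkd = log(kd0), ldh = log(dh_start)),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    if (!is.null(w)) args$weights <- w
    fit <- tryCatch(do.call(minpack.lm::nlsLM, args),
                    error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || deviance(fit) < deviance(best))) best <- fit
  }

  if (is.null(best)) {
    out <- list(kd_app_uM = NA_real_, dh0_kcal = NA_real_,
                se_kd_uM = NA_real_, se_dh0_kcal = NA_real_,
                t0_K = t0, converged = FALSE, residual_rms_K = NA_real_,
                n_points = nrow(series), fit = NULL)
    class(out) <- "schellman_fit"
    return(out)
  }

  cf <- coef(best)
  kd <- exp(cf[["lkd"]]); dh <- exp(cf[["ldh"]])
  se_log <- tryCatch(sqrt(diag(vcov(best))), error = function(e) c(NA, NA))
  conv <- isTRUE(best$convInfo$isConv)
  # trial parameters may have visited the guarded clamp; the optimum must not
  feasible <- t0 * GAS_CONSTANT_KCAL * log1p(max(dat$L) / kd) / dh < 1
  out <- list(
    kd_app_uM = kd,
    dh0_kcal = dh,
    se_kd_uM = kd * se_log[[1]],
    se_dh0_kcal = dh * se_log[[2]],
    t0_K = t0,
    converged = conv && feasible,
    residual_rms_K = sqrt(mean(residuals(best)^2)),
    n_points = nrow(series),
    fit = best
  )
  class(out) <- "schellman_fit"
  out
}

#' @export
print.schellman_fit <- function(x, ...) {
  cat("Schellman dose-series fit (t0 fixed at", format(x$t0_K), "K)\n")
  cat(sprintf("  Kd-app : %.4g +/- %.3g uM\n", x$kd_app_uM, x$se_kd_uM))
  cat(sprintf("  dH0    : %.4g +/- %.3g kcal/mol\n", x$dh0_kcal, x$se_dh0_kcal))
  cat(sprintf("  rms residual %.3g K over %d points; converged: %s\n",
              x$residual_rms_K, x$n_points, x$converged))
  invisible(x)
}

#' Single-point apparent Kd from one thermal shift
#'
#' Inverts the Schellman relation at a single ligand concentration,
#' substituting fixed values for the no-ligand melting temperature and the
#' unfolding enthalpy:
#' \deqn{K_{d\mathrm{-app}} = \frac{[L]}
#'       {\exp\!\big(\Delta T_m\,\Delta H^0 / (R\,T_m T_0)\big) - 1},
#'       \qquad T_m = T_0 + \Delta T_m.}
#'
#' Each estimate is classified by the empirical delta-Tm validity window:
#' shifts of 6--11 K give the most reliable single-point estimates
#' (`preferred`), 2--11 K is `acceptable`, shifts under 1 K are below the
#' reporting floor, negative shifts indicate destabilization (no Kd is
#' assigned), and anything else is `out_of_range`.
#'
#' @param delta_tm observed thermal shift(s) Tm - T0, K.
#' @param L ligand concentration(s), uM.
#' @param t0 assumed no-ligand melting temperature, K.
#' @param dh0 assumed unfolding enthalpy at `t0`, kcal mol^-1.
#' @param ligand_id optional ligand label(s) carried through.
#' @param config `dsf_config` supplying the window thresholds.
#' @return data.frame with columns `ligand_id`, `conc_uM`, `delta_tm_K`,
#'   `kd_app_uM`, `window`, `usable`.
#' @examples
#' estimate_kd_single_point(8.7, 300)  # ~17.6 uM, preferred window
#' @export
estimate_kd_single_point <- function(delta_tm, L,
                                     t0 = 326.1, dh0 = 72.1,
                                     ligand_id = NA_character_,
                                     config = dsf_config()) {
  stopifnot(all(L > 0), t0 > 0, dh0 > 0)
  n <- max(length(delta_tm), length(L))
  delta_tm <- rep_len(delta_tm, n)
  L <- rep_len(L, n)
  ligand_id <- rep_len(ligand_id, n)

  kd <- rep(NA_real_, n)
  pos <- which(delta_tm > 0)
  if (length(pos)) {
    tm <- t0 + delta_tm[pos]
    kd[pos] <- L[pos] /
      expm1(delta_tm[pos] * dh0 / (GAS_CONSTANT_KCAL * tm * t0))
  }

  window <- vapply(delta_tm, classify_window, character(1), config = config)
  usable <- window %in% c("preferred", "acceptable")
  data.frame(ligand_id = ligand_id, conc_uM = L, delta_tm_K = delta_tm,
             kd_app_uM = kd, window = window, usable = usable,
             stringsAsFactors = FALSE)
}

classify_window <- function(dtm, config) {
  if (is.na(dtm)) return(NA_character_)
  if (dtm < 0) return("destabilized")
  if (dtm < config$window_floor_K) return("below_floor")
  if (dtm >= config$window_pref_low_K && dtm <= config$window_high_K)
    return("preferred")
  if (dtm >= config$window_low_K && dtm <= config$window_high_K)
    return("acceptable")
  "out_of_range"
}

#' Select the reporting single-point estimate for a ligand
#'
#' Applies the concentration-adoption rule used for screening panels: among
#' a ligand's single-point estimates at several concentrations, adopt the
#' lowest concentration whose shift sits in the preferred (6--11 K) window;
#' failing that, the highest concentration in the acceptable (2--11 K)
#' window; otherwise mark the ligand unusable (destabilized, or all shifts
#' below the floor / out of range).
#'
#' @param estimates data.frame as returned by [estimate_kd_single_point()],
#'   all rows for one ligand.
#' @return One-row data.frame: the chosen estimate plus `selection_reason`.
#'   When no estimate qualifies, `kd_app_uM` is `NA` and `usable` is FALSE.
#' @export
select_reporting_estimate <- function(estimates) {
  stopifnot(is.data.frame(estimates), nrow(estimates) >= 1)
  ids <- unique(estimates$ligand_id)
  if (length(ids) > 1)
    stop("mixed ligand_ids in one selection group: ",
         paste(ids, collapse = ", "))

  pref <- estimates[estimates$window == "preferred", , drop = FALSE]
  if (nrow(pref)) {
    row <- pref[which.min(pref$conc_uM), , drop = FALSE]
    row$selection_reason <- sprintf(
      "lowest concentration in preferred 6-11 K window (%g uM)", row$conc_uM)
    return(row)
  }
  acc <- estimates[estimates$window == "acceptable", , drop = FALSE]
  if (nrow(acc)) {
    row <- acc[which.max(acc$conc_uM), , drop = FALSE]
    row$selection_reason <- sprintf(
      "highest concentration in acceptable 2-11 K window (%g uM)", row$conc_uM)
    return(row)
  }
  row <- estimates[which.max(estimates$conc_uM), , drop = FALSE]
  row$kd_app_uM <- NA_real_
  row$usable <- FALSE
  row$selection_reason <- if (all(estimates$delta_tm_K < 0, na.rm = TRUE)) {
    "unusable: destabilized at every concentration"
  } else {
    "unusable: no shift within the 2-11 K window"
  }
  row
}
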