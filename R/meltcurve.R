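#' Smoothed first derivative of a melt curve
#'
#' Savitzky–Golay local-quadratic smoothing differentiation
#' (dFluorescence/dT) on the curve's own grid.  A linear fluorescence ramp
#' differentiates to its exact constant slope.
#'
#' @param curve a `melt_curve` (see [simulate_melt_curve()] /
#'   [read_melt_table()]).
#' @param smooth_window_C smoothing window width, degrees C; must span at
#'   least 3 grid steps and be smaller than the curve.
#' @return data.frame with columns `temperature_C`, `dfdt` (AU/degC).
#' @export
differentiate <- function(curve, smooth_window_C = 1.0) {
  stopifnot(inherits(curve, "melt_curve"))
  temp <- curve$temperature_C
  n <- length(temp)
  if (n < 50) stop("melt curve must have at least 50 points")
  step <- median(diff(temp))
  npts <- max(3L, as.integer(round(smooth_window_C / step)))
  if (npts %% 2L == 0L) npts <- npts + 1L
  if (npts >= n) stop("smoothing window larger than the curve span")
  dfdt <- signal::sgolayfilt(curve$fluorescence, p = 2, n = npts,
                             m = 1, ts = step)
  data.frame(temperature_C = temp, dfdt = dfdt)
}

# Indices of strict local maxima of x (plateau-tolerant on the right).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# Topographic prominence of each peak: height above the higher of the two
# bases, where a base is the minimum between the peak and the nearest
# higher point on that side (or the boundary if none is higher).
peak_prominences <- function(x, idx) {
  n <- length(x)
  vapply(idx, function(i) {
    h <- x[i]
    lmin <- h; j <- i
    while (j > 1L && x[j - 1L] <= h) { j <- j - 1L; lmin <- min(lmin, x[j]) }
    rmin <- h; k <- i
    while (k < n && x[k + 1L] <= h) { k <- k + 1L; rmin <- min(rmin, x[k]) }
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Call apparent melting temperatures from one melt curve
#'
#' Applies the derivative-maximum Tm definition: local maxima of the
#' smoothed dFluorescence/dT are candidate transitions.  Peaks are retained
#' if their topographic prominence is (a) at least `prominence_frac` of the
#' most prominent peak's, and (b) at least `snr_min` times the noise floor
#' of the derivative trace (estimated from first differences, so smooth
#' curve structure does not inflate it; pure-noise traces therefore yield
#' no transition).  Peaks closer together than `min_separation_C` are
#' merged, keeping the more prominent.  When two or more peaks survive the
#' profile is biphasic and the rightmost (second) Tm is adopted —
#' binding-induced stabilisation acts on the right-side transition.
#'
#' @param curve a `melt_curve`.
#' @param config a [dsf_config()] providing smoothing window, prominence
#'   fraction, separation and noise floor.
#' @param t0_ref optional no-ligand reference Tm in degrees C; when given,
#'   `delta_tm_K = adopted_tm_C - t0_ref`.
#' @return list of class `tm_call`: `well_id`, `ligand_id`, `conc_uM`,
#'   `peaks` (data.frame `tm_C`, `prominence`, `frac`), `biphasic`,
#'   `adopted_tm_C`, `delta_tm_K`, `no_transition`, `usable` (FALSE when
#'   the global derivative maximum sits on a grid boundary).
#' @examples
#' mc <- simulate_melt_curve(list(transition_spec(53)), noise_sd = 0)
#' call_tm(mc)$adopted_tm_C
#' @export
call_tm <- function(curve, config = dsf_config(), t0_ref = NULL) {
  stopifnot(inherits(curve, "melt_curve"))
  d <- differentiate(curve, config$smooth_window_C)
  dfdt <- d$dfdt
  temp <- d$temperature_C

  # noise floor from first differences: smooth structure (transitions,
  # baseline, quench tail) cancels, leaving the stochastic component.
  # The SG quadratic-derivative filter has coefficients proportional to the
  # centred index, so adjacent outputs correlate with
  # rho = sum i(i+1) / sum i^2 over i = -h..h; undo that when scaling the
  # difference MAD back to the per-sample noise sd.
  step <- median(diff(temp))
  npts <- max(3L, as.integer(round(config$smooth_window_C / step)))
  if (npts %% 2L == 0L) npts <- npts + 1L
  h <- (npts - 1L) %/% 2L
  i <- seq(-h, h)
  rho <- sum(i[-length(i)] * (i[-length(i)] + 1)) / sum(i^2)
  noise <- mad(diff(dfdt)) / sqrt(2 * (1 - rho))
  boundary <- which.max(dfdt) %in% c(1L, length(dfdt))

  idx <- local_maxima(dfdt)
  prom <- peak_prominences(dfdt, idx)

  if (length(idx)) {
    pmax_ <- max(prom)
    keep <- prom >= config$prominence_frac * pmax_ &
      prom >= config$snr_min * noise
    idx <- idx[keep]; prom <- prom[keep]
  }

  # merge peaks closer than min_separation_C, keeping the more prominent
  if (length(idx) > 1) {
    ord <- order(prom, decreasing = TRUE)
    chosen <- integer(0)
    for (k in ord) {
      if (all(abs(temp[idx[k]] - temp[idx[chosen]]) >= config$min_separation_C))
        chosen <- c(chosen, k)
    }
    chosen <- sort(chosen)
    idx <- idx[chosen]; prom <- prom[chosen]
  }

  no_transition <- length(idx) == 0
  peaks <- data.frame(
    tm_C = temp[idx], prominence = prom,
    frac = if (length(idx)) prom / max(prom) else numeric(0))
  adopted <- if (no_transition) NA_real_ else max(peaks$tm_C)
  delta <- if (!is.null(t0_ref) && !is.na(adopted)) adopted - t0_ref
           else NA_real_

  structure(list(
    well_id = curve$well_id, ligand_id = curve$ligand_id,
    conc_uM = curve$conc_uM, peaks = peaks,
    biphasic = length(idx) >= 2,
    adopted_tm_C = adopted, delta_tm_K = delta,
    no_transition = no_transition,
    usable = !boundary && !no_transition
  ), class = "tm_call")
}

#' @export
print.tm_call <- function(x, ...) {
  if (x$no_transition) {
    cat(sprintf("tm_call [%s] %s: no transition detected\n",
                x$well_id, x$ligand_id))
  } else {
    cat(sprintf("tm_call [%s] %s @ %g uM: %d peak(s)%s, adopted Tm %.2f degC%s\n",
                x$well_id, x$ligand_id, x$conc_uM, nrow(x$peaks),
                if (x$biphasic) " (biphasic)" else "",
                x$adopted_tm_C,
                if (!is.na(x$delta_tm_K))
                  sprintf(", dTm %+.2f K", x$delta_tm_K) else ""))
  }
  invisible(x)
}

#' Call Tm across a plate of melt curves
#'
#' Runs [call_tm()] on every curve and tidies the calls into one table.
#' When `t0_ref` is `NULL` and the plate contains buffer wells
#' (concentration 0), the no-ligand reference is the mean adopted Tm of the
#' buffer wells and delta-Tm is filled in against it.
#'
#' @param curves list of `melt_curve`.
#' @param config a [dsf_config()].
#' @param t0_ref optional reference Tm, degrees C.
#' @return data.frame with one row per well: `well_id`, `ligand_id`,
#'   `conc_uM`, `tm_C` (adopted), `biphasic`, `n_peaks`, `delta_tm_K`,
#'   `usable`; attribute `t0_ref_C` records the reference used (NA if none).
#' @export
call_plate_tms <- function(curves, config = dsf_config(), t0_ref = NULL) {
  stopifnot(length(curves) > 0)
  calls <- lapply(curves, call_tm, config = config)
  df <- data.frame(
    well_id = vapply(calls, `[[`, character(1), "well_id"),
    ligand_id = vapply(calls, `[[`, character(1), "ligand_id"),
    conc_uM = vapply(calls, `[[`, numeric(1), "conc_uM"),
    tm_C = vapply(calls, `[[`, numeric(1), "adopted_tm_C"),
    biphasic = vapply(calls, `[[`, logical(1), "biphasic"),
    n_peaks = vapply(calls, function(x) nrow(x$peaks), integer(1)),
    usable = vapply(calls, `[[`, logical(1), "usable"),
    stringsAsFactors = FALSE
  )
  if (is.null(t0_ref)) {
    buf <- df$conc_uM == 0 & !is.na(df$tm_C)
    if (any(buf)) t0_ref <- mean(df$tm_C[buf])
  }
  df$delta_tm_K <- if (is.null(t0_ref)) NA_real_ else df$tm_C - t0_ref
  attr(df, "t0_ref_C") <- if (is.null(t0_ref)) NA_real_ else t0_ref
  df
}

#' Average technical replicates of adopted Tm values
#'
#' Groups Tm calls by (ligand, concentration) and reports the replicate
#' mean in kelvin with its standard error (sd/sqrt(n); absent when n = 1).
#' Kelvin is the working unit downstream of this point.
#'
#' @param calls data.frame with columns `ligand_id`, `conc_uM` and `tm_C`
#'   (e.g. from [call_plate_tms()]); rows with `NA` Tm are dropped.
#' @return data.frame: `ligand_id`, `conc_uM`, `mean_tm_K`, `sem_tm_K`, `n`.
#' @export
summarize_replicates <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("ligand_id", "conc_uM", "tm_C") %in% names(calls)))
  calls <- calls[!is.na(calls$tm_C), , drop = FALSE]
  if (!nrow(calls)) stop("no usable Tm calls to summarize")
  key <- interaction(calls$ligand_id, calls$conc_uM, drop = TRUE)
  groups <- split(calls, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    n <- nrow(g)
    tm_K <- celsius_to_kelvin(g$tm_C)
    data.frame(ligand_id = g$ligand_id[1], conc_uM = g$conc_uM[1],
               mean_tm_K = mean(tm_K),
               sem_tm_K = if (n > 1) sd(tm_K) / sqrt(n) else NA_real_,
               n = n, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$ligand_id, out$conc_uM), , drop = FALSE]
  rownames(out) <- NULL
  out
}
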