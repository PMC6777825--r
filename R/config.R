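#' Gas constant in kcal mol^-1 K^-1
#'
#' The value used throughout the Schellman-model arithmetic.
#' @export
GAS_CONSTANT_KCAL <- 1.9872e-3

#' Pipeline configuration
#'
#' Central container for every tunable parameter of the analysis.  The
#' defaults reproduce the constants used for the medaka T1r2a/T1r3LBD
#' amino-acid screen: a fixed single-point reference `t0_fixed_K` = 326.1 K,
#' a mean unfolding enthalpy `dh0_default` = 72.1 kcal mol^-1, a receptor
#' response maximum `drfu_max` = 104.3 RFU, and the empirical delta-Tm
#' validity windows (reporting floor 1 K, acceptable 2-11 K, preferred
#' 6-11 K).
#'
#' @param smooth_window_C Savitzky-Golay smoothing window for the melt-curve
#'   derivative, in degrees C.
#' @param prominence_frac retain derivative peaks at least this fraction of
#'   the tallest peak (height measured above the trace median).
#' @param min_separation_C merge derivative peaks closer than this, keeping
#'   the taller one.
#' @param snr_min absolute peak floor, in multiples of the MAD of the
#'   derivative trace; peaks below it are treated as noise.
#' @param window_floor_K,window_low_K,window_pref_low_K,window_high_K
#'   delta-Tm thresholds (K): below `window_floor_K` a shift is below the
#'   reporting floor; `window_low_K`--`window_high_K` is acceptable for
#'   single-point Kd estimation; `window_pref_low_K`--`window_high_K` is
#'   preferred.
#' @param t0_source `"buffer_wells"` to estimate the no-ligand reference Tm
#'   from buffer-only wells of the same plate, or `"fixed"` to use
#'   `t0_fixed_K`.
#' @param t0_fixed_K fixed no-ligand reference Tm in kelvin.
#' @param dh0_default assumed unfolding enthalpy at T0 for single-point
#'   inversion, kcal mol^-1.
#' @param drfu_max fixed maximum receptor response (RFU) for the Hill
#'   inversion.
#' @param qsar_alpha significance level for the overall F test in QSAR.
#' @param seed integer seed recorded in reports and used by any stochastic
#'   stage.
#'
#' @return A list of class `dsf_config`.
#' @examples
#' cfg <- dsf_config()
#' cfg$dh0_default
#' @export
dsf_config <- function(smooth_window_C = 1.0,
                       prominence_frac = 0.10,
                       min_separation_C = 2.0,
                       snr_min = 10,
                       window_floor_K = 1,
                       window_low_K = 2,
                       window_pref_low_K = 6,
                       window_high_K = 11,
                       t0_source = c("buffer_wells", "fixed"),
                       t0_fixed_K = 326.1,
                       dh0_default = 72.1,
                       drfu_max = 104.3,
                       qsar_alpha = 0.05,
                       seed = 1L) {
  t0_source <- match.arg(t0_source)
  stopifnot(
    smooth_window_C > 0, prominence_frac > 0, prominence_frac < 1,
    min_separation_C > 0, snr_min >= 0,
    window_floor_K < window_low_K, window_low_K < window_pref_low_K,
    window_pref_low_K < window_high_K,
    t0_fixed_K > 0, dh0_default > 0, drfu_max > 0,
    qsar_alpha > 0, qsar_alpha < 1
  )
  structure(list(
    smooth_window_C = smooth_window_C,
    prominence_frac = prominence_frac,
    min_separation_C = min_separation_C,
    snr_min = snr_min,
    window_floor_K = window_floor_K,
    window_low_K = window_low_K,
    window_pref_low_K = window_pref_low_K,
    window_high_K = window_high_K,
    t0_source = t0_source,
    t0_fixed_K = t0_fixed_K,
    dh0_default = dh0_default,
    drfu_max = drfu_max,
    qsar_alpha = qsar_alpha,
    seed = as.integer(seed)
  ), class = "dsf_config")
}

#' @export
print.dsf_config <- function(x, ...) {
  cat("DSF pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.  All simulator randomness flows through
# this; no function touches the global stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

celsius_to_kelvin <- function(x) x + 273.15
kelvin_to_celsius <- function(x) x - 273.15
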