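#' Specify one unfolding transition of a simulated melt curve
#'
#' @param tm_true true transition midpoint, degrees C (25-99).
#' @param dh_vh van 't Hoff enthalpy of the simulated transition,
#'   kcal mol^-1; controls sharpness (larger = sharper).  Distinct from the
#'   Schellman-model unfolding enthalpy used for Kd inference.
#' @param amplitude fluorescence gain of the transition, AU.
#' @return list of class `transition_spec`.
#' @export
transition_spec <- function(tm_true, dh_vh = 150, amplitude = 1) {
  stopifnot(tm_true >= 25, tm_true <= 99, dh_vh > 0, amplitude > 0)
  structure(list(tm_true = tm_true, dh_vh = dh_vh, amplitude = amplitude),
            class = "transition_spec")
}

#' Specify a ligand's ground-truth behaviour for the simulator
#'
#' Three modes mirror what a DSF amino-acid screen encounters: `agonist`
#' ligands stabilise the binding-competent transition with a true Kd
#' following the Schellman relation; `destabilizer` ligands lower Tm
#' (modelled phenomenologically as a linear delta-Tm vs log10 concentration
#' decrease, since no thermodynamic model is assumed for destabilization);
#' `inert` ligands leave the curve unchanged.
#'
#' @param ligand_id ligand name.
#' @param mode `"agonist"`, `"destabilizer"` or `"inert"`.
#' @param kd_true true dissociation constant, uM (agonists).
#' @param dh0_true true Schellman unfolding enthalpy, kcal mol^-1 (agonists).
#' @param slope_K_per_decade delta-Tm slope for destabilizers, K per decade
#'   of concentration (negative).
#' @return list of class `ligand_spec`.
#' @export
ligand_spec <- function(ligand_id,
                        mode = c("agonist", "destabilizer", "inert"),
                        kd_true = NULL, dh0_true = 72.1,
                        slope_K_per_decade = -1) {
  mode <- match.arg(mode)
  if (mode == "agonist") {
    stopifnot(!is.null(kd_true), kd_true > 0, dh0_true > 0)
  }
  if (mode == "destabilizer") stopifnot(slope_K_per_decade < 0)
  structure(list(ligand_id = ligand_id, mode = mode, kd_true = kd_true,
                 dh0_true = dh0_true,
                 slope_K_per_decade = slope_K_per_decade),
            class = "ligand_spec")
}

#' Default temperature grid: 25 to 99 degrees C in 0.2 degree steps
#' @return numeric vector of temperatures (degrees C).
#' @export
default_grid <- function() seq(25, 99, by = 0.2)

# Two-state unfolded fraction of one transition on a Celsius grid;
# temperatures enter in kelvin.
unfolded_fraction <- function(temp_C, tm_true_C, dh_vh) {
  TK <- celsius_to_kelvin(temp_C)
  TmK <- celsius_to_kelvin(tm_true_C)
  1 / (1 + exp((dh_vh / GAS_CONSTANT_KCAL) * (1 / TK - 1 / TmK)))
}

#' Simulate one melt curve
#'
#' Fluorescence model: linear dye baseline plus one logistic (two-state
#' van 't Hoff) component per transition, optionally attenuated by an
#' exponential post-melt quench that switches on `quench_offset_C` degrees
#' above the last transition midpoint (mimicking dye release after
#' unfolding is essentially complete, so the quench does not bias any
#' transition midpoint):
#' \deqn{F(T) = \Big[b_0 + b_1 T + \sum_i A_i f_i(T)\Big]
#'       e^{-q \max(0, T - \max_i Tm_i - \delta)} + \varepsilon,}
#' with \eqn{f_i(T) = 1/(1+\exp[(\Delta H_{vH,i}/R)(1/T - 1/T_{m,i})])}
#' (kelvin inside \eqn{f_i}).  With `noise_sd = 0` and `quench_rate = 0`
#' the derivative maximum of each component sits exactly at its `tm_true`.
#'
#' @param transitions list of [transition_spec()] (at least one).
#' @param baseline_intercept,baseline_slope dye baseline, AU and AU/degC.
#' @param quench_rate post-melt quench rate, 1/degC (0 disables).
#' @param quench_offset_C onset of the quench above the last transition
#'   midpoint, degC.
#' @param noise_sd white fluorescence noise sd, AU.
#' @param grid strictly increasing temperature grid in [25, 99] degC.
#' @param seed integer seed (required when `noise_sd > 0`).
#' @param well_id,ligand_id,conc_uM annotations carried on the curve.
#' @return list of class `melt_curve` with fields `well_id`, `ligand_id`,
#'   `conc_uM`, `temperature_C`, `fluorescence`.
#' @examples
#' mc <- simulate_melt_curve(list(transition_spec(53)), noise_sd = 0)
#' @export
simulate_melt_curve <- function(transitions,
                                baseline_intercept = 1,
                                baseline_slope = 0.005,
                                quench_rate = 0,
                                quench_offset_C = 5,
                                noise_sd = 0,
                                grid = default_grid(),
                                seed = NULL,
                                well_id = "A1",
                                ligand_id = "buffer",
                                conc_uM = 0) {
  if (length(transitions) == 0) stop("at least one transition is required")
  if (inherits(transitions, "transition_spec")) transitions <- list(transitions)
  stopifnot(all(vapply(transitions, inherits, logical(1), "transition_spec")))
  if (any(diff(grid) <= 0)) stop("temperature grid must be strictly increasing")
  if (min(grid) < 25 || max(grid) > 99)
    stop("temperature grid must lie within [25, 99] degrees C")
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is required when noise_sd > 0")

  f <- baseline_intercept + baseline_slope * grid
  for (tr in transitions) {
    f <- f + tr$amplitude * unfolded_fraction(grid, tr$tm_true, tr$dh_vh)
  }
  if (quench_rate > 0) {
    tm_last <- max(vapply(transitions, `[[`, numeric(1), "tm_true"))
    f <- f * exp(-quench_rate * pmax(0, grid - tm_last - quench_offset_C))
  }
  if (noise_sd > 0) {
    f <- f + with_seed(seed, rnorm(length(grid), sd = noise_sd))
  }
  structure(list(well_id = well_id, ligand_id = ligand_id, conc_uM = conc_uM,
                 temperature_C = grid, fluorescence = f),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("melt curve [%s] %s @ %g uM: %d points, %.1f-%.1f degC\n",
              x$well_id, x$ligand_id, x$conc_uM, length(x$temperature_C),
              min(x$temperature_C), max(x$temperature_C)))
  invisible(x)
}

#' Simulate a replicate Tm dose series from the Schellman model
#'
#' Generates replicate apparent-Tm observations at each concentration:
#' `predict_tm(L, kd_true, dh0_true, t0)` plus Gaussian Tm noise.  Ground
#' truth is attached as attributes for recovery tests.
#'
#' @param ligand a [ligand_spec()] with mode `"agonist"`.
#' @param t0 no-ligand melting temperature, K.
#' @param concentrations ligand concentrations, uM (> 0).
#' @param n_reps technical replicates per concentration.
#' @param tm_noise_sd replicate Tm noise sd, K.
#' @param seed integer seed.
#' @return data.frame with columns `ligand_id`, `conc_uM`, `replicate`,
#'   `tm_K`; attributes `kd_true`, `dh0_true`, `t0`.
#' @export
simulate_dose_series <- function(ligand, t0, concentrations,
                                 n_reps = 4, tm_noise_sd = 0.3,
                                 seed = NULL) {
  stopifnot(inherits(ligand, "ligand_spec"), ligand$mode == "agonist",
            all(concentrations > 0), t0 > 0, n_reps >= 1, tm_noise_sd >= 0)
  mu <- predict_tm(concentrations, ligand$kd_true, ligand$dh0_true, t0)
  tm <- rep(mu, each = n_reps)
  if (tm_noise_sd > 0) {
    tm <- tm + with_seed(seed, rnorm(length(tm), sd = tm_noise_sd))
  }
  out <- data.frame(
    ligand_id = ligand$ligand_id,
    conc_uM = rep(concentrations, each = n_reps),
    replicate = rep(seq_len(n_reps), times = length(concentrations)),
    tm_K = tm,
    stringsAsFactors = FALSE
  )
  attr(out, "kd_true") <- ligand$kd_true
  attr(out, "dh0_true") <- ligand$dh0_true
  attr(out, "t0") <- t0
  out
}

#' Average a replicate Tm dose series
#'
#' Collapses replicate rows from [simulate_dose_series()] (or any table
#' with `conc_uM` and `tm_K`) to per-concentration means ready for
#' [fit_dose_series()].
#'
#' @param series data.frame with columns `conc_uM`, `tm_K`.
#' @return data.frame: `conc_uM`, `mean_tm_K`, `sem_tm_K` (NA when n = 1),
#'   `n`.
#' @export
average_dose_series <- function(series) {
  stopifnot(all(c("conc_uM", "tm_K") %in% names(series)))
  groups <- split(series$tm_K, series$conc_uM)
  out <- data.frame(
    conc_uM = as.numeric(names(groups)),
    mean_tm_K = vapply(groups, mean, numeric(1)),
    sem_tm_K = vapply(groups, function(x)
      if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_, numeric(1)),
    n = vapply(groups, length, integer(1))
  )
  out <- out[order(out$conc_uM), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a plate map
#'
#' @param well_id,ligand_id,conc_uM equal-length vectors; buffer-only wells
#'   carry concentration 0.
#' @return data.frame of class `plate_map`.
#' @export
plate_map <- function(well_id, ligand_id, conc_uM) {
  stopifnot(length(well_id) == length(ligand_id),
            length(well_id) == length(conc_uM),
            all(conc_uM >= 0))
  if (anyDuplicated(well_id)) stop("well_ids must be unique")
  structure(data.frame(well_id = well_id, ligand_id = ligand_id,
                       conc_uM = conc_uM, stringsAsFactors = FALSE),
            class = c("plate_map", "data.frame"))
}

#' Simulate a whole DSF plate
#'
#' Composes [simulate_melt_curve()] per well.  Buffer wells (concentration
#' 0) carry a single transition at `buffer_tm_C`.  Agonist wells carry the
#' ligand-shifted transition computed from the Schellman ground truth and,
#' when `biphasic = TRUE`, an additional fixed ligand-insensitive first
#' transition at `first_tm_C` (emulating the left-side ~50 degC peak that
#' does not shift with ligand).  Destabilizers lower the main transition by
#' `slope * log10(1 + [L]/1000)` K; inert ligands leave it unchanged.
#'
#' @param map a [plate_map()].
#' @param ligand_specs named list of [ligand_spec()], keyed by ligand_id.
#' @param buffer_tm_C no-ligand main-transition midpoint, degC.
#' @param first_tm_C midpoint of the fixed first transition, degC.
#' @param biphasic add the fixed first transition to ligand wells.
#' @param noise_sd fluorescence noise sd per well, AU.  Transition
#'   amplitudes are normalised to ~1 AU, so the default 0.001 corresponds
#'   to the relative noise of a real-time PCR optical read-out and
#'   reproduces a per-well Tm repeatability of ~0.15 K.
#' @param quench_rate post-melt quench, 1/degC.
#' @param grid temperature grid, degC.
#' @param seed integer seed; per-well streams are derived from it.
#' @return list of `melt_curve`, one per map row.
#' @export
simulate_plate <- function(map, ligand_specs,
                           buffer_tm_C = 53.0,
                           first_tm_C = 50.0,
                           biphasic = TRUE,
                           noise_sd = 0.001,
                           quench_rate = 0.01,
                           grid = default_grid(),
                           seed = 1L) {
  stopifnot(inherits(map, "plate_map"))
  needed <- unique(map$ligand_id[map$conc_uM > 0])
  missing <- setdiff(needed, names(ligand_specs))
  if (length(missing))
    stop("no ligand_spec for mapped ligand(s): ", paste(missing, collapse = ", "))

  t0_K <- celsius_to_kelvin(buffer_tm_C)
  curves <- vector("list", nrow(map))
  for (i in seq_len(nrow(map))) {
    w <- map[i, ]
    if (w$conc_uM == 0) {
      trs <- list(transition_spec(buffer_tm_C))
    } else {
      spec <- ligand_specs[[w$ligand_id]]
      main_tm_C <- switch(spec$mode,
        agonist = kelvin_to_celsius(
          predict_tm(w$conc_uM, spec$kd_true, spec$dh0_true, t0_K)),
        destabilizer = buffer_tm_C +
          spec$slope_K_per_decade * log10(1 + w$conc_uM / 1000),
        inert = buffer_tm_C)
      trs <- list(transition_spec(main_tm_C))
      if (biphasic && spec$mode == "agonist") {
        # fixed ligand-insensitive first transition, smaller amplitude
        trs <- c(list(transition_spec(first_tm_C, amplitude = 0.6)), trs)
      }
    }
    curves[[i]] <- simulate_melt_curve(
      trs, noise_sd = noise_sd, quench_rate = quench_rate, grid = grid,
      seed = if (noise_sd > 0) seed + i else NULL,
      well_id = w$well_id, ligand_id = w$ligand_id, conc_uM = w$conc_uM)
  }
  curves
}

#' Simulate a single-concentration receptor-response panel
#'
#' Generates delta-RFU responses under the fixed-maximum Hill relation
#' `dRFU = drfu_max * L / (ec50 + L)` plus Gaussian noise.  Noise can push
#' weak responses negative, exercising the downstream negative-response
#' exclusion rule.
#'
#' @param ec50s named numeric vector: true EC50 per ligand, mM.
#' @param drfu_max maximum response, AU.
#' @param concentrations concentrations at which to read responses, mM.
#' @param noise_sd response noise sd, AU.
#' @param seed integer seed.
#' @return data.frame with columns `ligand_id`, `conc_mM`, `drfu`;
#'   attribute `ec50_true` keeps the generating values.
#' @export
simulate_response_panel <- function(ec50s, drfu_max = 104.3,
                                    concentrations = c(5, 10),
                                    noise_sd = 0, seed = NULL) {
  stopifnot(drfu_max > 0, !is.null(names(ec50s)), all(ec50s > 0),
            all(concentrations > 0))
  grid <- expand.grid(ligand_id = names(ec50s), conc_mM = concentrations,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$ligand_id, grid$conc_mM), , drop = FALSE]
  mu <- drfu_max * grid$conc_mM / (ec50s[grid$ligand_id] + grid$conc_mM)
  drfu <- as.numeric(mu)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sd > 0")
    drfu <- drfu + with_seed(seed, rnorm(length(drfu), sd = noise_sd))
  }
  out <- data.frame(ligand_id = grid$ligand_id, conc_mM = grid$conc_mM,
                    drfu = drfu, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ec50_true") <- ec50s
  out
}
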