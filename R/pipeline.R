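#' Run the full thermal-shift analysis pipeline
#'
#' Composes the analysis stages in assay order: Tm calling per well, T0
#' from buffer wells (or the configured fixed value), replicate averaging,
#' single-point Kd estimation with window classification and the
#' concentration-adoption rule, Schellman dose-series fits where a ligand
#' has at least four concentrations, EC50 estimation from responses,
#' binding-vs-response correlations, and QSAR — degrading gracefully when
#' the optional response or descriptor inputs are absent.  Per-ligand
#' failures (e.g. an unfittable series) are caught and reported, never
#' fatal to the run.
#'
#' @param curves list of `melt_curve` (from [simulate_plate()] or
#'   [read_melt_table()]).
#' @param responses optional response data.frame (`ligand_id`, `conc_mM`,
#'   `drfu`).
#' @param descriptors optional descriptor table keyed by `ligand_id`.
#' @param config a [dsf_config()].
#' @return list of class `dsf_report` with elements `config_seed`, `t0`,
#'   `tm_calls`, `replicate_summary`, `single_point`, `selected`,
#'   `dose_fits`, `ec50`, `correlations`, `qsar`, `exclusion_log`;
#'   absent stages are `NULL` and listed in `sections_absent`.
#' @export
run_pipeline <- function(curves, responses = NULL, descriptors = NULL,
                         config = dsf_config()) {
  stopifnot(length(curves) > 0)
  exclusion_log <- character(0)

  tm_calls <- call_plate_tms(curves, config,
    t0_ref = if (config$t0_source == "fixed")
      kelvin_to_celsius(config$t0_fixed_K) else NULL)
  t0_C <- attr(tm_calls, "t0_ref_C")
  if (is.na(t0_C))
    stop("no T0 reference: plate has no buffer wells and t0_source is not fixed")
  t0_K <- celsius_to_kelvin(t0_C)

  summ <- summarize_replicates(tm_calls[tm_calls$usable, , drop = FALSE])
  summ$delta_tm_K <- summ$mean_tm_K - t0_K
  ligands <- setdiff(unique(summ$ligand_id),
                     summ$ligand_id[summ$conc_uM == 0])

  # single-point estimates + per-ligand adoption
  sp <- estimate_kd_single_point(
    delta_tm = summ$delta_tm_K[summ$conc_uM > 0],
    L = summ$conc_uM[summ$conc_uM > 0],
    t0 = t0_K, dh0 = config$dh0_default,
    ligand_id = summ$ligand_id[summ$conc_uM > 0],
    config = config)
  selected <- do.call(rbind, lapply(ligands, function(lg) {
    select_reporting_estimate(sp[sp$ligand_id == lg, , drop = FALSE])
  }))
  rownames(selected) <- NULL
  for (i in seq_len(nrow(selected))) {
    if (!selected$usable[i])
      exclusion_log[selected$ligand_id[i]] <- selected$selection_reason[i]
  }

  # dose-series fits where enough concentrations exist
  dose_fits <- list()
  for (lg in ligands) {
    ser <- summ[summ$ligand_id == lg & summ$conc_uM > 0, , drop = FALSE]
    if (nrow(ser) < 4) next
    dose_fits[[lg]] <- tryCatch(
      fit_dose_series(ser, t0 = t0_K),
      error = function(e) {
        exclusion_log[lg] <<- paste("dose fit failed:", conditionMessage(e))
        NULL
      })
  }
  dose_fits <- Filter(Negate(is.null), dose_fits)

  ec50 <- NULL
  correlations <- NULL
  if (!is.null(responses)) {
    ec50 <- estimate_ec50(responses, drfu_max = config$drfu_max)
    correlations <- list()
    for (cc in unique(ec50$conc_mM)) {
      has_dtm <- any(summ$conc_uM == cc * 1000)
      correlations[[sprintf("dTm_vs_dRFU_%gmM", cc)]] <- if (has_dtm)
        tryCatch(correlate_binding_response(summ, responses,
                                            mode = "dTm_vs_dRFU",
                                            conc_mM = cc),
                 error = function(e) conditionMessage(e)) else NULL
    }
    correlations$pKd_vs_pEC50 <- tryCatch(
      correlate_binding_response(selected,
                                 ec50[ec50$conc_mM == max(ec50$conc_mM), ],
                                 mode = "pKd_vs_pEC50"),
      error = function(e) conditionMessage(e))
  }

  qsar <- NULL
  if (!is.null(descriptors)) {
    usable <- selected[selected$usable & !is.na(selected$kd_app_uM), ]
    if (nrow(usable) >= 6) {
      pkd <- data.frame(ligand_id = usable$ligand_id,
                        pkd = to_p_scale(usable$kd_app_uM, "uM"))
      qsar <- tryCatch(
        qsar_search(pkd, descriptors, alpha = config$qsar_alpha),
        error = function(e) conditionMessage(e))
    } else {
      exclusion_log["qsar"] <-
        sprintf("skipped: only %d usable ligands (need >= 6)", nrow(usable))
    }
  }

  absent <- c(if (is.null(responses)) c("ec50", "correlations"),
              if (is.null(qsar)) "qsar")
  structure(list(
    config_seed = config$seed,
    t0 = list(source = config$t0_source, t0_K = t0_K, t0_C = t0_C),
    tm_calls = tm_calls,
    replicate_summary = summ,
    single_point = sp,
    selected = selected,
    dose_fits = dose_fits,
    ec50 = ec50,
    correlations = correlations,
    qsar = qsar,
    exclusion_log = exclusion_log,
    sections_absent = absent
  ), class = "dsf_report")
}

#' @export
print.dsf_report <- function(x, ...) {
  cat("DSF pipeline report\n")
  cat(sprintf("  T0: %.2f K (%.2f degC, %s)\n",
              x$t0$t0_K, x$t0$t0_C, x$t0$source))
  cat(sprintf("  wells called: %d (%d usable)\n",
              nrow(x$tm_calls), sum(x$tm_calls$usable)))
  cat(sprintf("  ligands with selected single-point Kd: %d of %d\n",
              sum(x$selected$usable), nrow(x$selected)))
  cat(sprintf("  dose-series fits: %d\n", length(x$dose_fits)))
  if (!is.null(x$correlations)) {
    for (nm in names(x$correlations)) {
      cr <- x$correlations[[nm]]
      if (inherits(cr, "correlation_result"))
        cat(sprintf("  %s: n = %d, r = %.3f\n", nm, cr$n, cr$r))
    }
  }
  if (length(x$sections_absent))
    cat("  absent sections:", paste(x$sections_absent, collapse = ", "), "\n")
  if (length(x$exclusion_log)) {
    cat("  exclusions:\n")
    for (lg in names(x$exclusion_log))
      cat(sprintf("    %s: %s\n", lg, x$exclusion_log[[lg]]))
  }
  invisible(x)
}

#' Serialize a pipeline report to JSON (+ per-stage TSV tables)
#'
#' @param report a `dsf_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the JSON path.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "dsf_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  tsv <- function(df, name) {
    if (!is.null(df) && is.data.frame(df))
      write.table(df, file.path(dir, paste0(name, ".tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
  }
  tsv(report$tm_calls, "tm_calls")
  tsv(report$replicate_summary, "replicate_summary")
  tsv(report$single_point, "single_point")
  tsv(report$selected, "selected_estimates")
  tsv(report$ec50, "ec50")
  if (is.data.frame(report$qsar)) tsv(report$qsar, "qsar")

  js <- list(
    seed = report$config_seed,
    t0 = report$t0,
    n_wells = nrow(report$tm_calls),
    n_wells_usable = sum(report$tm_calls$usable),
    dose_fits = lapply(report$dose_fits, function(f)
      f[c("kd_app_uM", "dh0_kcal", "se_kd_uM", "se_dh0_kcal", "t0_K",
          "converged", "residual_rms_K", "n_points")]),
    selected = report$selected,
    correlations = lapply(report$correlations, function(cr)
      if (inherits(cr, "correlation_result"))
        list(mode = cr$mode, n = cr$n, r = cr$r,
             exclusions = as.list(cr$exclusions)) else cr),
    exclusion_log = as.list(report$exclusion_log),
    sections_absent = report$sections_absent
  )
  path <- file.path(dir, "report.json")
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
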