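#' Single-point EC50 from a receptor response
#'
#' Inverts the fixed-maximum Hill relation (Hill coefficient 1)
#' `dRFU = drfu_max * L / (ec50 + L)` at one concentration:
#' `ec50 = L * (drfu_max - dRFU) / dRFU`.  Non-positive responses are
#' excluded (`negative_excluded`) and responses at or above the fixed
#' maximum cannot yield a finite estimate (`saturated`); both are states,
#' not errors, and are dropped from downstream correlations.
#'
#' @param responses data.frame with columns `ligand_id`, `conc_mM`, `drfu`.
#' @param drfu_max fixed maximum response, AU.
#' @return data.frame: `ligand_id`, `conc_mM`, `drfu`, `status`
#'   (`ok` / `negative_excluded` / `saturated`), `ec50_mM`, `pec50`
#'   (molar basis, `-log10(ec50 in M)`).
#' @examples
#' estimate_ec50(data.frame(ligand_id = "Gln", conc_mM = 5,
#'                          drfu = 104.3 / 2))$ec50_mM  # 5
#' @export
estimate_ec50 <- function(responses, drfu_max = 104.3) {
  stopifnot(is.data.frame(responses),
            all(c("ligand_id", "conc_mM", "drfu") %in% names(responses)),
            all(responses$conc_mM > 0), drfu_max > 0)
  drfu <- responses$drfu
  L <- responses$conc_mM
  status <- ifelse(drfu <= 0, "negative_excluded",
                   ifelse(drfu >= drfu_max, "saturated", "ok"))
  ec50 <- ifelse(status == "ok", L * (drfu_max - drfu) / drfu, NA_real_)
  out <- responses[, c("ligand_id", "conc_mM", "drfu")]
  out$status <- status
  out$ec50_mM <- ec50
  out$pec50 <- ifelse(is.na(ec50), NA_real_, to_p_scale(ec50, "mM"))
  rownames(out) <- NULL
  out
}

#' Convert a concentration-valued constant to the p-scale
#'
#' `-log10` of the value expressed in mol/L (molar basis), as in
#' pKd = -log10(Kd in M) and pEC50 = -log10(EC50 in M).
#'
#' @param value positive concentration value(s).
#' @param unit `"uM"` or `"mM"`.
#' @return dimensionless p-scale value(s).
#' @examples
#' to_p_scale(1, "uM")    # 6
#' to_p_scale(10, "mM")   # 2
#' @export
to_p_scale <- function(value, unit = c("uM", "mM")) {
  unit <- match.arg(unit)
  if (any(value <= 0, na.rm = TRUE)) stop("p-scale requires positive values")
  molar <- value * switch(unit, uM = 1e-6, mM = 1e-3)
  -log10(molar)
}
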