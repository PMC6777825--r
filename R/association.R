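#' Pearson product-moment correlation with validity checks
#'
#' @param x,y equal-length numeric vectors (>= 3 finite pairs, non-zero
#'   variance in both).
#' @return the correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("at least 3 pairs are required")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in correlation input")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in correlation input")
  cor(x, y, method = "pearson")
}

#' Correlate LBD binding with full-length receptor response
#'
#' Two comparison modes, matching how a thermal-shift screen is validated
#' against a cell-based response assay:
#'
#' * `dTm_vs_dRFU` — raw thermal shift at one concentration against the raw
#'   receptor response at the same concentration (destabilized ligands keep
#'   their negative shifts; only ligands missing a value are excluded).
#' * `pKd_vs_pEC50` — p-scaled selected single-point binding affinities
#'   (usable estimates only) against p-scaled single-point response
#'   potencies (status `ok` only).
#'
#' Tables are inner-joined on `ligand_id`; every exclusion is recorded with
#' its reason.
#'
#' @param binding for `dTm_vs_dRFU`: data.frame with `ligand_id`, `conc_uM`,
#'   `delta_tm_K` (e.g. [call_plate_tms()] output or a replicate summary
#'   with a `delta_tm_K` column); for `pKd_vs_pEC50`: selected single-point
#'   estimates from [select_reporting_estimate()] (columns `ligand_id`,
#'   `kd_app_uM`, `usable`).
#' @param responses for `dTm_vs_dRFU`: data.frame with `ligand_id`,
#'   `conc_mM`, `drfu`; for `pKd_vs_pEC50`: [estimate_ec50()] output.
#' @param mode comparison mode.
#' @param conc_mM concentration at which raw values are paired
#'   (`dTm_vs_dRFU` mode).
#' @return list of class `correlation_result`: `mode`, `n`, `r`, `pairs`
#'   (data.frame `ligand_id`, `x`, `y`), `exclusions` (named character).
#' @export
correlate_binding_response <- function(binding, responses,
                                       mode = c("dTm_vs_dRFU",
                                                "pKd_vs_pEC50"),
                                       conc_mM = 10) {
  mode <- match.arg(mode)
  exclusions <- character(0)

  if (mode == "dTm_vs_dRFU") {
    stopifnot(all(c("ligand_id", "conc_uM", "delta_tm_K") %in% names(binding)),
              all(c("ligand_id", "conc_mM", "drfu") %in% names(responses)))
    b <- binding[binding$conc_uM == conc_mM * 1000 & !is.na(binding$delta_tm_K),
                 c("ligand_id", "delta_tm_K")]
    r <- responses[responses$conc_mM == conc_mM, c("ligand_id", "drfu")]
    names(b)[2] <- "x"; names(r)[2] <- "y"
  } else {
    stopifnot(all(c("ligand_id", "kd_app_uM", "usable") %in% names(binding)),
              all(c("ligand_id", "status", "pec50") %in% names(responses)))
    drop_b <- binding$ligand_id[!binding$usable | is.na(binding$kd_app_uM)]
    for (lg in drop_b) exclusions[lg] <- "binding estimate not usable"
    b <- binding[binding$usable & !is.na(binding$kd_app_uM),
                 c("ligand_id", "kd_app_uM")]
    b$x <- to_p_scale(b$kd_app_uM, "uM"); b <- b[, c("ligand_id", "x")]
    drop_r <- responses$ligand_id[responses$status != "ok"]
    for (lg in setdiff(drop_r, names(exclusions)))
      exclusions[lg] <- paste0("response ", responses$status[
        match(lg, responses$ligand_id)])
    r <- responses[responses$status == "ok", c("ligand_id", "pec50")]
    names(r)[2] <- "y"
  }

  if (anyDuplicated(b$ligand_id) || anyDuplicated(r$ligand_id))
    stop("multiple rows per ligand at the requested concentration")

  only_b <- setdiff(b$ligand_id, r$ligand_id)
  only_r <- setdiff(r$ligand_id, b$ligand_id)
  for (lg in only_b) exclusions[lg] <- "no response value"
  for (lg in only_r) exclusions[lg] <- "no binding value"

  pairs <- merge(b, r, by = "ligand_id")
  if (!nrow(pairs)) stop("no ligands shared between binding and response tables")
  pairs <- pairs[order(pairs$ligand_id), , drop = FALSE]
  rownames(pairs) <- NULL

  structure(list(mode = mode, n = nrow(pairs),
                 r = pearson_r(pairs$x, pairs$y),
                 pairs = pairs, exclusions = exclusions),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation [%s]: n = %d, r = %.3f\n", x$mode, x$n, x$r))
  if (length(x$exclusions)) {
    cat("excluded:\n")
    for (lg in names(x$exclusions))
      cat(sprintf("  %s: %s\n", lg, x$exclusions[[lg]]))
  }
  invisible(x)
}

#' Classical QSAR subset regression of binding affinity on descriptors
#'
#' Ordinary least squares of p-scaled affinity on every descriptor subset
#' of size 1 and 2 (classical QSAR practice for small panels; no stepwise
#' selection).  Each fit reports the multiple correlation coefficient r,
#' the standard error of estimate s, the overall F statistic with its
#' p-value, and a significance flag at `alpha`.  Near-collinear subsets
#' (design-matrix condition number above `kappa_max`) are skipped and
#' listed in the `skipped` attribute.  The number of models tried is
#' reported; no multiplicity correction is applied (a documented caveat of
#' the classical workflow).
#'
#' @param pkd data.frame with columns `ligand_id` and `pkd`.
#' @param descriptors data.frame keyed by `ligand_id` with numeric
#'   descriptor columns (e.g. [builtin_descriptor_table()]).
#' @param max_terms maximum subset size (1 or 2).
#' @param alpha significance level for the overall F test.
#' @param kappa_max condition-number threshold for skipping a subset.
#' @return data.frame ranked by decreasing r: `terms`, `n`, `r`, `s`, `F`,
#'   `p_value`, `significant`, plus intercept/coefficients in `coef_*`
#'   columns; attributes `n_models_tried` and `skipped`.
#' @export
qsar_search <- function(pkd, descriptors, max_terms = 2, alpha = 0.05,
                        kappa_max = 1e8) {
  stopifnot(all(c("ligand_id", "pkd") %in% names(pkd)),
            "ligand_id" %in% names(descriptors),
            max_terms %in% 1:2)
  dat <- merge(pkd[, c("ligand_id", "pkd")], descriptors, by = "ligand_id")
  desc_cols <- setdiff(names(descriptors), c("ligand_id", "name"))
  if (nrow(dat) < 6) stop("QSAR requires at least 6 ligands")
  if (anyNA(dat[, desc_cols]))
    stop("descriptor table has missing cells for analyzed ligands")

  subsets <- lapply(seq_len(max_terms), function(k)
    combn(desc_cols, k, simplify = FALSE))
  subsets <- unlist(subsets, recursive = FALSE)

  skipped <- character(0)
  rows <- list()
  for (terms in subsets) {
    if (nrow(dat) < length(terms) + 2) { # need residual df for F
      skipped <- c(skipped, paste(terms, collapse = "+"))
      next
    }
    X <- cbind(1, as.matrix(dat[, terms, drop = FALSE]))
    if (kappa(X, exact = TRUE) > kappa_max ||
        qr(X)$rank < ncol(X)) {
      skipped <- c(skipped, paste(terms, collapse = "+"))
      next
    }
    fm <- lm(stats::reformulate(terms, response = "pkd"), data = dat)
    sm <- summary(fm)
    Fst <- sm$fstatistic
    p <- pf(Fst[["value"]], Fst[["numdf"]], Fst[["dendf"]],
            lower.tail = FALSE)
    cf <- coef(fm)
    rows[[length(rows) + 1L]] <- data.frame(
      terms = paste(terms, collapse = "+"),
      n = nrow(dat),
      r = sqrt(max(sm$r.squared, 0)),
      s = sm$sigma,
      F = Fst[["value"]],
      p_value = p,
      significant = p < alpha,
      intercept = cf[["(Intercept)"]],
      coef1 = cf[[2]],
      coef2 = if (length(terms) == 2) cf[[3]] else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$r), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_models_tried") <- nrow(out)
  attr(out, "skipped") <- skipped
  out
}
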