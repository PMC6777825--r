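#' Read melt curves from long-format CSV plus a plate map
#'
#' The melt table has columns `well`, `temperature_C`, `fluorescence`
#' (long format, one row per reading); the plate map has `well`, `ligand`,
#' `conc_uM` with buffer-only wells at concentration 0.  Temperatures out
#' of order are sorted with a warning; duplicate (well, temperature) rows,
#' non-numeric cells, and wells missing from the map are errors.
#'
#' @param path melt-curve CSV path.
#' @param plate_map_path plate-map CSV path.
#' @return list of `melt_curve`, one per well, in plate-map order.
#' @seealso [write_melt_table()]
#' @export
read_melt_table <- function(path, plate_map_path) {
  melt <- read.csv(path, stringsAsFactors = FALSE)
  map <- read.csv(plate_map_path, stringsAsFactors = FALSE)
  need_m <- c("well", "temperature_C", "fluorescence")
  need_p <- c("well", "ligand", "conc_uM")
  if (!all(need_m %in% names(melt)))
    stop("melt table must have columns: ", paste(need_m, collapse = ", "))
  if (!all(need_p %in% names(map)))
    stop("plate map must have columns: ", paste(need_p, collapse = ", "))
  if (!is.numeric(melt$temperature_C) || !is.numeric(melt$fluorescence))
    stop("non-numeric temperature_C or fluorescence values in melt table")
  if (!is.numeric(map$conc_uM)) stop("non-numeric conc_uM in plate map")
  melt$temperature_C <- as.numeric(melt$temperature_C)
  melt$fluorescence <- as.numeric(melt$fluorescence)
  map$conc_uM <- as.numeric(map$conc_uM)

  wells <- unique(melt$well)
  unmapped <- setdiff(wells, map$well)
  if (length(unmapped))
    stop("well(s) missing from plate map: ", paste(unmapped, collapse = ", "))

  lapply(intersect(map$well, wells), function(w) {
    sub <- melt[melt$well == w, , drop = FALSE]
    if (anyDuplicated(sub$temperature_C))
      stop("duplicate (well, temperature) rows for well ", w)
    if (is.unsorted(sub$temperature_C)) {
      warning("temperatures out of order for well ", w, "; sorting")
      sub <- sub[order(sub$temperature_C), , drop = FALSE]
    }
    m <- map[match(w, map$well), ]
    structure(list(well_id = w, ligand_id = m$ligand, conc_uM = m$conc_uM,
                   temperature_C = sub$temperature_C,
                   fluorescence = sub$fluorescence),
              class = "melt_curve")
  })
}

#' Write melt curves to long-format CSV plus a plate map
#'
#' @param curves list of `melt_curve`.
#' @param path melt-curve CSV destination.
#' @param plate_map_path plate-map CSV destination.
#' @return invisibly, the two paths.
#' @export
write_melt_table <- function(curves, path, plate_map_path) {
  long <- do.call(rbind, lapply(curves, function(cv)
    data.frame(well = cv$well_id, temperature_C = cv$temperature_C,
               fluorescence = cv$fluorescence, stringsAsFactors = FALSE)))
  map <- do.call(rbind, lapply(curves, function(cv)
    data.frame(well = cv$well_id, ligand = cv$ligand_id,
               conc_uM = cv$conc_uM, stringsAsFactors = FALSE)))
  write.csv(long, path, row.names = FALSE)
  write.csv(map, plate_map_path, row.names = FALSE)
  invisible(c(path, plate_map_path))
}

#' Read a receptor-response CSV (ligand, conc_mM, dRFU)
#' @param path CSV path with columns `ligand`, `conc_mM`, `dRFU`.
#' @return data.frame with columns `ligand_id`, `conc_mM`, `drfu`.
#' @export
read_response_table <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("ligand", "conc_mM", "dRFU")
  if (!all(need %in% names(x)))
    stop("response table must have columns: ", paste(need, collapse = ", "))
  data.frame(ligand_id = x$ligand, conc_mM = x$conc_mM, drfu = x$dRFU,
             stringsAsFactors = FALSE)
}

#' Write a receptor-response CSV
#' @param responses data.frame with `ligand_id`, `conc_mM`, `drfu`.
#' @param path destination CSV path.
#' @return invisibly, `path`.
#' @export
write_response_table <- function(responses, path) {
  write.csv(data.frame(ligand = responses$ligand_id,
                       conc_mM = responses$conc_mM,
                       dRFU = responses$drfu), path, row.names = FALSE)
  invisible(path)
}
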