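#' Packaged calibration criteria
#'
#' The default biomarker criteria used throughout calibration.  AP-duration
#' biomarkers (APD20, APD50, APD90, Tri9040) carry experimental means and
#' standard deviations and are applied in implausibility mode; RMP (no
#' experimental SD is available) and the Ca2+-transient biomarkers are applied
#' in min-max mode, using the extreme values found across experiments as
#' cutoff borders.  Force biomarkers (FTTP, FTTr, FTD) form the re-calibration
#' stage used by the mechanical tests.
#'
#' @return Tibble with columns `biomarker`, `stage` ("calibration" or
#'   "recalibration"), `mode` ("implausibility" or "minmax"), `mean`, `sd`,
#'   `min`, `max`, `units`.
#' @export
default_criteria <- function() {
  read_criteria(system.file("extdata", "calibration_criteria.csv",
                            package = "cardiopop", mustWork = TRUE))
}

#' Read / write a criteria table
#'
#' @param path CSV file with the columns of [default_criteria()].
#' @return Tibble of validated criteria.
#' @export
read_criteria <- function(path) {
  crit <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            biomarker = "c", stage = "c", mode = "c",
                            mean = "d", sd = "d", min = "d", max = "d",
                            units = "c"))
  validate_criteria(crit)
  crit
}

#' @rdname read_criteria
#' @param criteria Criteria tibble.
#' @export
write_criteria <- function(criteria, path) {
  validate_criteria(criteria)
  readr::write_csv(criteria, path)
  invisible(path)
}

validate_criteria <- function(crit) {
  need <- c("biomarker", "stage", "mode", "mean", "sd", "min", "max")
  if (!all(need %in% names(crit)))
    abort(paste("criteria table must have columns:",
                paste(need, collapse = ", ")))
  if (!all(crit$mode %in% c("implausibility", "minmax")))
    abort("criterion mode must be 'implausibility' or 'minmax'")
  imp <- crit$mode == "implausibility"
  if (any(is.na(crit$mean[imp])) || any(!is.finite(crit$sd[imp])) ||
      any(crit$sd[imp] <= 0))
    abort("implausibility-mode criteria require a mean and a positive sd")
  mm <- crit$mode == "minmax"
  if (any(is.na(crit$min[mm])) || any(is.na(crit$max[mm])) ||
      any(crit$min[mm] >= crit$max[mm]))
    abort("minmax-mode criteria require min < max")
  invisible(crit)
}
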