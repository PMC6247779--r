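#' Log-linear pixel-value / concentration calibration
#'
#' Silver-density immunosignals are approximately log-linear in small
#' molecule concentration: pixel value `PV = pv_ref + slope * log10(c /
#' c_ref)`, clamped to the 8-bit range. The default (0.1 mM at PV 96,
#' 64 PV per decade) spans roughly 0.003–30 mM across 0–255, comfortably
#' covering the 0.1–10 mM range over which GABA content separates
#' ganglion-cell and amacrine-cell populations. All constants are
#' user-configurable.
#'
#' @param pv_ref Pixel value at the reference concentration.
#' @param c_ref_mM Reference concentration in mM.
#' @param slope_pv_per_decade Pixel values per factor-10 change in
#'   concentration (must be > 0).
#' @return An object of class `calibration_model`.
#' @export
#' @examples
#' m <- calibration_model()
#' conc_to_pv(c(0.1, 1, 10), m)
calibration_model <- function(pv_ref = 96, c_ref_mM = 0.1,
                              slope_pv_per_decade = 64) {
  if (slope_pv_per_decade <= 0) {
    abort("slope must be positive", class = "retcouple_domain_error")
  }
  if (c_ref_mM <= 0) {
    abort("reference concentration must be positive",
          class = "retcouple_domain_error")
  }
  structure(list(pv_ref = pv_ref, c_ref_mM = c_ref_mM,
                 slope_pv_per_decade = slope_pv_per_decade),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> PV = %g + %g * log10(c / %g mM), clamped to [0, 255]\n",
              x$pv_ref, x$slope_pv_per_decade, x$c_ref_mM))
  invisible(x)
}

#' @rdname calibration_model
#' @param c_mM Concentration(s) in mM, > 0.
#' @param model A `calibration_model`.
#' @export
conc_to_pv <- function(c_mM, model = calibration_model()) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(c_mM <= 0, na.rm = TRUE)) {
    abort("concentration must be positive",
          class = "retcouple_domain_error")
  }
  pv <- model$pv_ref +
    model$slope_pv_per_decade * log10(c_mM / model$c_ref_mM)
  pmin(pmax(pv, 0), 255)
}

#' @rdname calibration_model
#' @param pv Pixel value(s). Exact inverse only on the unclamped part of
#'   the range.
#' @export
pv_to_conc <- function(pv, model = calibration_model()) {
  stopifnot(inherits(model, "calibration_model"))
  model$c_ref_mM * 10^((pv - model$pv_ref) / model$slope_pv_per_decade)
}
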