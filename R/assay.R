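# Fluorescent-AGE quantification normalized to collagen.

#' Fit a plate-reader standard curve by ordinary least squares
#'
#' @param standards data frame with columns `concentration`, `reading`, or a
#'   [plate_assay()] (its standards are used).
#' @param min_r2 QC threshold on the curve R^2.
#' @return list of class `standard_curve`: `slope`, `intercept`, `r2`,
#'   `range` (valid concentration range).
#' @export
fit_standard_curve <- function(standards, min_r2 = 0.95) {
  if (inherits(standards, "plate_assay")) standards <- standards$standards
  stopifnot(all(c("concentration", "reading") %in% names(standards)))
  if (nrow(standards) < 3L) stop("need at least 3 standards")
  if (diff(range(standards$concentration)) <= 0)
    stop("degenerate standard concentration range")
  fit <- linfit(standards$concentration, standards$reading)
  if (fit$r2 < min_r2)
    stop(sprintf("standard curve failed QC (R^2 = %.4f < %.2f)",
                 fit$r2, min_r2))
  if (fit$slope <= 0) stop("standard curve slope must be positive")
  structure(list(slope = fit$slope, intercept = fit$intercept, r2 = fit$r2,
                 range = range(standards$concentration)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> reading = %.4g * conc + %.4g (R2 %.4f)\n",
              x$slope, x$intercept, x$r2))
  invisible(x)
}

# back-calculate a concentration from a reading, flagging extrapolation
back_calc <- function(reading, curve, flags_env = NULL) {
  conc <- (reading - curve$intercept) / curve$slope
  if (!is.null(flags_env)) {
    if (conc < curve$range[1] || conc > curve$range[2])
      flags_env$flags <- c(flags_env$flags, "extrapolated")
    if (conc < 0) flags_env$flags <- c(flags_env$flags, "clamped_negative")
  }
  max(conc, 0)
}

#' Quantify hydroxyproline and collagen from a chloramine-T absorbance
#' reading
#'
#' Collagen is derived from hydroxyproline using the standard composition
#' assumption that collagen is 14 percent hydroxyproline by mass.
#'
#' @param reading sample absorbance at 570 nm.
#' @param curve a [fit_standard_curve()] on the hydroxyproline standards
#'   (concentrations in mg/mL).
#' @param dilution hydrolysate dilution factor before reading.
#' @param hydrolysate_mL hydrolysate volume, mL.
#' @return list: `hydroxyproline_mg`, `collagen_mg`, `flags`.
#' @export
quantify_hydroxyproline <- function(reading, curve, dilution = 10,
                                    hydrolysate_mL = 5) {
  env <- new.env(); env$flags <- character(0)
  conc <- back_calc(reading, curve, env)          # mg/mL in the well
  hyp <- conc * dilution * hydrolysate_mL         # mg in the hydrolysate
  list(hydroxyproline_mg = hyp, collagen_mg = hyp / 0.14, flags = env$flags)
}

#' Total fluorescent AGEs normalized to collagen
#'
#' Back-calculates quinine-equivalents from the sample fluorescence via the
#' quinine standard curve, scales by the hydrolysate dilution and volume,
#' and normalizes to the collagen mass: the result is reported as ng quinine
#' fluorescence per mg collagen.
#'
#' @param reading sample fluorescence (excitation 360 nm, emission 460 nm).
#' @param curve a [fit_standard_curve()] on the quinine standards
#'   (concentrations in ug/mL).
#' @param collagen_mg collagen mass, mg (> 0).
#' @param dilution hydrolysate dilution factor (the protocol dilutes the
#'   supernatant 10-fold).
#' @param hydrolysate_mL hydrolysate volume, mL (100 uL per mg bone).
#' @return list of class `fage_result`: `fage` (ng quinine / mg collagen),
#'   `quinine_eq_ng`, `collagen_mg`, `flags`.
#' @export
compute_fage <- function(reading, curve, collagen_mg, dilution = 10,
                         hydrolysate_mL = 5) {
  if (collagen_mg <= 0) stop("collagen mass must be positive")
  env <- new.env(); env$flags <- character(0)
  conc_ug_mL <- back_calc(reading, curve, env)    # quinine eq in the well
  quinine_eq_ng <- conc_ug_mL * 1000 * dilution * hydrolysate_mL
  structure(list(fage = quinine_eq_ng / collagen_mg,
                 quinine_eq_ng = quinine_eq_ng,
                 collagen_mg = collagen_mg, flags = env$flags),
            class = "fage_result")
}

#' @export
print.fage_result <- function(x, ...) {
  cat(sprintf("<fage_result> %.1f ng quinine/mg collagen (%.3g ng over %.3g mg)\n",
              x$fage, x$quinine_eq_ng, x$collagen_mg))
  invisible(x)
}

#' Run the full fAGE pipeline on a forward-modelled plate pair
#'
#' Convenience wrapper: fits both standard curves, quantifies collagen from
#' the absorbance plate and fAGE from the fluorescence plate.
#'
#' @param plates list with `fluorescence` and `absorbance` [plate_assay()]s
#'   (as returned by [forward_plate()]).
#' @return the [compute_fage()] result, with `collagen_mg` taken from the
#'   hydroxyproline assay.
#' @export
analyze_fage <- function(plates) {
  qc <- fit_standard_curve(plates$fluorescence)
  hc <- fit_standard_curve(plates$absorbance)
  fl <- plates$fluorescence$samples
  ab <- plates$absorbance$samples
  vol <- plates$fluorescence$meta$hydrolysate_mL
  hyp <- quantify_hydroxyproline(ab$reading[1], hc, dilution = ab$dilution[1],
                                 hydrolysate_mL = vol)
  compute_fage(fl$reading[1], qc, collagen_mg = hyp$collagen_mg,
               dilution = fl$dilution[1], hydrolysate_mL = vol)
}
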