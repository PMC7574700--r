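# Forward models for FTIR and XRD spectra.

#' Compose a bone-like FTIR band library from target compositional ratios
#'
#' Builds a Gaussian band table (phosphate nu1/nu3 envelope, carbonate nu2,
#' amide I sub-bands) whose integrated-band and intensity ratios equal the
#' requested values. The 1020/1030 and 1096/1127 amplitudes are obtained by
#' solving a small linear system for the summed-envelope heights at those
#' wavenumbers, so the intensity ratios hold for the full spectrum, not just
#' the isolated bands.
#'
#' @param mineral_to_matrix target area ratio, phosphate (916-1180 cm^-1) over
#'   amide I (1596-1712 cm^-1).
#' @param carbonate_to_phosphate target area ratio, carbonate nu2 (852-890)
#'   over phosphate.
#' @param crystallinity target intensity ratio 1030/1020 cm^-1.
#' @param acid_phosphate target intensity ratio 1127/1096 cm^-1.
#' @param NE_xLR target amide I sub-band area ratio A1678/A1692.
#' @param collagen_maturity target area ratio A1660/A1692.
#' @param amide_sigma Gaussian sd of the amide I sub-bands, cm^-1.
#' @return data frame with columns `center`, `sigma`, `area`.
#' @export
ftir_band_library <- function(mineral_to_matrix = 4.0,
                              carbonate_to_phosphate = 0.009,
                              crystallinity = 1.25,
                              acid_phosphate = 0.72,
                              NE_xLR = 1.55,
                              collagen_maturity = 3.0,
                              amide_sigma = 5.5) {
  # amide I sub-bands; A1692 is the reference area
  amide <- data.frame(
    center = c(1610, 1630, 1645, 1660, 1678, 1692),
    sigma  = amide_sigma,
    area   = c(0.6, 1.2, 1.4, collagen_maturity, NE_xLR, 1.0))
  amide_total <- sum(amide$area)

  # phosphate envelope: fixed flank bands + four solved amplitudes
  ph_centers <- c(960, 1020, 1030, 1075, 1096, 1127)
  ph_sigma   <- c(10,  9,    9,    14,   8,    8)
  solved <- c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE)
  amp <- c(1.3, NA, NA, 0.8, NA, NA)            # heights (not areas)
  # target summed-envelope heights at the four intensity wavenumbers
  pts <- c(1020, 1030, 1096, 1127)
  tgt <- c(1.0, crystallinity, 0.55, 0.55 * acid_phosphate)
  G <- outer(seq_along(ph_centers), pts,
             function(i, x) exp(-0.5 * ((x - ph_centers[i]) / ph_sigma[i])^2))
  fixed_contrib <- colSums(G[!solved, , drop = FALSE] * amp[!solved])
  M <- t(G[solved, , drop = FALSE])
  sol <- solve(M, tgt - fixed_contrib)
  if (any(sol <= 0))
    stop("infeasible intensity-ratio targets for the phosphate envelope")
  amp[solved] <- sol
  ph_area <- amp * ph_sigma * sqrt(2 * pi)
  # scale the phosphate group so its total area hits the mineral/matrix target
  scale_ph <- mineral_to_matrix * amide_total / sum(ph_area)
  phosphate <- data.frame(center = ph_centers, sigma = ph_sigma,
                          area = ph_area * scale_ph)
  carbonate <- data.frame(center = 871, sigma = 7,
                          area = carbonate_to_phosphate * sum(phosphate$area))
  rbind(phosphate, carbonate, amide)
}

#' Forward-model an FTIR absorbance spectrum
#'
#' Sum of Gaussian bands plus a linear baseline and optional white noise on a
#' uniform wavenumber grid.
#'
#' @param bands data frame with columns `center` (cm^-1), `sigma` (cm^-1),
#'   `area`; see [ftir_band_library()].
#' @param baseline numeric length-2: intercept and slope (per cm^-1, about
#'   400 cm^-1) of a linear baseline drift.
#' @param noise absolute sd of additive Gaussian noise (absorbance units).
#' @param wn_range spectral range, cm^-1.
#' @param step grid step, cm^-1.
#' @param truth optional truth list to attach (defaults to the band table).
#' @return A [spectrum_oq()] of kind `"ftir"`.
#' @export
forward_ftir <- function(bands, baseline = c(0, 0), noise = 0,
                         wn_range = c(400, 1800), step = 2, truth = NULL) {
  stopifnot(all(c("center", "sigma", "area") %in% names(bands)),
            all(bands$sigma > 0), all(bands$area >= 0),
            all(bands$center >= wn_range[1] & bands$center <= wn_range[2]))
  x <- seq(wn_range[1], wn_range[2], by = step)
  y <- baseline[1] + baseline[2] * (x - wn_range[1])
  for (i in seq_len(nrow(bands)))
    y <- y + gauss(x, bands$center[i], bands$sigma[i], bands$area[i])
  if (noise > 0) y <- y + rnorm(length(y), 0, noise)
  spectrum_oq(x, y, kind = "ftir", truth = truth %||% list(bands = bands))
}

#' Forward-model an XRD pattern with Scherrer-consistent peak widths
#'
#' Places Gaussian diffraction peaks at 2-theta = 26 deg (002, crystallite
#' length) and 40 deg (310, crystallite width) whose FWHMs are obtained by
#' inverting the Scherrer relation `B = lambda / (L cos(theta))` at the
#' requested sizes.
#'
#' @param length_nm mean crystallite length (002 direction), nm.
#' @param width_nm mean crystallite width (310 direction), nm.
#' @param wavelength_nm X-ray wavelength (CuKalpha, 0.15406 nm).
#' @param background polynomial coefficients (intercept, slope, ...) in
#'   (2theta - 20) for the background counts.
#' @param noise relative sd of additive noise (fraction of the 26-deg peak
#'   height).
#' @param amp26,amp40 peak heights in counts.
#' @param range_deg scan range in 2-theta degrees.
#' @param step_deg scan step (instrument default 0.0334 deg).
#' @return A [spectrum_oq()] of kind `"xrd"`; `truth` holds the sizes and the
#'   exact FWHMs in degrees.
#' @export
forward_xrd <- function(length_nm, width_nm = length_nm,
                        wavelength_nm = 0.15406, background = c(50, -0.5),
                        noise = 0, amp26 = 1000, amp40 = 400,
                        range_deg = c(20, 45), step_deg = 0.0334) {
  stopifnot(length_nm > 0, width_nm > 0)
  fwhm_deg <- function(size_nm, two_theta) {
    rad <- wavelength_nm / (size_nm * cos(two_theta / 2 * pi / 180))
    rad * 180 / pi
  }
  f26 <- fwhm_deg(length_nm, 26)
  f40 <- fwhm_deg(width_nm, 40)
  x <- seq(range_deg[1], range_deg[2], by = step_deg)
  y <- outer(x - range_deg[1], seq_along(background) - 1, `^`) %*% background
  y <- as.numeric(y)
  y <- y + amp26 * exp(-0.5 * ((x - 26) / (f26 / FWHM_FACTOR))^2)
  y <- y + amp40 * exp(-0.5 * ((x - 40) / (f40 / FWHM_FACTOR))^2)
  if (noise > 0) y <- y + rnorm(length(y), 0, noise * amp26)
  spectrum_oq(x, y, kind = "xrd",
              truth = list(length_nm = length_nm, width_nm = width_nm,
                           fwhm26_deg = f26, fwhm40_deg = f40,
                           wavelength_nm = wavelength_nm))
}
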