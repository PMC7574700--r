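# Forward model for the fluorescent-AGE / hydroxyproline plate assay.

#' Forward-model a fluorescent-AGE plate assay with quinine and
#' hydroxyproline standards
#'
#' Emits a fluorescence plate (quinine standards, serially diluted two-fold
#' from a 10 ug/mL stock, plus sample wells) and an absorbance plate
#' (hydroxyproline standards from a 2 mg/mL stock plus sample wells), all on
#' linear instrument responses, consistent with the latent per-sample truth:
#' total fluorescent AGEs `true_fage` (ng quinine per mg collagen) and
#' `collagen_mg`. Bone is hydrolysed at 100 uL of 6 N HCl per mg bone and the
#' hydrolysate read after a 10-fold dilution.
#'
#' @param true_fage ng quinine-equivalents per mg collagen.
#' @param collagen_mg collagen mass in the hydrolysed specimen, mg.
#' @param bone_mg specimen mass, mg (sets the hydrolysate volume).
#' @param dilution dilution factor of the hydrolysate before reading.
#' @param n_dilutions number of two-fold serial dilution steps for the
#'   standards (a blank is always appended).
#' @param q_slope,q_intercept fluorescence response: reading per (ug/mL)
#'   quinine, and background.
#' @param h_slope,h_intercept absorbance response: OD570 per (mg/mL)
#'   hydroxyproline, and background.
#' @param noise relative sd of reading noise (fraction of each reading).
#' @param sample_id sample well identifier.
#' @return list with elements `fluorescence` and `absorbance` (both
#'   [plate_assay()]) and `truth`.
#' @export
forward_plate <- function(true_fage, collagen_mg, bone_mg = 50,
                          dilution = 10, n_dilutions = 7,
                          q_slope = 5000, q_intercept = 50,
                          h_slope = 0.45, h_intercept = 0.04,
                          noise = 0, sample_id = "S1") {
  stopifnot(true_fage >= 0, collagen_mg > 0, bone_mg > 0)
  hydrolysate_mL <- bone_mg * 100 / 1000   # 100 uL 6N HCl per mg bone

  jitter <- function(r) if (noise > 0) r * (1 + rnorm(length(r), 0, noise)) else r

  q_conc <- c(10 / 2^(0:(n_dilutions - 1)), 0)          # ug/mL
  q_read <- jitter(q_slope * q_conc + q_intercept)
  h_conc <- c(2 / 2^(0:(n_dilutions - 1)), 0)           # mg/mL
  h_read <- jitter(h_slope * h_conc + h_intercept)

  # sample fluorescence: total quinine-equivalents spread over the
  # hydrolysate, then diluted into the read well
  quinine_eq_ng <- true_fage * collagen_mg
  q_well_ug_mL <- quinine_eq_ng / 1000 / hydrolysate_mL / dilution
  s_fluor <- jitter(q_slope * q_well_ug_mL + q_intercept)

  hyp_mg <- 0.14 * collagen_mg
  h_well_mg_mL <- hyp_mg / hydrolysate_mL / dilution
  s_abs <- jitter(h_slope * h_well_mg_mL + h_intercept)

  wells <- function(n) sprintf("%s%d", rep(LETTERS[1:8], length.out = n), seq_len(n))
  fluor <- plate_assay(
    standards = data.frame(well = wells(length(q_conc)), role = "standard",
                           concentration = q_conc, reading = q_read),
    samples = data.frame(id = sample_id, reading = s_fluor, dilution = dilution),
    mode = "fluorescence_360_460",
    meta = list(bone_mg = bone_mg, hydrolysate_mL = hydrolysate_mL,
                hydrolysate_uL_per_mg = 100))
  absb <- plate_assay(
    standards = data.frame(well = wells(length(h_conc)), role = "standard",
                           concentration = h_conc, reading = h_read),
    samples = data.frame(id = sample_id, reading = s_abs, dilution = dilution),
    mode = "absorbance_570",
    meta = list(bone_mg = bone_mg, hydrolysate_mL = hydrolysate_mL,
                hydrolysate_uL_per_mg = 100))
  list(fluorescence = fluor, absorbance = absb,
       truth = list(fage = true_fage, collagen_mg = collagen_mg,
                    hydroxyproline_mg = hyp_mg,
                    quinine_eq_ng = quinine_eq_ng))
}
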