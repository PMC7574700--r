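# Forward models for voxel volumes: cortical annulus and trabecular lattice.

#' Forward-model a voxel volume (cortical annulus or trabecular lattice)
#'
#' `kind = "cortical"` builds a hollow-cylinder binary mask (optionally with
#' gray values at a constant calibrated tissue density); the outer/inner radii
#' are either given directly or derived from a target cortical area and
#' thickness via `Ct.Ar = pi (R^2 - r^2)`, `Ct.Th = R - r`.
#'
#' `kind = "trabecular"` builds, by default, a parallel-plate lattice whose
#' plate thickness equals the target `Tb.Th` and whose plate spacing is set so
#' the foreground fraction equals the target `BV/TV`; alternatively
#' (`method = "field"`) a thresholded smoothed Gaussian random field whose
#' threshold is chosen by quantile so BV/TV is hit exactly (thickness is then
#' emergent).
#'
#' @param kind `"cortical"` or `"trabecular"`.
#' @param voxel_um isotropic voxel size, um (the study scans used 20 um for
#'   the whole femur and 5 um for the femoral head).
#' @param outer_radius_mm,inner_radius_mm cortical annulus radii, mm.
#' @param ct_ar_mm2,ct_th_mm alternative cortical parameterisation.
#' @param height_mm axial extent of the cortical ROI (1 mm above and below
#'   the mid-diaphysis by convention).
#' @param margin_mm background margin added around the annulus in-plane.
#' @param edge_mm edge length of the cubical trabecular ROI.
#' @param bvtv_pct target trabecular bone volume fraction, percent.
#' @param tb_th_mm target trabecular thickness, mm.
#' @param method trabecular generator: `"plates"` or `"field"`.
#' @param field_sigma_mm smoothing length of the random field, mm.
#' @param phase plate-stack phase offset in [0,1); randomised when `NA`.
#' @param gray logical: emit gray values instead of a binary mask.
#' @param tissue_density_mg_cc constant calibrated density of bone voxels
#'   (used with `gray = TRUE`).
#' @param calibration a [calibrate_density()] object mapping gray to density;
#'   identity when `NULL`.
#' @param noise relative sd of gray-value noise.
#' @return A [voxel_volume()] with analytic `truth`.
#' @export
forward_volume <- function(kind = c("cortical", "trabecular"),
                           voxel_um = if (kind == "cortical") 20 else 5,
                           outer_radius_mm = NULL, inner_radius_mm = NULL,
                           ct_ar_mm2 = NULL, ct_th_mm = NULL,
                           height_mm = 2, margin_mm = 0.2,
                           edge_mm = 1.5, bvtv_pct = 46.14, tb_th_mm = 0.095,
                           method = c("plates", "field"),
                           field_sigma_mm = 0.05, phase = NA,
                           gray = FALSE, tissue_density_mg_cc = 1594.7,
                           calibration = NULL, noise = 0) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  vox_mm <- voxel_um / 1000
  if (kind == "cortical") {
    if (is.null(outer_radius_mm)) {
      stopifnot(!is.null(ct_ar_mm2), !is.null(ct_th_mm))
      t <- ct_th_mm
      s <- ct_ar_mm2 / (pi * t)            # R + r
      outer_radius_mm <- (s + t) / 2
      inner_radius_mm <- (s - t) / 2
      if (inner_radius_mm <= 0)
        stop("infeasible cortical geometry: Ct.Ar/Ct.Th imply r <= 0")
    }
    R <- outer_radius_mm; r <- inner_radius_mm
    stopifnot(R > r, r >= 0)
    half <- R + margin_mm
    nxy <- 2L * as.integer(ceiling(half / vox_mm))
    nz <- max(1L, as.integer(round(height_mm / vox_mm)))
    cx <- (nxy + 1) / 2
    xs <- (seq_len(nxy) - cx) * vox_mm
    rad2 <- outer(xs^2, xs^2, `+`)
    mask2d <- rad2 <= R^2 & rad2 >= r^2
    vals <- array(rep(as.numeric(mask2d), nz), dim = c(nxy, nxy, nz))
    truth <- list(outer_radius_mm = R, inner_radius_mm = r,
                  ct_ar_mm2 = pi * (R^2 - r^2), ct_th_mm = R - r,
                  j_mm4 = pi * (R^4 - r^4) / 2,
                  tmd_mg_cc = if (gray) tissue_density_mg_cc else NA_real_)
    roi <- list(kind = "cylinder", outer_radius_mm = R, height_mm = height_mm)
  } else {
    n <- max(2L, as.integer(round(edge_mm / vox_mm)))
    f <- bvtv_pct / 100
    stopifnot(f > 0, f < 1)
    if (method == "plates") {
      gap_mm <- tb_th_mm * (1 - f) / f
      period <- tb_th_mm + gap_mm
      if (is.na(phase)) phase <- runif(1)
      z <- (seq_len(n) - 0.5) * vox_mm
      inplate <- ((z / period + phase) %% 1) < (tb_th_mm / period)
      vals <- array(rep(as.numeric(inplate), each = n * n), dim = c(n, n, n))
      truth <- list(bvtv_pct = 100 * tb_th_mm / period, tb_th_mm = tb_th_mm,
                    tb_sp_mm = gap_mm, tb_n_per_mm = f / tb_th_mm,
                    method = "plates")
    } else {
      field <- array(rnorm(n^3), dim = c(n, n, n))
      field <- gaussian_blur3d(field, field_sigma_mm / vox_mm)
      thr <- quantile(field, 1 - f)
      vals <- array(as.numeric(field >= thr), dim = dim(field))
      truth <- list(bvtv_pct = bvtv_pct, tb_th_mm = NA_real_,
                    method = "field")
    }
    truth$tmd_mg_cc <- if (gray) tissue_density_mg_cc else NA_real_
    roi <- list(kind = "cube", edge_mm = edge_mm)
  }
  if (gray) {
    # invert the density calibration so that calibrated gray == density
    g_fg <- if (is.null(calibration)) tissue_density_mg_cc else
      (tissue_density_mg_cc - calibration$intercept) / calibration$slope
    g_bg <- if (is.null(calibration)) 0 else -calibration$intercept /
      calibration$slope
    gvals <- ifelse(vals > 0.5, g_fg, g_bg)
    if (noise > 0) gvals <- gvals + rnorm(length(gvals), 0, noise * abs(g_fg))
    vals <- array(gvals, dim = dim(vals))
    thr <- (g_fg + g_bg) / 2
    voxel_volume(vals, voxel_um, binary = FALSE, threshold = thr, roi = roi,
                 truth = truth)
  } else {
    voxel_volume(vals, voxel_um, binary = TRUE, roi = roi, truth = truth)
  }
}

#' Separable Gaussian blur of a 3D array (reflecting boundaries)
#' @noRd
gaussian_blur3d <- function(a, sigma_vox) {
  if (sigma_vox <= 0) return(a)
  half <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-0.5 * ((-half):half / sigma_vox)^2)
  k <- k / sum(k)
  smooth_lines <- function(m) {
    # m: matrix, smooth along rows (dimension 1)
    n <- nrow(m)
    idx <- outer(seq_len(n), (-half):half, `+`)
    idx <- abs(idx - 1L) %% (2L * (n - 1L))
    idx <- ifelse(idx >= n, 2L * (n - 1L) - idx, idx) + 1L
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  d <- dim(a)
  a <- array(smooth_lines(matrix(a, d[1])), d)
  a <- aperm(a, c(2, 3, 1))
  a <- array(smooth_lines(matrix(a, d[2])), c(d[2], d[3], d[1]))
  a <- aperm(a, c(2, 3, 1))
  a <- array(smooth_lines(matrix(a, d[3])), c(d[3], d[1], d[2]))
  aperm(a, c(2, 3, 1))
}
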