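# Density calibration and cortical/trabecular voxel morphometry.

#' Two-point hydroxyapatite density calibration
#'
#' Builds the exact linear map from mean phantom gray values to known
#' hydroxyapatite densities.
#'
#' @param gray_means mean gray values of the two phantoms.
#' @param densities known phantom densities, mg/cc HA (default 200, 800).
#' @return list of class `density_calibration`: `slope`, `intercept`.
#' @export
calibrate_density <- function(gray_means, densities = c(200, 800)) {
  stopifnot(length(gray_means) == 2L, length(densities) == 2L)
  if (gray_means[1] == gray_means[2])
    stop("phantom gray values must be distinct")
  slope <- diff(densities) / diff(gray_means)
  if (slope <= 0) stop("calibration must be strictly increasing")
  structure(list(slope = slope, intercept = densities[1] -
                   slope * gray_means[1]),
            class = "density_calibration")
}

#' Apply a density calibration voxel-wise
#' @param calibration a [calibrate_density()] object.
#' @param gray gray value(s).
#' @return density, mg/cc HA.
#' @export
apply_calibration <- function(calibration, gray) {
  calibration$intercept + calibration$slope * gray
}

#' Tissue mineral density over the bone mask
#'
#' @param v a gray [voxel_volume()].
#' @param calibration a [calibrate_density()] object.
#' @return mean calibrated density over foreground voxels, mg/cc.
#' @export
tissue_mineral_density <- function(v, calibration) {
  m <- volume_mask(v)
  if (!any(m)) stop("empty bone mask")
  mean(apply_calibration(calibration, v$values[m]))
}

# squared EDT in voxel units, plus the distance ridge, via compiled code
edt_and_ridge <- function(mask) {
  dims <- dim(mask)
  edt <- edt_sq_cpp(as.logical(mask), as.integer(dims))
  ridge <- distance_ridge_cpp(edt, as.integer(dims))
  list(edt_sq = array(edt, dims), ridge = ridge)
}

#' Inscribed-sphere local thickness map
#'
#' Computes the Hildebrand-style local thickness of a binary phase: each
#' voxel is assigned the diameter of the largest sphere that fits entirely
#' inside the phase and contains it (distance-ridge sphere painting on the
#' Euclidean distance transform).
#'
#' @param mask logical 3D array (the phase of interest is `TRUE`).
#' @param voxel_mm voxel edge length in mm.
#' @return list: `map` (3D array of thickness, mm; 0 outside the phase),
#'   `mean` (voxel-weighted mean thickness over the phase, mm).
#' @export
local_thickness <- function(mask, voxel_mm) {
  dims <- dim(mask)
  er <- edt_and_ridge(mask)
  th <- local_thickness_cpp(as.logical(mask), as.numeric(er$edt_sq),
                            er$ridge, as.integer(dims))
  th <- array(th, dims) * voxel_mm
  list(map = th, mean = mean(th[mask]))
}

#' Cortical morphometry of a mid-diaphysis ROI
#'
#' Per axial slice: cortical area `Ct.Ar` (foreground voxel count times the
#' voxel area), the area centroid, and the polar moment of inertia
#' `J = sum(r^2 dA)` about the slice centroid; results are averaged over
#' slices. Cortical thickness `Ct.Th` is twice the mean Euclidean distance
#' to the background over the medial (distance-ridge) surface, evaluated in
#' 3D.
#'
#' @param v a binary (or thresholded gray) [voxel_volume()].
#' @return list of class `morphometry_result`: `ct_ar_mm2`, `ct_th_mm`,
#'   `j_mm4`, `n_slices`, `flags`.
#' @export
cortical_morphometry <- function(v) {
  m <- volume_mask(v)
  if (!any(m)) stop("empty ROI")
  vox_mm <- v$voxel_um / 1000
  apx <- vox_mm^2
  dims <- dim(m)
  flags <- character(0)
  ar <- j <- numeric(0)
  for (z in seq_len(dims[3])) {
    sl <- m[, , z]
    nfg <- sum(sl)
    if (nfg == 0L) {
      flags <- c(flags, "empty_slice_skipped")
      next
    }
    idx <- which(sl, arr.ind = TRUE)
    xs <- idx[, 1] * vox_mm
    ys <- idx[, 2] * vox_mm
    cx <- mean(xs); cy <- mean(ys)
    ar <- c(ar, nfg * apx)
    j <- c(j, sum((xs - cx)^2 + (ys - cy)^2) * apx)
  }
  if (!length(ar)) stop("all slices empty")
  if (length(flags)) warning("empty slices skipped")
  er <- edt_and_ridge(m)
  rvals <- sqrt(er$edt_sq[er$ridge])
  ct_th <- 2 * mean(rvals) * vox_mm
  structure(list(ct_ar_mm2 = mean(ar), ct_th_mm = ct_th, j_mm4 = mean(j),
                 n_slices = length(ar), flags = unique(flags)),
            class = "morphometry_result")
}

#' Trabecular morphometry of a cubical ROI
#'
#' `BV/TV` is the foreground voxel fraction; `Tb.Th` and `Tb.Sp` are the
#' inscribed-sphere local thickness of the foreground and background phases;
#' `Tb.N = (BV/TV)/Tb.Th`.
#'
#' @param v a binary (or thresholded gray) [voxel_volume()].
#' @return list of class `morphometry_result`: `bvtv_pct`, `tb_th_mm`,
#'   `tb_sp_mm`, `tb_n_per_mm`, `flags`.
#' @export
trabecular_morphometry <- function(v) {
  m <- volume_mask(v)
  vox_mm <- v$voxel_um / 1000
  f <- mean(m)
  if (f <= 0 || f >= 1) {
    return(structure(list(bvtv_pct = 100 * f, tb_th_mm = NA_real_,
                          tb_sp_mm = NA_real_, tb_n_per_mm = NA_real_,
                          flags = "single_phase"),
                     class = "morphometry_result"))
  }
  th <- local_thickness(m, vox_mm)
  sp <- local_thickness(!m, vox_mm)
  structure(list(bvtv_pct = 100 * f, tb_th_mm = th$mean, tb_sp_mm = sp$mean,
                 tb_n_per_mm = f / th$mean, flags = character(0)),
            class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  if (!is.null(x$ct_ar_mm2))
    cat(sprintf("<morphometry> Ct.Ar %.3f mm^2, Ct.Th %.3f mm, J %.4f mm^4\n",
                x$ct_ar_mm2, x$ct_th_mm, x$j_mm4))
  else
    cat(sprintf(paste0("<morphometry> BV/TV %.2f%%, Tb.Th %.4f mm, ",
                       "Tb.Sp %.4f mm, Tb.N %.3f /mm\n"),
                x$bvtv_pct, x$tb_th_mm, x$tb_sp_mm, x$tb_n_per_mm))
  invisible(x)
}
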