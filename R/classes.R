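# Core S3 containers. Constructors validate the invariants the analyzers rely
# on; analysis functions accept either the class or a plain data frame with the
# documented columns.

#' Load-displacement trace from a three-point bending test
#'
#' @param time seconds.
#' @param load Newtons.
#' @param displacement millimetres, non-decreasing once the preload is crossed.
#' @param span support span in mm (default 19).
#' @param preload preload force in N (default 10).
#' @param rate crosshead displacement rate in mm/min (default 10).
#' @param truth optional named list of generator ground truth (see
#'   [forward_bending()]).
#' @return An object of class `ld_trace`: a data frame with columns
#'   `time_s`, `load_N`, `disp_mm` and protocol metadata attributes.
#' @export
ld_trace <- function(time, load, displacement, span = 19, preload = 10,
                     rate = 10, truth = NULL) {
  n <- length(load)
  stopifnot(length(time) == n, length(displacement) == n)
  if (n < 10L) stop("trace needs at least 10 samples")
  # displacement must be non-decreasing after the preload crossing
  after <- which(load >= preload)
  if (length(after)) {
    d <- displacement[min(after):n]
    if (any(diff(d) < -1e-9)) stop("displacement decreases after preload crossing")
  }
  out <- data.frame(time_s = time, load_N = load, disp_mm = displacement)
  structure(out, class = c("ld_trace", "data.frame"),
            span = span, preload = preload, rate = rate, truth = truth)
}

#' @export
print.ld_trace <- function(x, ...) {
  cat(sprintf("<ld_trace> %d samples, span %g mm, peak load %.2f N\n",
              nrow(x), attr(x, "span"), max(x$load_N)))
  invisible(x)
}

#' Cyclic reference-point indentation cycle set (one indent site)
#'
#' @param cycles list of data frames with columns `force_N`, `depth_um`,
#'   one per indentation cycle in temporal order.
#' @param F_target nominal peak force per cycle, N (default 8).
#' @param frequency cycling frequency, Hz (default 2).
#' @param site_id identifier of the indent site.
#' @param truth optional generator ground truth.
#' @return An object of class `cycle_set`.
#' @export
cycle_set <- function(cycles, F_target = 8, frequency = 2, site_id = "site1",
                      truth = NULL) {
  if (length(cycles) < 2L) stop("need at least 2 cycles")
  peaks <- vapply(cycles, function(cy) max(cy$force_N), numeric(1))
  if (any(abs(peaks - F_target) / F_target > 0.02))
    stop("cycle peak force deviates more than 2% from F_target")
  structure(list(cycles = cycles, F_target = F_target, frequency = frequency,
                 site_id = site_id, truth = truth),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> %d cycles at %g N (%s)\n",
              length(x$cycles), x$F_target, x$site_id))
  invisible(x)
}

#' Nanoindentation load-depth curve
#'
#' @param load microNewtons.
#' @param depth nanometres.
#' @param segment character vector: `"load"`, `"hold"` or `"unload"`.
#' @param P_max nominal peak load, uN (default 1000).
#' @param truth optional generator ground truth.
#' @return An object of class `nano_curve` (data frame `load_uN`, `depth_nm`,
#'   `segment`).
#' @export
nano_curve <- function(load, depth, segment, P_max = 1000, truth = NULL) {
  n <- length(load)
  stopifnot(length(depth) == n, length(segment) == n)
  segment <- as.character(segment)
  if (!all(segment %in% c("load", "hold", "unload")))
    stop("segment labels must be load/hold/unload")
  # contiguity: each label forms one run
  r <- rle(segment)
  if (anyDuplicated(r$values)) stop("segments must be contiguous")
  if (abs(max(load) - P_max) / P_max > 0.01)
    stop("max load deviates more than 1% from P_max")
  out <- data.frame(load_uN = load, depth_nm = depth, segment = segment)
  structure(out, class = c("nano_curve", "data.frame"),
            P_max = P_max, truth = truth)
}

#' Spectrum (FTIR absorbance or XRD counts)
#'
#' @param axis strictly increasing axis values: wavenumber (cm^-1) for FTIR,
#'   two-theta degrees for XRD.
#' @param values absorbance or counts.
#' @param kind `"ftir"` or `"xrd"`.
#' @param truth optional generator ground truth.
#' @return An object of class `spectrum_oq` (data frame `axis`, `value`).
#' @export
spectrum_oq <- function(axis, values, kind = c("ftir", "xrd"), truth = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(axis) == length(values))
  if (any(diff(axis) <= 0)) stop("axis must be strictly increasing")
  steps <- diff(axis)
  uniform <- max(steps) - min(steps) < 1e-6 * mean(steps)
  out <- data.frame(axis = axis, value = values)
  structure(out, class = c("spectrum_oq", "data.frame"),
            kind = kind, uniform = uniform, truth = truth)
}

#' @export
print.spectrum_oq <- function(x, ...) {
  cat(sprintf("<spectrum_oq:%s> %d points, axis %.4g..%.4g\n",
              attr(x, "kind"), nrow(x), min(x$axis), max(x$axis)))
  invisible(x)
}

#' Voxel volume with isotropic spacing
#'
#' @param values 3D array; binary mask (0/1) or gray values.
#' @param voxel_um isotropic voxel edge length in micrometres.
#' @param binary logical: is `values` already a segmentation mask?
#' @param threshold global gray threshold used when `binary = FALSE`.
#' @param roi ROI descriptor list (free-form, e.g. `list(kind="cube", edge_mm=1.5)`).
#' @param truth optional generator ground truth.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, voxel_um, binary = TRUE, threshold = NULL,
                         roi = NULL, truth = NULL) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (voxel_um <= 0) stop("voxel size must be positive")
  structure(list(values = values, voxel_um = voxel_um, binary = binary,
                 threshold = threshold, roi = roi, truth = truth),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume> %dx%dx%d @ %g um (%s)\n", d[1], d[2], d[3],
              x$voxel_um, if (x$binary) "binary" else "gray"))
  invisible(x)
}

#' Binary foreground mask of a voxel volume
#' @param v a [voxel_volume()].
#' @return logical 3D array.
#' @export
volume_mask <- function(v) {
  if (v$binary) v$values > 0.5 else v$values >= (v$threshold %||% stop(
    "gray volume needs a threshold"))
}

#' Plate-reader assay table
#'
#' @param standards data frame with columns `concentration`, `reading`.
#' @param samples data frame with columns `id`, `reading`, `dilution`.
#' @param mode `"fluorescence_360_460"` (quinine / fAGE) or
#'   `"absorbance_570"` (chloramine-T hydroxyproline).
#' @param meta named list of assay metadata (e.g. `bone_mg`,
#'   `hydrolysate_uL_per_mg`).
#' @param truth optional generator ground truth.
#' @return An object of class `plate_assay`.
#' @export
plate_assay <- function(standards, samples,
                        mode = c("fluorescence_360_460", "absorbance_570"),
                        meta = list(), truth = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(c("concentration", "reading") %in% names(standards)))
  if (nrow(standards) < 3L) stop("need at least 3 standards")
  if (diff(range(standards$concentration)) <= 0)
    stop("standards must span a non-degenerate concentration range")
  structure(list(standards = standards, samples = samples, mode = mode,
                 meta = meta, truth = truth),
            class = "plate_assay")
}
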