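# Plain-text readers/writers for the instrument formats. All artifacts are
# text so a cohort can be archived and audited without binary dependencies.

#' Write / read a bending trace CSV (`time_s,load_N,disp_mm`)
#' @param trace an [ld_trace()].
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  write.csv(as.data.frame(trace)[c("time_s", "load_N", "disp_mm")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param span,preload,rate protocol metadata to attach on read.
#' @export
read_trace <- function(path, span = 19, preload = 10, rate = 10) {
  d <- read.csv(path)
  ld_trace(d$time_s, d$load_N, d$disp_mm, span = span, preload = preload,
           rate = rate)
}

#' Write / read a cRPI record CSV (`cycle,force_N,depth_um`)
#' @param rec a [forward_rpi()] record.
#' @param path file path.
#' @export
write_rpi <- function(rec, path) {
  write.csv(data.frame(cycle = rec$cycle, force_N = rec$force,
                       depth_um = rec$depth), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rpi
#' @export
read_rpi <- function(path) {
  d <- read.csv(path)
  list(force = d$force_N, depth = d$depth_um, cycle = d$cycle)
}

#' Write / read a nanoindentation curve CSV (`segment,load_uN,depth_nm`)
#' @param curve a [nano_curve()].
#' @param path file path.
#' @export
write_nano <- function(curve, path) {
  write.csv(as.data.frame(curve)[c("segment", "load_uN", "depth_nm")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_nano
#' @param P_max nominal peak load on read, uN.
#' @export
read_nano <- function(path, P_max = 1000) {
  d <- read.csv(path)
  nano_curve(d$load_uN, d$depth_nm, d$segment, P_max = P_max)
}

#' Write / read a spectrum as two-column whitespace text
#'
#' Lines beginning with `#` carry metadata (`# kind: ftir`).
#' @param s a [spectrum_oq()].
#' @param path file path.
#' @export
write_spectrum <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", attr(s, "kind")), con)
  writeLines(sprintf("%.10g %.10g", s$axis, s$value), con)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  kind <- if (any(grepl("kind: xrd", meta))) "xrd" else "ftir"
  dat <- lines[!grepl("^#", lines)]
  m <- do.call(rbind, lapply(strsplit(trimws(dat), "\\s+"), as.numeric))
  spectrum_oq(m[, 1], m[, 2], kind = kind)
}

#' Write / read a plate assay CSV (`well,role,concentration,reading`)
#'
#' Sample rows carry the dilution factor in the `concentration` column slot
#' `dilution`.
#' @param assay a [plate_assay()].
#' @param path file path.
#' @export
write_plate <- function(assay, path) {
  std <- data.frame(well = assay$standards$well, role = "standard",
                    concentration = assay$standards$concentration,
                    reading = assay$standards$reading,
                    dilution = NA_real_)
  smp <- data.frame(well = paste0("S", seq_len(nrow(assay$samples))),
                    role = "sample", concentration = NA_real_,
                    reading = assay$samples$reading,
                    dilution = assay$samples$dilution)
  out <- rbind(std, smp)
  attrline <- sprintf("# mode: %s; bone_mg: %g; hydrolysate_mL: %g",
                      assay$mode, assay$meta$bone_mg %||% NA,
                      assay$meta$hydrolysate_mL %||% NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attrline, con)
  write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate
#' @export
read_plate <- function(path) {
  first <- readLines(path, n = 1L)
  mode <- if (grepl("absorbance", first)) "absorbance_570" else
    "fluorescence_360_460"
  getnum <- function(key) {
    m <- regmatches(first, regexec(paste0(key, ": ([-0-9.eE]+)"), first))[[1]]
    if (length(m) == 2L) as.numeric(m[2]) else NA_real_
  }
  d <- read.csv(path, skip = 1L)
  std <- d[d$role == "standard", ]
  smp <- d[d$role == "sample", ]
  plate_assay(standards = data.frame(well = std$well, role = "standard",
                                     concentration = std$concentration,
                                     reading = std$reading),
              samples = data.frame(id = smp$well, reading = smp$reading,
                                   dilution = smp$dilution),
              mode = mode,
              meta = list(bone_mg = getnum("bone_mg"),
                          hydrolysate_mL = getnum("hydrolysate_mL")))
}

#' Write / read a voxel volume as plain text plus a JSON sidecar
#'
#' The voxel values are written slice-row-major, one z-slice row per line;
#' `<path>.json` records the dimensions, voxel size and ROI metadata. (The
#' study toolchain would use TIFF stacks; plain text keeps the archive
#' binary-free.)
#' @param v a [voxel_volume()].
#' @param path file path for the voxel text (sidecar written alongside).
#' @export
write_volume <- function(v, path) {
  d <- dim(v$values)
  side <- list(dims = d, voxel_um = v$voxel_um, binary = v$binary,
               threshold = v$threshold, roi = v$roi)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  vals <- v$values
  fmt <- if (v$binary) function(x) as.integer(x > 0.5) else
    function(x) signif(x, 8)
  for (z in seq_len(d[3])) {
    sl <- matrix(fmt(vals[, , z]), d[1], d[2])
    writeLines(apply(sl, 2, paste, collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- scan(path, what = numeric(), quiet = TRUE)
  d <- as.integer(side$dims)
  # file stores one z-slice column per line (length d[1]), d[2]*d[3] lines
  arr <- array(vals, dim = d)
  voxel_volume(arr, side$voxel_um, binary = isTRUE(side$binary),
               threshold = side$threshold,
               roi = side$roi)
}
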