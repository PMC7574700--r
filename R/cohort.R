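# Synthetic two-group cohort generation: latent per-animal parameters drawn
# from group-specific truncated normals, forward-modelled into raw
# instrument artifacts.

#' Default latent-parameter table for a control vs T2D rat cohort
#'
#' One row per latent parameter: control mean/SD, T2D mean/SD, positivity
#' flag and a glycation-factor loading. Endpoint metabolic covariates and
#' every micro-CT parameter use the study's group summary values verbatim;
#' nanoindentation (reduced modulus, hardness), XRD crystallite length and
#' width, and the fAGE concentration use the printed group means; the
#' remaining modality parameters are anchored at typical SD-rat control
#' values with the T2D mean set by the reported percent group difference.
#'
#' The `loading` column couples a parameter to a per-animal latent
#' "glycation severity" factor in the T2D group only (positive loading:
#' higher severity raises the parameter). The default +/-0.835 loadings on
#' NE-xLR and PYD reproduce a within-T2D-group Pearson correlation of
#' about -0.697 between them.
#'
#' @return data frame with columns `parameter`, `ctrl_mean`, `ctrl_sd`,
#'   `t2d_mean`, `t2d_sd`, `positive`, `loading`.
#' @export
default_parameter_table <- function() {
  p <- function(name, cm, cs, tm, ts, positive = TRUE, loading = 0)
    data.frame(parameter = name, ctrl_mean = cm, ctrl_sd = cs,
               t2d_mean = tm, t2d_sd = ts, positive = positive,
               loading = loading)
  rbind(
    # endpoint metabolic covariates (group summary table, verbatim)
    p("body_weight_g",      252.8, 30.67, 247.8, 13.92),
    p("fasting_glucose_mg_dL", 97.9, 10.46, 292.5, 45.69),
    p("hba1c_pct",          6.08, 0.39, 7.89, 0.52),
    p("plasma_insulin_mIU_L", 2.82, 0.588, 2.216, 0.197),
    p("triglyceride_mg_dL", 64.21, 8.39, 213.66, 29.06),
    p("cholesterol_mg_dL",  63.68, 7.78, 130.64, 26.53),
    # three-point bending (control anchors chosen; T2D set by reported
    # percent differences: -36.9%, -57%, -41%, -36.8%)
    p("F_max_N",       120,  12,   120 * (1 - 0.369),  7.6),
    p("stiffness_N_mm", 250, 25,   250 * (1 - 0.57),  10.8),
    p("work_N_mm",      45,  9,    45 * (1 - 0.41),    5.3),
    p("PYD_mm",        0.25, 0.05, 0.25 * (1 - 0.368), 0.032, loading = -0.835),
    # cRPI (control anchors chosen; T2D by +4.1%, +14.7%, -9.1%, +11.3%)
    p("ID_1st_um",      85,  4,    85 * 1.041,  4.2),
    p("IDI_um",         10,  1.2,  10 * 1.147,  1.38),
    p("US_1st_N_um",  0.55, 0.05, 0.55 * (1 - 0.091), 0.045),
    p("Avg_ED_uJ",      25,  3,    25 * 1.113,  3.34),
    # nanoindentation (printed group means)
    p("Er_GPa",       20.6, 1.04, 16.22, 0.78),
    p("H_GPa",       0.577, 0.039, 0.387, 0.039),
    # XRD crystallite sizes (printed group means)
    p("crystallite_length_nm", 18.29, 0.73, 16.67, 0.85),
    p("crystallite_width_nm",   4.64, 0.11,  5.18, 0.19),
    # FTIR (control anchors chosen; T2D by -33.46%, -22.22%, -9.93%,
    # -6.94%, +85.65%, maturity unchanged)
    p("mineral_to_matrix",  4.0, 0.45, 4.0 * (1 - 0.3346), 0.50),
    p("carbonate_to_phosphate", 0.0090, 0.0012, 0.0090 * (1 - 0.2222), 0.0010),
    p("crystallinity",     1.25, 0.06, 1.25 * (1 - 0.0993), 0.055),
    p("acid_phosphate",    0.72, 0.05, 0.72 * (1 - 0.0694), 0.047),
    p("NE_xLR",            1.55, 0.18, 1.55 * 1.8565, 0.33, loading = 0.835),
    p("collagen_maturity",  3.0, 0.30, 3.0, 0.30),
    # fAGE (printed group means)
    p("fage_ng_mg",       288.6, 33.5, 412.4, 36.6),
    # micro-CT (group summary table, verbatim; Tb.Sp/Tb.N/J/Tb.TMD recorded
    # as covariates, the forward volumes honour BV/TV, Tb.Th, Ct.Ar, Ct.Th)
    p("bvtv_pct",         46.14, 2.10, 38.54, 6.05),
    p("tb_n_per_mm",      5.048, 1.20, 4.32, 0.44),
    p("tb_th_mm",         0.095, 0.017, 0.089, 0.011),
    p("tb_sp_mm",         0.142, 0.037, 0.166, 0.029),
    p("tb_tmd_mg_cc",     739.0, 343, 963.0, 105),
    p("ct_tmd_mg_cc",    1594.7, 50, 1604.1, 114),
    p("ct_ar_mm2",         6.76, 0.28, 5.72, 0.85),
    p("ct_th_mm",          0.70, 0.02, 0.61, 0.05),
    p("j_mm4",             0.34, 0.046, 0.26, 0.056)
  )
}

#' Cohort generation configuration
#'
#' @param n_per_group animals per group (>= 2).
#' @param seed RNG seed; everything downstream is deterministic given it.
#' @param parameter_table latent parameter table
#'   ([default_parameter_table()]).
#' @param noise named list of per-modality relative noise amplitudes.
#' @param modalities modalities to forward-model.
#' @param n_rpi_sites cRPI indents per animal (study protocol: 6).
#' @param n_nano_indents nanoindents per animal (study protocol: 8).
#' @param site_cv relative between-indent variation within an animal.
#' @param cortical_voxel_um,trabecular_voxel_um scan resolutions (study
#'   protocol: 20 and 5 um).
#' @param trabecular_edge_mm trabecular ROI edge (study protocol: 1.5 mm).
#' @param cortical_height_mm cortical ROI height (1 mm above + below the
#'   mid-diaphysis).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 10, seed = 1,
                          parameter_table = default_parameter_table(),
                          noise = list(bending = 0.002, rpi = 0.002,
                                       nano = 0, ftir = 0.0005, xrd = 0.005,
                                       plate = 0.002, volume = 0),
                          modalities = c("bending", "rpi", "nano", "ftir",
                                         "xrd", "fage", "microct"),
                          n_rpi_sites = 6, n_nano_indents = 8,
                          site_cv = 0.03,
                          cortical_voxel_um = 20, trabecular_voxel_um = 5,
                          trabecular_edge_mm = 1.5, cortical_height_mm = 2) {
  if (n_per_group < 2) stop("need at least 2 animals per group")
  if (any(parameter_table$ctrl_sd < 0) || any(parameter_table$t2d_sd < 0))
    stop("SDs must be non-negative")
  structure(list(n_per_group = n_per_group, seed = seed,
                 parameter_table = parameter_table, noise = noise,
                 modalities = modalities, n_rpi_sites = n_rpi_sites,
                 n_nano_indents = n_nano_indents, site_cv = site_cv,
                 cortical_voxel_um = cortical_voxel_um,
                 trabecular_voxel_um = trabecular_voxel_um,
                 trabecular_edge_mm = trabecular_edge_mm,
                 cortical_height_mm = cortical_height_mm),
            class = "cohort_config")
}

#' Draw the latent parameter table for one cohort
#'
#' Independent truncated-at-zero normals per parameter, with the configured
#' glycation-factor loadings inducing cross-parameter correlation within the
#' T2D group.
#'
#' @param config a [cohort_config()].
#' @return data frame, one row per animal: `id`, `group`, `glycation_factor`
#'   and one `true_<parameter>` column per latent parameter.
#' @export
draw_latents <- function(config) {
  pt <- config$parameter_table
  n <- config$n_per_group
  groups <- rep(c("control", "T2D"), each = n)
  ids <- c(sprintf("C%02d", seq_len(n)), sprintf("D%02d", seq_len(n)))
  g <- rnorm(2 * n)                       # glycation severity factor
  out <- data.frame(id = ids, group = groups, glycation_factor = g,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pt))) {
    mu <- ifelse(groups == "control", pt$ctrl_mean[i], pt$t2d_mean[i])
    sdv <- ifelse(groups == "control", pt$ctrl_sd[i], pt$t2d_sd[i])
    lam <- ifelse(groups == "T2D", pt$loading[i], 0)
    z <- rnorm(2 * n)
    val <- mu + sdv * (lam * g + sqrt(1 - lam^2) * z)
    if (pt$positive[i]) {
      bad <- val <= 0
      tries <- 0L
      while (any(bad) && tries < 100L) {
        z2 <- rnorm(sum(bad))
        val[bad] <- mu[bad] + sdv[bad] * (lam[bad] * g[bad] +
                                            sqrt(1 - lam[bad]^2) * z2)
        bad <- val <= 0
        tries <- tries + 1L
      }
      if (any(bad)) {
        warning("truncating non-positive draws for ", pt$parameter[i])
        val[bad] <- mu[bad] * 1e-3
      }
    }
    out[[paste0("true_", pt$parameter[i])]] <- val
  }
  out
}

#' Generate a full synthetic cohort on disk
#'
#' Draws the latent truth for every animal, forward-models one file set per
#' animal per enabled modality under `out_dir`, and returns (and writes) the
#' cohort table linking animals to artifact paths and latent truths.
#' Deterministic given `(config, seed)`.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if missing).
#' @return the cohort table (also written as `cohort.csv`).
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  set.seed(config$seed)
  tab <- draw_latents(config)
  mods <- config$modalities
  nz <- config$noise
  for (a in seq_len(nrow(tab))) {
    id <- tab$id[a]
    tr <- function(p) tab[[paste0("true_", p)]][a]
    if ("bending" %in% mods) {
      k <- tr("stiffness_N_mm"); fm <- tr("F_max_N"); pyd <- tr("PYD_mm")
      fy <- max(0.9 * fm, fm - 0.8 * k * pyd)   # keep the arc feasible
      trace <- forward_bending(k, F_yield = fy, F_max = fm, PYD = pyd,
                               noise = nz$bending)
      f <- file.path(out_dir, sprintf("%s_bending.csv", id))
      write_trace(trace, f)
      tab$bending_file[a] <- f
    }
    if ("rpi" %in% mods) {
      files <- character(config$n_rpi_sites)
      for (s in seq_len(config$n_rpi_sites)) {
        jit <- function(x) x * (1 + rnorm(1, 0, config$site_cv))
        rec <- forward_rpi(first_depth = jit(tr("ID_1st_um")),
                           creep_per_cycle = jit(tr("IDI_um")) / 9,
                           unload_slope = jit(tr("US_1st_N_um")),
                           loop_area = jit(tr("Avg_ED_uJ")),
                           noise = nz$rpi)
        files[s] <- file.path(out_dir, sprintf("%s_rpi_site%d.csv", id, s))
        write_rpi(rec, files[s])
      }
      tab$rpi_files[a] <- paste(files, collapse = ";")
    }
    if ("nano" %in% mods) {
      files <- character(config$n_nano_indents)
      for (s in seq_len(config$n_nano_indents)) {
        jit <- function(x) x * (1 + rnorm(1, 0, config$site_cv))
        cur <- forward_nano(Er = jit(tr("Er_GPa")), H = jit(tr("H_GPa")),
                            noise = nz$nano)
        files[s] <- file.path(out_dir, sprintf("%s_nano%d.csv", id, s))
        write_nano(cur, files[s])
      }
      tab$nano_files[a] <- paste(files, collapse = ";")
    }
    if ("ftir" %in% mods) {
      bands <- ftir_band_library(
        mineral_to_matrix = tr("mineral_to_matrix"),
        carbonate_to_phosphate = tr("carbonate_to_phosphate"),
        crystallinity = tr("crystallinity"),
        acid_phosphate = tr("acid_phosphate"),
        NE_xLR = tr("NE_xLR"),
        collagen_maturity = tr("collagen_maturity"))
      sp <- forward_ftir(bands, noise = nz$ftir)
      f <- file.path(out_dir, sprintf("%s_ftir.txt", id))
      write_spectrum(sp, f)
      tab$ftir_file[a] <- f
    }
    if ("xrd" %in% mods) {
      sp <- forward_xrd(length_nm = tr("crystallite_length_nm"),
                        width_nm = tr("crystallite_width_nm"),
                        noise = nz$xrd)
      f <- file.path(out_dir, sprintf("%s_xrd.txt", id))
      write_spectrum(sp, f)
      tab$xrd_file[a] <- f
    }
    if ("fage" %in% mods) {
      plates <- forward_plate(true_fage = tr("fage_ng_mg"),
                              collagen_mg = 12, bone_mg = 50,
                              noise = nz$plate, sample_id = id)
      f1 <- file.path(out_dir, sprintf("%s_fage_fluor.csv", id))
      f2 <- file.path(out_dir, sprintf("%s_fage_abs.csv", id))
      write_plate(plates$fluorescence, f1)
      write_plate(plates$absorbance, f2)
      tab$fage_fluor_file[a] <- f1
      tab$fage_abs_file[a] <- f2
    }
    if ("microct" %in% mods) {
      cort <- forward_volume("cortical", voxel_um = config$cortical_voxel_um,
                             ct_ar_mm2 = tr("ct_ar_mm2"),
                             ct_th_mm = tr("ct_th_mm"),
                             height_mm = config$cortical_height_mm,
                             noise = nz$volume)
      f1 <- file.path(out_dir, sprintf("%s_cortical.vox", id))
      write_volume(cort, f1)
      trab <- forward_volume("trabecular",
                             voxel_um = config$trabecular_voxel_um,
                             edge_mm = config$trabecular_edge_mm,
                             bvtv_pct = tr("bvtv_pct"),
                             tb_th_mm = tr("tb_th_mm"),
                             noise = nz$volume)
      f2 <- file.path(out_dir, sprintf("%s_trabecular.vox", id))
      write_volume(trab, f2)
      tab$cortical_file[a] <- f1
      tab$trabecular_file[a] <- f2
    }
  }
  write.csv(tab, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  tab
}
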