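# Orchestration: generate -> analyze -> compare -> report.

#' Study configuration
#'
#' @param cohort a [cohort_config()].
#' @param out_dir output directory for artifacts and reports.
#' @param compare_parameters parameters to tabulate; defaults to every
#'   parameter measured by the enabled modalities plus the metabolic
#'   covariates.
#' @param outlier_k SD multiple for the per-parameter outlier screen.
#' @param alpha significance level.
#' @return list of class `study_config`.
#' @export
study_config <- function(cohort = cohort_config(), out_dir = tempfile("study"),
                         compare_parameters = NULL, outlier_k = 2,
                         alpha = 0.05) {
  structure(list(cohort = cohort, out_dir = out_dir,
                 compare_parameters = compare_parameters,
                 outlier_k = outlier_k, alpha = alpha),
            class = "study_config")
}

# analyze every artifact of one animal; returns a named list of measured
# parameters (NA + warning on stage failure)
analyze_animal <- function(row, config) {
  out <- list()
  try_stage <- function(name, expr) {
    v <- tryCatch(expr, error = function(e) {
      warning(sprintf("%s failed for %s: %s", name, row$id,
                      conditionMessage(e)))
      NULL
    })
    v
  }
  if (!is.null(row$bending_file) && !is.na(row$bending_file)) {
    b <- try_stage("bending", analyze_bending(read_trace(row$bending_file)))
    out$F_max_N <- b$F_max %||% NA_real_
    out$stiffness_N_mm <- b$stiffness %||% NA_real_
    out$work_N_mm <- b$work_to_failure %||% NA_real_
    out$PYD_mm <- b$PYD %||% NA_real_
  }
  if (!is.null(row$rpi_files) && !is.na(row$rpi_files)) {
    r <- try_stage("rpi", {
      sites <- lapply(strsplit(row$rpi_files, ";")[[1]], function(f) {
        rec <- read_rpi(f)
        segment_cycles(rec$force, rec$depth)
      })
      analyze_rpi(sites)
    })
    out$ID_1st_um <- r$ID_1st %||% NA_real_
    out$TID_um <- r$TID %||% NA_real_
    out$IDI_um <- r$IDI %||% NA_real_
    out$US_1st_N_um <- r$US_1st %||% NA_real_
    out$Avg_ED_uJ <- r$Avg_ED %||% NA_real_
  }
  if (!is.null(row$nano_files) && !is.na(row$nano_files)) {
    nn <- try_stage("nano", {
      res <- lapply(strsplit(row$nano_files, ";")[[1]], function(f)
        analyze_nanoindentation(read_nano(f)))
      list(Er = mean(vapply(res, `[[`, 0, "Er")),
           H = mean(vapply(res, `[[`, 0, "H")))
    })
    out$Er_GPa <- nn$Er %||% NA_real_
    out$H_GPa <- nn$H %||% NA_real_
  }
  if (!is.null(row$ftir_file) && !is.na(row$ftir_file)) {
    ft <- try_stage("ftir", compute_ftir_params(read_spectrum(row$ftir_file)))
    out$mineral_to_matrix <- ft$mineral_to_matrix %||% NA_real_
    out$carbonate_to_phosphate <- ft$carbonate_to_phosphate %||% NA_real_
    out$crystallinity <- ft$crystallinity %||% NA_real_
    out$acid_phosphate <- ft$acid_phosphate %||% NA_real_
    out$NE_xLR <- ft$NE_xLR %||% NA_real_
    out$collagen_maturity <- ft$collagen_maturity %||% NA_real_
  }
  if (!is.null(row$xrd_file) && !is.na(row$xrd_file)) {
    xr <- try_stage("xrd", analyze_xrd(read_spectrum(row$xrd_file)))
    out$crystallite_length_nm <- xr$length_nm %||% NA_real_
    out$crystallite_width_nm <- xr$width_nm %||% NA_real_
  }
  if (!is.null(row$fage_fluor_file) && !is.na(row$fage_fluor_file)) {
    fg <- try_stage("fage", analyze_fage(list(
      fluorescence = read_plate(row$fage_fluor_file),
      absorbance = read_plate(row$fage_abs_file))))
    out$fage_ng_mg <- fg$fage %||% NA_real_
  }
  if (!is.null(row$cortical_file) && !is.na(row$cortical_file)) {
    cm <- try_stage("microct", cortical_morphometry(
      read_volume(row$cortical_file)))
    out$ct_ar_mm2 <- cm$ct_ar_mm2 %||% NA_real_
    out$ct_th_mm <- cm$ct_th_mm %||% NA_real_
    out$j_mm4 <- cm$j_mm4 %||% NA_real_
  }
  if (!is.null(row$trabecular_file) && !is.na(row$trabecular_file)) {
    tm <- try_stage("microct", trabecular_morphometry(
      read_volume(row$trabecular_file)))
    out$bvtv_pct <- tm$bvtv_pct %||% NA_real_
    out$tb_th_mm <- tm$tb_th_mm %||% NA_real_
    out$tb_sp_mm <- tm$tb_sp_mm %||% NA_real_
    out$tb_n_per_mm <- tm$tb_n_per_mm %||% NA_real_
  }
  out
}

#' Run the full synthetic study
#'
#' Generates the cohort, analyzes every artifact back from disk, applies the
#' per-parameter 2-SD outlier screen, builds the group-comparison table
#' (mean +/- SD, selected test, p, signed percent difference), computes the
#' glycation correlations and the forward stepwise regression of PYD on the
#' glycation measures within the T2D group, and writes per-stage CSV/JSON
#' artifacts plus a consolidated report.
#'
#' @param config a [study_config()].
#' @return list of class `study_report`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  out_dir <- config$out_dir
  t0 <- Sys.time()
  cohort <- generate_cohort(config$cohort, file.path(out_dir, "raw"))
  measured <- lapply(seq_len(nrow(cohort)), function(i)
    analyze_animal(cohort[i, , drop = FALSE], config))
  pars <- unique(unlist(lapply(measured, names)))
  mtab <- data.frame(id = cohort$id, group = cohort$group)
  for (p in pars)
    mtab[[p]] <- vapply(measured, function(m) m[[p]] %||% NA_real_,
                        numeric(1))
  write.csv(mtab, file.path(out_dir, "measured_parameters.csv"),
            row.names = FALSE)

  use_pars <- config$compare_parameters %||% pars
  rows <- list(); n_failed <- 0L
  for (p in use_pars) {
    res <- tryCatch({
      a <- mtab[[p]][mtab$group == "control"]
      b <- mtab[[p]][mtab$group == "T2D"]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      ra <- remove_outliers(a, k = config$outlier_k)
      rb <- remove_outliers(b, k = config$outlier_k)
      cmp <- compare_groups(ra$values, rb$values, alpha = config$alpha)
      data.frame(parameter = p,
                 control_mean = cmp$mean_a, control_sd = cmp$sd_a,
                 t2d_mean = cmp$mean_b, t2d_sd = cmp$sd_b,
                 n_control = cmp$n_a, n_t2d = cmp$n_b,
                 test = cmp$test, p_value = cmp$p,
                 percent_difference = cmp$percent_difference,
                 stars = cmp$stars,
                 n_outliers_removed = length(ra$removed) + length(rb$removed))
    }, error = function(e) {
      warning("comparison failed for ", p, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) n_failed <- n_failed + 1L else rows <- c(rows, list(res))
  }
  comparison <- do.call(rbind, rows)
  write.csv(comparison, file.path(out_dir, "comparison_table.csv"),
            row.names = FALSE)

  # glycation correlations and stepwise regression within the T2D group
  t2d <- mtab[mtab$group == "T2D", ]
  correlations <- NULL
  stepwise <- NULL
  if (all(c("NE_xLR", "PYD_mm") %in% names(t2d))) {
    correlations <- tryCatch({
      pr <- pearson_r(t2d$NE_xLR, t2d$PYD_mm)
      data.frame(x = "NE_xLR", y = "PYD_mm", r = pr$r, r2 = r_squared(pr$r),
                 p = pr$p, n = pr$n, group = "T2D")
    }, error = function(e) NULL)
    cand <- t2d[intersect(c("fage_ng_mg", "NE_xLR"), names(t2d))]
    if (ncol(cand) >= 1L)
      stepwise <- tryCatch(
        forward_stepwise(t2d$PYD_mm, cand, alpha_enter = config$alpha),
        error = function(e) NULL)
  }

  report <- structure(list(
    comparison = comparison,
    correlations = correlations,
    stepwise = stepwise,
    measured = mtab,
    cohort = cohort,
    provenance = list(seed = config$cohort$seed,
                      n_per_group = config$cohort$n_per_group,
                      modalities = config$cohort$modalities,
                      config_hash = config_hash(unclass(config)),
                      package_version =
                        as.character(utils::packageVersion("osteoquant")),
                      elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs"))),
    n_failed = n_failed), class = "study_report")
  jsonlite::write_json(
    list(comparison = comparison, correlations = correlations,
         stepwise = if (!is.null(stepwise))
           list(entered = stepwise$entered, r2 = stepwise$r2,
                entry_p = as.list(stepwise$entry_p)) else NULL,
         provenance = report$provenance[c("seed", "n_per_group",
                                          "config_hash")]),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    null = "null", dataframe = "rows")
  if (n_failed > 0.2 * length(use_pars))
    stop("more than 20% of report cells missing (", n_failed, " of ",
         length(use_pars), ")")
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> seed %s, %d parameters compared (%d failed)\n",
              x$provenance$seed, nrow(x$comparison), x$n_failed))
  sig <- x$comparison[x$comparison$p_value < 0.05, ]
  if (nrow(sig)) {
    cat("significant group differences (control-referenced):\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("  %-24s %+7.1f%%  p = %.4g %s\n", sig$parameter[i],
                  sig$percent_difference[i], sig$p_value[i], sig$stars[i]))
  }
  if (!is.null(x$correlations))
    cat(sprintf("T2D r(NE-xLR, PYD) = %.3f (p = %.3g)\n",
                x$correlations$r[1], x$correlations$p[1]))
  if (!is.null(x$stepwise) && length(x$stepwise$entered))
    cat(sprintf("stepwise PYD ~ glycation: %s entered, R2 = %.3f\n",
                paste(x$stepwise$entered, collapse = " + "), x$stepwise$r2))
  invisible(x)
}
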