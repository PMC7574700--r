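# Synthetic cohort generation: defaults, determinism, latent moments.

test_that("default parameter table carries the study group summaries verbatim", {
  pt <- default_parameter_table()
  row <- function(p) pt[pt$parameter == p, ]
  # endpoint metabolic covariates
  expect_identical(unname(unlist(row("fasting_glucose_mg_dL")[2:5])),
                   c(97.9, 10.46, 292.5, 45.69))
  expect_identical(unname(unlist(row("body_weight_g")[2:5])),
                   c(252.8, 30.67, 247.8, 13.92))
  expect_identical(unname(unlist(row("hba1c_pct")[2:5])),
                   c(6.08, 0.39, 7.89, 0.52))
  expect_identical(unname(unlist(row("plasma_insulin_mIU_L")[2:5])),
                   c(2.82, 0.588, 2.216, 0.197))
  # micro-CT
  expect_identical(unname(unlist(row("bvtv_pct")[2:5])),
                   c(46.14, 2.10, 38.54, 6.05))
  expect_identical(unname(unlist(row("ct_th_mm")[2:5])),
                   c(0.70, 0.02, 0.61, 0.05))
  expect_identical(unname(unlist(row("ct_ar_mm2")[2:5])),
                   c(6.76, 0.28, 5.72, 0.85))
  expect_identical(unname(unlist(row("ct_tmd_mg_cc")[2:5])),
                   c(1594.7, 50, 1604.1, 114))
  # printed group means for nano, XRD, fAGE
  expect_identical(unname(unlist(row("Er_GPa")[2:5])),
                   c(20.6, 1.04, 16.22, 0.78))
  expect_identical(unname(unlist(row("H_GPa")[2:5])),
                   c(0.577, 0.039, 0.387, 0.039))
  expect_identical(unname(unlist(row("crystallite_length_nm")[2:5])),
                   c(18.29, 0.73, 16.67, 0.85))
  expect_identical(unname(unlist(row("crystallite_width_nm")[2:5])),
                   c(4.64, 0.11, 5.18, 0.19))
  expect_identical(unname(unlist(row("fage_ng_mg")[2:5])),
                   c(288.6, 33.5, 412.4, 36.6))
})

test_that("zero-variance configuration pins every latent to its group mean", {
  pt <- default_parameter_table()
  pt$ctrl_sd <- 0
  pt$t2d_sd <- 0
  cfg <- cohort_config(n_per_group = 2, seed = 5, parameter_table = pt)
  set.seed(cfg$seed)
  lat <- draw_latents(cfg)
  for (i in seq_len(nrow(pt))) {
    col <- paste0("true_", pt$parameter[i])
    expect_equal(lat[[col]][lat$group == "control"], rep(pt$ctrl_mean[i], 2))
    expect_equal(lat[[col]][lat$group == "T2D"], rep(pt$t2d_mean[i], 2))
  }
})

test_that("same config and seed give byte-identical cohort tables", {
  cfg <- cohort_config(n_per_group = 2, seed = 42,
                       modalities = c("bending", "xrd"))
  dir <- file.path(tempdir(), "det_cohort")
  generate_cohort(cfg, dir)
  first <- readBin(file.path(dir, "cohort.csv"), "raw",
                   file.size(file.path(dir, "cohort.csv")))
  trace1 <- readBin(file.path(dir, "C01_bending.csv"), "raw",
                    file.size(file.path(dir, "C01_bending.csv")))
  generate_cohort(cfg, dir)
  second <- readBin(file.path(dir, "cohort.csv"), "raw",
                    file.size(file.path(dir, "cohort.csv")))
  trace2 <- readBin(file.path(dir, "C01_bending.csv"), "raw",
                    file.size(file.path(dir, "C01_bending.csv")))
  expect_identical(first, second)
  expect_identical(trace1, trace2)
  unlink(dir, recursive = TRUE)
})

test_that("latent sample moments converge to the configured values as n grows", {
  cfg <- cohort_config(n_per_group = 2000, seed = 123)
  set.seed(cfg$seed)
  lat <- draw_latents(cfg)
  pt <- cfg$parameter_table
  for (p in c("fasting_glucose_mg_dL", "Er_GPa", "NE_xLR", "PYD_mm",
              "fage_ng_mg", "ct_th_mm")) {
    r <- pt[pt$parameter == p, ]
    x <- lat[[paste0("true_", p)]]
    expect_equal(mean(x[lat$group == "control"]), r$ctrl_mean,
                 tolerance = 0.05)
    expect_equal(sd(x[lat$group == "control"]), r$ctrl_sd, tolerance = 0.05)
    expect_equal(mean(x[lat$group == "T2D"]), r$t2d_mean, tolerance = 0.05)
    expect_equal(sd(x[lat$group == "T2D"]), r$t2d_sd, tolerance = 0.05)
  }
})

test_that("the glycation factor induces r(NE-xLR, PYD) near -0.697 in the T2D group only", {
  cfg <- cohort_config(n_per_group = 500, seed = 77)
  set.seed(cfg$seed)
  lat <- draw_latents(cfg)
  t2d <- lat[lat$group == "T2D", ]
  ctl <- lat[lat$group == "control", ]
  r_t2d <- pearson_r(t2d$true_NE_xLR, t2d$true_PYD_mm)$r
  r_ctl <- pearson_r(ctl$true_NE_xLR, ctl$true_PYD_mm)$r
  expect_equal(r_t2d, -0.697, tolerance = 0.05)
  expect_lt(abs(r_ctl), 0.12)
})

test_that("glucose group means land near the study values at n = 10", {
  cfg <- cohort_config(n_per_group = 10, seed = 1,
                       modalities = character(0))
  dir <- file.path(tempdir(), "glucose_cohort")
  tab <- generate_cohort(cfg, dir)
  expect_equal(nrow(tab), 20)
  g_ctl <- mean(tab$true_fasting_glucose_mg_dL[tab$group == "control"])
  g_t2d <- mean(tab$true_fasting_glucose_mg_dL[tab$group == "T2D"])
  expect_equal(g_ctl, 97.9, tolerance = 0.12)
  expect_equal(g_t2d, 292.5, tolerance = 0.12)
  unlink(dir, recursive = TRUE)
})

test_that("strictly positive latents are redrawn above zero", {
  pt <- default_parameter_table()
  cfg <- cohort_config(n_per_group = 50, seed = 8, parameter_table = pt)
  set.seed(cfg$seed)
  lat <- draw_latents(cfg)
  # Tb.TMD has a huge configured SD (739 +/- 343): truncation must bite
  expect_true(all(lat$true_tb_tmd_mg_cc > 0))
  expect_true(all(lat$true_PYD_mm > 0))
})
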