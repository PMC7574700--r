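# Density calibration and voxel morphometry.

test_that("two-point density calibration is exact", {
  id <- calibrate_density(c(200, 800))
  expect_equal(apply_calibration(id, c(200, 800)), c(200, 800))
  cal <- calibrate_density(c(1000, 4000))
  expect_equal(cal$slope, 0.2)
  expect_equal(cal$intercept, 0)
  expect_error(calibrate_density(c(500, 500)), "distinct")
})

test_that("constant calibrated density gives TMD equal to that density", {
  cal <- calibrate_density(c(1000, 4000))
  v <- forward_volume("cortical", outer_radius_mm = 0.8,
                      inner_radius_mm = 0.4, voxel_um = 40, height_mm = 0.2,
                      gray = TRUE, tissue_density_mg_cc = 1594.7,
                      calibration = cal)
  expect_equal(tissue_mineral_density(v, cal), 1594.7, tolerance = 1e-9)
})

test_that("voxelized annulus matches the closed-form section properties within 2%", {
  v <- forward_volume("cortical", outer_radius_mm = 1.0,
                      inner_radius_mm = 0.5, voxel_um = 20, height_mm = 0.2)
  o <- oracle_annulus(1.0, 0.5)
  m <- cortical_morphometry(v)
  expect_equal(m$ct_ar_mm2, o$area, tolerance = 0.02)
  expect_equal(m$ct_th_mm, o$thickness, tolerance = 0.02)
  expect_equal(m$j_mm4, o$j, tolerance = 0.02)
})

test_that("scaling the annulus by 2 scales Ct.Ar by 4 and J by 16", {
  m1 <- cortical_morphometry(forward_volume("cortical", outer_radius_mm = 0.6,
                                            inner_radius_mm = 0.3,
                                            voxel_um = 20, height_mm = 0.1))
  m2 <- cortical_morphometry(forward_volume("cortical", outer_radius_mm = 1.2,
                                            inner_radius_mm = 0.6,
                                            voxel_um = 20, height_mm = 0.1))
  expect_equal(m2$ct_ar_mm2 / m1$ct_ar_mm2, 4, tolerance = 0.02)
  expect_equal(m2$j_mm4 / m1$j_mm4, 16, tolerance = 0.03)
})

test_that("J agrees with a brute-force voxel summation on a perturbed annulus", {
  set.seed(11)
  v <- forward_volume("cortical", outer_radius_mm = 0.9,
                      inner_radius_mm = 0.45, voxel_um = 30, height_mm = 0.09)
  m <- volume_mask(v)
  # random perturbation: knock out a few voxels
  sl <- m[, , 1]
  fg <- which(sl)
  sl[sample(fg, 40)] <- FALSE
  for (z in seq_len(dim(m)[3])) m[, , z] <- sl
  v2 <- voxel_volume(array(as.numeric(m), dim(m)), v$voxel_um)
  res <- cortical_morphometry(v2)
  expect_equal(res$j_mm4, oracle_j_voxels(sl, 0.03), tolerance = 1e-9)
})

test_that("J about the centroid is the minimum over candidate axes", {
  v <- forward_volume("cortical", outer_radius_mm = 0.8,
                      inner_radius_mm = 0.4, voxel_um = 40, height_mm = 0.08)
  sl <- volume_mask(v)[, , 1]
  vox <- 0.04
  idx <- which(sl, arr.ind = TRUE)
  xs <- idx[, 1] * vox; ys <- idx[, 2] * vox
  j0 <- sum((xs - mean(xs))^2 + (ys - mean(ys))^2) * vox^2
  for (dx in c(-0.1, 0.07)) for (dy in c(-0.05, 0.12)) {
    js <- sum((xs - mean(xs) - dx)^2 + (ys - mean(ys) - dy)^2) * vox^2
    expect_gt(js, j0)
  }
  expect_equal(cortical_morphometry(v)$j_mm4, j0, tolerance = 1e-9)
})

test_that("cortical results are invariant to translation and 90-degree rotation", {
  v <- forward_volume("cortical", outer_radius_mm = 0.7,
                      inner_radius_mm = 0.35, voxel_um = 35, height_mm = 0.07)
  m1 <- cortical_morphometry(v)
  a <- v$values
  pad <- array(0, dim(a) + c(6, 4, 0))
  pad[4 + seq_len(dim(a)[1]) - 1 + 1, 3 + seq_len(dim(a)[2]) - 1 + 1, ] <- a
  m2 <- cortical_morphometry(voxel_volume(pad, v$voxel_um))
  rot <- aperm(a, c(2, 1, 3))[, rev(seq_len(dim(a)[1])), , drop = FALSE]
  m3 <- cortical_morphometry(voxel_volume(rot, v$voxel_um))
  for (k in c("ct_ar_mm2", "ct_th_mm", "j_mm4")) {
    expect_equal(m2[[k]], m1[[k]], tolerance = 1e-9)
    expect_equal(m3[[k]], m1[[k]], tolerance = 1e-9)
  }
})

test_that("a solid cube has BV/TV 100% with undefined phase thicknesses", {
  v <- voxel_volume(array(1, c(10, 10, 10)), 20)
  m <- trabecular_morphometry(v)
  expect_equal(m$bvtv_pct, 100)
  expect_true(is.na(m$tb_th_mm))
})

test_that("parallel plates recover thickness, separation and BV/TV", {
  v <- forward_volume("trabecular", voxel_um = 20, edge_mm = 1.5,
                      bvtv_pct = 40, tb_th_mm = 0.10, phase = 0.25)
  m <- trabecular_morphometry(v)
  expect_equal(m$bvtv_pct, 40, tolerance = 0.02)
  # voxelization tolerance: one voxel on each thickness estimate
  expect_lt(abs(m$tb_th_mm - 0.10), 0.021)
  expect_lt(abs(m$tb_sp_mm - 0.15), 0.021)
  expect_equal(m$tb_n_per_mm, m$bvtv_pct / 100 / m$tb_th_mm, tolerance = 1e-12)
})

test_that("random-field BV/TV equals the voxel-count oracle", {
  set.seed(5)
  v <- forward_volume("trabecular", voxel_um = 25, edge_mm = 1.0,
                      bvtv_pct = 46.14, tb_th_mm = 0.095, method = "field")
  m <- trabecular_morphometry(v)
  mask <- volume_mask(v)
  expect_equal(m$bvtv_pct, 100 * sum(mask) / length(mask), tolerance = 1e-12)
  expect_equal(m$bvtv_pct, 46.14, tolerance = 0.01)
})

test_that("halving the voxel size drives the annulus metrics toward the closed forms", {
  o <- oracle_annulus(1.0, 0.5)
  errs <- sapply(c(40, 20, 10), function(vx) {
    m <- cortical_morphometry(forward_volume("cortical", outer_radius_mm = 1,
                                             inner_radius_mm = 0.5,
                                             voxel_um = vx,
                                             height_mm = 3 * vx / 1000))
    c(ar = abs(m$ct_ar_mm2 - o$area) / o$area,
      j = abs(m$j_mm4 - o$j) / o$j)
  })
  expect_true(all(diff(errs["ar", ]) < 1e-12 | errs["ar", -1] < 0.005))
  expect_true(all(errs[, 3] < errs[, 1] + 1e-12))
})
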