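# Independent oracles used across the suite. These deliberately reimplement
# the quantities with the most naive formulation available so they cannot
# share bugs with the package implementations.

# polygon area by direct shoelace loop
oracle_polygon_area <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + x[i] * y[j] - x[j] * y[i]
  }
  abs(s) / 2
}

# OLS slope/intercept from the normal equations, written out longhand
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

# exhaustive two-sided Mann-Whitney p-value: every labeling enumerated with
# combn, U recomputed by pairwise comparison counting (not ranks)
oracle_mwu_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  z <- c(x, y)
  ustat <- function(ix) {
    a <- z[ix]; b <- z[-ix]
    u <- 0
    for (ai in a) for (bi in b)
      u <- u + (ai > bi) + 0.5 * (ai == bi)
    u
  }
  u_obs <- ustat(seq_len(n1))
  mu <- n1 * n2 / 2
  combs <- combn(n1 + n2, n1)
  devs <- apply(combs, 2, function(ix) abs(ustat(ix) - mu))
  mean(devs >= abs(u_obs - mu) - 1e-9)
}

# closed-form annulus section properties
oracle_annulus <- function(R, r) {
  list(area = pi * (R^2 - r^2), thickness = R - r, j = pi * (R^4 - r^4) / 2)
}

# brute-force polar moment over a binary slice about its centroid
oracle_j_voxels <- function(slice, vox_mm) {
  idx <- which(slice, arr.ind = TRUE)
  xs <- idx[, 1] * vox_mm; ys <- idx[, 2] * vox_mm
  sum((xs - mean(xs))^2 + (ys - mean(ys))^2) * vox_mm^2
}

# Scherrer inversion used as the closed-form FWHM oracle
oracle_fwhm_deg <- function(size_nm, two_theta_deg, lambda_nm = 0.15406) {
  lambda_nm / (size_nm * cos(two_theta_deg / 2 * pi / 180)) * 180 / pi
}

# trapezoid integral, index loop
oracle_trapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1))
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  s
}
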