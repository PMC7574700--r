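# Tissue-level indentation: cyclic reference-point indentation (cRPI) and
# Oliver-Pharr nanoindentation.

#' Split a continuous cRPI force record into indentation cycles
#'
#' Splits the interleaved force/depth record at the force minima between
#' successive force peaks and returns the detected cycles in temporal order.
#'
#' @param force force record, N.
#' @param depth depth record, um.
#' @param n_expected expected number of cycles (default 10); a differing
#'   detected count raises a warning, not an error.
#' @param F_target nominal peak force, N.
#' @param frequency cycling frequency, Hz.
#' @param site_id site identifier.
#' @param min_peak_frac a peak must exceed this fraction of the overall
#'   maximum force to count as a cycle peak.
#' @return An [cycle_set()] with the detected cycles.
#' @export
segment_cycles <- function(force, depth, n_expected = 10, F_target = 8,
                           frequency = 2, site_id = "site1",
                           min_peak_frac = 0.5) {
  stopifnot(length(force) == length(depth))
  n <- length(force)
  thr <- min_peak_frac * max(force)
  # peaks: local maxima above threshold (plateaus take the first sample)
  is_pk <- c(FALSE, diff(force) > 0) & c(force[-n] >= force[-1], TRUE) &
    force >= thr
  pk <- which(is_pk)
  # collapse runs of near-adjacent peak candidates
  if (length(pk) > 1L) pk <- pk[c(TRUE, diff(pk) > 2L)]
  if (length(pk) < 2L) stop("fewer than 2 cycles detected")
  # split at the force minimum between consecutive peaks
  splits <- integer(length(pk) - 1L)
  for (i in seq_len(length(pk) - 1L)) {
    seg <- pk[i]:pk[i + 1L]
    splits[i] <- seg[which.min(force[seg])]
  }
  bounds <- c(1L, splits, n)
  cycles <- vector("list", length(pk))
  for (i in seq_along(pk)) {
    idx <- bounds[i]:bounds[i + 1L]
    cycles[[i]] <- data.frame(force_N = force[idx], depth_um = depth[idx])
  }
  if (length(cycles) != n_expected)
    warning(sprintf("detected %d cycles, expected %d; proceeding with %d",
                    length(cycles), n_expected, length(cycles)))
  cycle_set(cycles, F_target = F_target, frequency = frequency,
            site_id = site_id)
}

#' Analyze cyclic reference-point indentation cycle sets
#'
#' Per site: `ID_1st` is the depth at peak force of the first cycle, `TID`
#' the depth at peak force of the last cycle, `IDI = TID - ID_1st`, `US_1st`
#' the linear-fit slope of the upper portion of the first cycle's unloading
#' branch, and the per-cycle energy dissipation the orientation-corrected
#' polygon (shoelace) area of the force-depth loop, averaged into `Avg_ED`.
#' Results are unweighted means over sites.
#'
#' @param sites a [cycle_set()] or list of them (one per indent site).
#' @param unload_fit_range fraction of peak force delimiting the unloading
#'   branch used for the US-1st fit (default 40-95 percent).
#' @param exclude_first_ed exclude the first cycle from `Avg_ED`?
#' @return list of class `rpi_result`: `ID_1st`, `TID`, `IDI` (um),
#'   `US_1st` (N/um), `Avg_ED` (uJ), `n_sites`, per-site table, `flags`.
#' @export
analyze_rpi <- function(sites, unload_fit_range = c(0.40, 0.95),
                        exclude_first_ed = FALSE) {
  if (inherits(sites, "cycle_set")) sites <- list(sites)
  if (!length(sites)) stop("need at least one indent site")
  flags <- character(0)
  per_site <- lapply(sites, function(cs) {
    cyc <- cs$cycles
    peak_depth <- function(cy) cy$depth_um[which.max(cy$force_N)]
    id1 <- peak_depth(cyc[[1L]])
    tid <- peak_depth(cyc[[length(cyc)]])
    # US-1st: upper unloading branch of cycle 1
    cy1 <- cyc[[1L]]
    ip <- which.max(cy1$force_N)
    unld <- cy1[ip:nrow(cy1), ]
    fmax <- cy1$force_N[ip]
    sel <- unld$force_N >= unload_fit_range[1] * fmax &
      unld$force_N <= unload_fit_range[2] * fmax
    if (sum(sel) < 2L) stop("too few samples on the unloading branch")
    fit <- linfit(unld$depth_um[sel], unld$force_N[sel])
    # per-cycle hysteresis: shoelace area, orientation-corrected
    eds <- vapply(cyc, function(cy) {
      x <- cy$depth_um; y <- cy$force_N
      abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
    }, numeric(1))
    last <- cyc[[length(cyc)]]
    if (abs(last$force_N[1] - last$force_N[nrow(last)]) >
        0.05 * max(last$force_N))
      flags <<- c(flags, "non_closed_final_cycle")
    ed_use <- if (exclude_first_ed) eds[-1L] else eds
    c(ID_1st = id1, TID = tid, IDI = tid - id1, US_1st = fit$slope,
      Avg_ED = mean(ed_use))
  })
  tab <- do.call(rbind, per_site)
  means <- colMeans(tab)
  structure(c(as.list(means),
              list(n_sites = length(sites), per_site = as.data.frame(tab),
                   flags = unique(flags))),
            class = "rpi_result")
}

#' @export
print.rpi_result <- function(x, ...) {
  cat(sprintf(paste0("<rpi_result> %d site(s): ID-1st %.2f um, TID %.2f um, ",
                     "IDI %.2f um, US-1st %.4f N/um, Avg-ED %.2f uJ\n"),
              x$n_sites, x$ID_1st, x$TID, x$IDI, x$US_1st, x$Avg_ED))
  invisible(x)
}

#' Oliver-Pharr analysis of a nanoindentation load-depth curve
#'
#' Fits the power law `P = alpha (h - h_f)^m` to the stated fraction of the
#' unloading branch, evaluates the contact stiffness `S = dP/dh` at `h_max`,
#' and derives contact depth `h_c = h_max - epsilon P_max / S`, contact area
#' `A = area_coeff h_c^2`, hardness `H = P_max / A` and reduced modulus
#' `Er = (sqrt(pi)/2) S / sqrt(A)`.
#'
#' @param curve a [nano_curve()] or data frame with `load_uN`, `depth_nm`,
#'   `segment`.
#' @param epsilon Oliver-Pharr geometry constant (0.75, Berkovich).
#' @param unload_fit_range force fractions of `P_max` delimiting the fitted
#'   part of the unloading branch.
#' @param area_coeff ideal-tip area coefficient (24.5 for a perfect
#'   Berkovich); a polynomial area function can be supplied instead as a
#'   function `A(h_c)`.
#' @param beta geometry correction on S (1 = none).
#' @return list of class `nano_result`: `Er`, `H` (GPa), `S` (uN/nm), `h_c`,
#'   `h_max`, `h_f` (nm), `A` (nm^2), `m`, `r2`.
#' @export
analyze_nanoindentation <- function(curve, epsilon = 0.75,
                                    unload_fit_range = c(0.40, 0.95),
                                    area_coeff = 24.5, beta = 1) {
  seg <- curve$segment
  unld <- curve[seg == "unload", ]
  if (!nrow(unld)) stop("curve has no unloading segment")
  P_max <- max(curve$load_uN)
  h_max <- max(unld$depth_nm)
  sel <- unld$load_uN >= unload_fit_range[1] * P_max &
    unld$load_uN <= unload_fit_range[2] * P_max
  if (sum(sel) < 10L) stop("need at least 10 samples in the unload fit range")
  h <- unld$depth_nm[sel]
  p <- unld$load_uN[sel]

  # profile alpha out: given (h_f, m), alpha is the LS scale of (h - h_f)^m
  sse <- function(par) {
    hf <- par[1]; m <- par[2]
    x <- (h - hf)
    if (any(x <= 0)) return(1e30)
    xm <- x^m
    alpha <- sum(p * xm) / sum(xm * xm)
    sum((p - alpha * xm)^2)
  }
  sse_grad <- function(par) {
    hf <- par[1]; m <- par[2]
    x <- (h - hf)
    if (any(x <= 0)) return(c(0, 0))
    xm <- x^m
    alpha <- sum(p * xm) / sum(xm * xm)
    r <- alpha * xm - p
    # envelope theorem: alpha is at its conditional optimum
    c(-sum(2 * r * alpha * m * x^(m - 1)),
      sum(2 * r * alpha * xm * log(x)))
  }
  # initial h_f from a linear extrapolation of the top of the branch
  top <- unld$load_uN >= 0.8 * P_max
  ftop <- linfit(unld$depth_nm[top], unld$load_uN[top])
  hf0 <- h_max - 1.5 * P_max / max(ftop$slope, 1e-9)
  hf0 <- min(max(hf0, 0), min(h) * 0.98)
  fit <- optim(c(hf0, 1.5), sse, sse_grad, method = "L-BFGS-B",
               lower = c(0, 1), upper = c(min(h) * 0.999999, 3),
               control = list(factr = 1, maxit = 1000))
  if (fit$convergence != 0 && fit$convergence != 52)
    stop("power-law unloading fit failed to converge: ", fit$message)
  hf <- fit$par[1]; m <- fit$par[2]
  if (m < 1 - 1e-8 || m > 3 + 1e-8)
    stop("unloading exponent m outside [1, 3]: ", signif(m, 4))
  xm <- (h - hf)^m
  alpha <- sum(p * xm) / sum(xm * xm)
  ss_tot <- sum((p - mean(p))^2)
  r2 <- if (ss_tot > 0) 1 - fit$value / ss_tot else 1
  S <- beta * alpha * m * (h_max - hf)^(m - 1)       # uN/nm
  h_c <- h_max - epsilon * P_max / S
  if (h_c <= 0) stop("non-positive contact depth; curve inconsistent")
  A <- if (is.function(area_coeff)) area_coeff(h_c) else area_coeff * h_c^2
  H <- P_max / A * 1000                               # GPa
  Er <- sqrt(pi) / 2 * S / sqrt(A) * 1000             # GPa
  structure(list(Er = Er, H = H, S = S, h_c = h_c, h_max = h_max, h_f = hf,
                 A = A, m = m, alpha = alpha, r2 = r2),
            class = "nano_result")
}

#' @export
print.nano_result <- function(x, ...) {
  cat(sprintf(paste0("<nano_result> Er %.2f GPa, H %.3f GPa ",
                     "(S %.3f uN/nm, h_c %.1f nm, m %.3f, R2 %.5f)\n"),
              x$Er, x$H, x$S, x$h_c, x$m, x$r2))
  invisible(x)
}
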