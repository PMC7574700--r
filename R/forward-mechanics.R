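# Forward models for the mechanical modalities. Each emits a raw-looking
# instrument record whose ground truth is attached as `truth`, so the
# analyzers can be validated by exact round-trips.

#' Forward-model a three-point bending load-displacement trace
#'
#' Builds a trace that is linear (slope `stiffness`) up to an internally
#' solved proportional limit and then follows an exponential-saturation
#' hardening arc. The arc is shaped so that the 0.2 percent offset
#' construction used by [analyze_bending()] recovers exactly the requested
#' yield point `(D_yield, F_yield)` with `D_yield = F_yield/stiffness +
#' offset_fraction * span`, and the trace terminates at
#' `D_fx = D_yield + PYD` where the load equals `F_max` (the global maximum
#' before the fracture drop).
#'
#' @param stiffness elastic slope, N/mm.
#' @param F_yield load at the offset yield point, N.
#' @param F_max maximum load before fracture, N. Requires
#'   `F_max - F_yield < stiffness * PYD` for a feasible hardening arc.
#' @param PYD post-yield displacement, mm (>= 0).
#' @param span support span, mm.
#' @param rate displacement rate, mm/min.
#' @param noise relative load-noise amplitude (sd as a fraction of `F_max`).
#' @param preload preload force, N.
#' @param offset_fraction offset used by the downstream yield construction.
#' @param fs sampling rate, Hz (instrument logs at 0.01 s intervals).
#' @return An [ld_trace()] whose `truth` attribute holds the closed-form
#'   `stiffness`, `F_max`, `F_yield`, `D_yield`, `D_fx`, `PYD` and
#'   `work_to_failure` implied by the constructed geometry.
#' @export
forward_bending <- function(stiffness, F_yield, F_max = F_yield, PYD = 0,
                            span = 19, rate = 10, noise = 0, preload = 10,
                            offset_fraction = 0.002, fs = 100) {
  stopifnot(stiffness > 0, F_yield > 0, F_yield <= F_max)
  if (PYD < 0) stop("PYD must be non-negative")
  k <- stiffness
  v <- rate / 60                      # mm/s
  step <- v / fs                      # mm per sample
  delta <- offset_fraction * span     # offset displacement, mm

  elastic <- (PYD == 0 && F_yield == F_max)
  if (!elastic && F_max - F_yield >= k * PYD) {
    warning("hardening arc infeasible (F_max - F_yield >= stiffness * PYD); ",
            "generating a purely elastic ramp to F_max")
    elastic <- TRUE
    F_yield <- F_max
    PYD <- 0
  }

  if (elastic) {
    D_fx <- F_max / k
    d <- seq(0, D_fx, by = step)
    if (tail(d, 1) < D_fx) d <- c(d, D_fx)
    f <- k * d
    truth <- list(stiffness = k, F_max = F_max, F_yield = F_max,
                  D_yield = D_fx, D_fx = D_fx, PYD = 0,
                  work_to_failure = F_max * D_fx / 2, proportional_limit = F_max)
  } else {
    D_y <- F_yield / k + delta
    D_fx <- D_y + PYD
    # Post-knee model: F(d) = F_sat - k*tau*exp(-(d - d_p)/tau), C1 at d_p,
    # F_sat = k*d_p + k*tau. Solve tau so that the deviation from the elastic
    # line reaches k*delta exactly at D_y, and F(D_fx) = F_max.
    s_y_of <- function(tau) {
      arg <- (F_max - F_yield) / (k * tau * (1 - exp(-PYD / tau)))
      if (arg >= 1 || arg <= 0) return(NA_real_)
      -tau * log(arg)
    }
    hfun <- function(tau) {
      s_y <- s_y_of(tau)
      if (is.na(s_y)) return(NA_real_)
      s_y - tau * (1 - exp(-s_y / tau)) - delta
    }
    # bracket the root on a log grid of tau
    taus <- exp(seq(log(delta * 1e-3), log((D_fx + delta) * 50), length.out = 400))
    hv <- vapply(taus, hfun, numeric(1))
    ok <- which(!is.na(hv))
    sgn <- sign(hv[ok])
    flip <- which(diff(sgn) != 0)
    if (!length(flip)) stop("could not solve bending arc shape; ",
                            "check stiffness/F_yield/F_max/PYD consistency")
    i <- ok[flip[1]]; j <- ok[flip[1] + 1]
    tau <- uniroot(hfun, c(taus[i], taus[j]), tol = 1e-12)$root
    s_y <- s_y_of(tau)
    d_p <- D_y - s_y
    if (d_p <= 0) stop("solved proportional limit is non-positive; ",
                       "parameters imply yielding from the origin")
    F_sat <- k * d_p + k * tau
    fcurve <- function(d) ifelse(d <= d_p, k * d,
                                 F_sat - k * tau * exp(-(d - d_p) / tau))
    d <- seq(0, D_fx, by = step)
    if (tail(d, 1) < D_fx - 1e-12) d <- c(d, D_fx)
    f <- fcurve(d)
    s_fx <- D_fx - d_p
    work <- k * d_p^2 / 2 + F_sat * s_fx - k * tau^2 * (1 - exp(-s_fx / tau))
    truth <- list(stiffness = k, F_max = F_max, F_yield = F_yield,
                  D_yield = D_y, D_fx = D_fx, PYD = PYD,
                  work_to_failure = work, proportional_limit = k * d_p,
                  tau = tau, F_sat = F_sat)
  }

  # fracture drop: one sample far below the 50%-of-Fmax detection level
  d <- c(d, tail(d, 1) + step)
  f <- c(f, 0.02 * F_max)
  if (noise > 0) f <- f + rnorm(length(f), 0, noise * F_max)
  ld_trace(time = d / v, load = f, displacement = d, span = span,
           preload = preload, rate = rate, truth = truth)
}

#' Forward-model a cyclic reference-point indentation record
#'
#' Generates `n_cycles` triangular force-depth cycles at `F_max` peak force.
#' The peak-force depth of cycle c is `first_depth + (c-1)*creep_per_cycle`,
#' the first-cycle unloading branch is linear with slope `unload_slope`, and
#' every cycle's hysteresis-loop area equals `loop_area` (the loading branch
#' start point is repositioned at zero force between cycles to decouple loop
#' area from creep).
#'
#' @param first_depth depth at peak force of cycle 1 (ID-1st), um.
#' @param creep_per_cycle per-cycle advance of the peak-force depth, um.
#' @param unload_slope unloading slope, N/um.
#' @param loop_area per-cycle hysteresis energy, uJ (N*um).
#' @param n_cycles number of cycles (default 10).
#' @param F_max peak force per cycle, N (default 8).
#' @param frequency cycling frequency, Hz.
#' @param noise relative force-noise amplitude.
#' @param fs sampling rate, Hz.
#' @return A list with the interleaved `force` (N) and `depth` (um) records,
#'   a `cycle` index vector, and `truth` (ID_1st, TID, IDI, US_1st, Avg_ED).
#' @export
forward_rpi <- function(first_depth, creep_per_cycle = 0, unload_slope = 0.55,
                        loop_area = 0, n_cycles = 10, F_max = 8,
                        frequency = 2, noise = 0, fs = 100) {
  if (n_cycles < 2) stop("need at least 2 cycles")
  if (creep_per_cycle < 0) stop("creep_per_cycle must be non-negative")
  if (loop_area < 0) stop("loop_area must be non-negative")
  stopifnot(unload_slope > 0)
  half_n <- max(5L, round(fs / frequency / 2))
  w <- loop_area * 2 / F_max          # horizontal loop width at zero force
  force <- depth <- time <- cycle <- numeric(0)
  t0 <- 0
  for (cc in seq_len(n_cycles)) {
    D_c <- first_depth + (cc - 1) * creep_per_cycle
    e_c <- D_c - F_max / unload_slope          # unload end depth
    s_c <- e_c - w                             # load start depth
    fr_up <- seq(0, F_max, length.out = half_n + 1L)
    fr_dn <- seq(F_max, 0, length.out = half_n + 1L)[-1L]
    d_up <- s_c + (D_c - s_c) * fr_up / F_max
    d_dn <- D_c + (e_c - D_c) * (F_max - fr_dn) / F_max
    f_cy <- c(fr_up, fr_dn)
    d_cy <- c(d_up, d_dn)
    tt <- t0 + seq_along(f_cy) / fs
    force <- c(force, f_cy); depth <- c(depth, d_cy); time <- c(time, tt)
    cycle <- c(cycle, rep(cc, length(f_cy)))
    t0 <- tail(tt, 1)
  }
  if (noise > 0) {
    force <- force + rnorm(length(force), 0, noise * F_max)
    force[force < 0] <- 0
  }
  TID <- first_depth + (n_cycles - 1) * creep_per_cycle
  list(force = force, depth = depth, time = time, cycle = cycle,
       F_target = F_max, frequency = frequency,
       truth = list(ID_1st = first_depth, TID = TID,
                    IDI = TID - first_depth, US_1st = unload_slope,
                    Avg_ED = loop_area))
}

#' Forward-model a self-consistent Oliver-Pharr nanoindentation curve
#'
#' Constructs a load-depth curve whose Oliver-Pharr analysis returns exactly
#' the requested reduced modulus and hardness: contact area `A = P_max / H`,
#' contact depth `h_c = sqrt(A / area_coeff)`, contact stiffness
#' `S = (2/sqrt(pi)) * Er * sqrt(A)`, maximum depth
#' `h_max = h_c + epsilon * P_max / S`, parabolic loading
#' `P = P_max (h/h_max)^2`, and power-law unloading `P = alpha (h - h_f)^m`
#' with `h_f = h_max - m * P_max / S`.
#'
#' @param Er reduced modulus, GPa.
#' @param H hardness, GPa.
#' @param P_max peak load, uN.
#' @param epsilon Oliver-Pharr geometry constant (0.75 for Berkovich).
#' @param m unloading power-law exponent.
#' @param area_coeff ideal-tip area coefficient (A = area_coeff * h_c^2).
#' @param n_seg samples per segment.
#' @param noise relative load-noise amplitude.
#' @return A [nano_curve()] with `truth` holding `Er`, `H`, `S` (uN/nm),
#'   `h_c`, `h_max`, `h_f` (nm) and `A` (nm^2).
#' @export
forward_nano <- function(Er, H, P_max = 1000, epsilon = 0.75, m = 1.5,
                         area_coeff = 24.5, n_seg = 200, noise = 0) {
  stopifnot(Er > 0, H > 0, P_max > 0)
  Er_u <- Er / 1000    # GPa -> uN/nm^2
  H_u <- H / 1000
  A <- P_max / H_u                       # nm^2
  h_c <- sqrt(A / area_coeff)            # nm
  S <- 2 / sqrt(pi) * Er_u * sqrt(A)     # uN/nm
  h_max <- h_c + epsilon * P_max / S
  h_f <- h_max - m * P_max / S
  if (h_f < 0)
    stop(sprintf(paste0("final unloading depth would be negative ",
                        "(h_f = %.1f nm): Er/H combination implies m*P_max/S ",
                        "> h_max"), h_f))
  alpha <- P_max / (h_max - h_f)^m
  h_load <- seq(0, h_max, length.out = n_seg)
  p_load <- P_max * (h_load / h_max)^2
  h_hold <- rep(h_max, max(2L, n_seg %/% 10L))
  p_hold <- rep(P_max, length(h_hold))
  h_unld <- seq(h_max, h_f, length.out = n_seg)
  p_unld <- alpha * (h_unld - h_f)^m
  load <- c(p_load, p_hold, p_unld)
  depth <- c(h_load, h_hold, h_unld)
  seg <- c(rep("load", n_seg), rep("hold", length(h_hold)),
           rep("unload", n_seg))
  if (noise > 0) {
    load <- load + rnorm(length(load), 0, noise * P_max)
    load[1] <- 0
  }
  nano_curve(load, depth, seg, P_max = P_max,
             truth = list(Er = Er, H = H, S = S, h_c = h_c, h_max = h_max,
                          h_f = h_f, A = A, m = m, alpha = alpha,
                          epsilon = epsilon, area_coeff = area_coeff))
}
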