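# Whole-bone mechanics: three-point bending trace analysis.

#' Analyze a three-point bending load-displacement trace
#'
#' Extracts the whole-bone mechanical parameters: maximum load before
#' fracture, stiffness (slope of the best linear region), work-to-failure
#' (trapezoidal area under the curve up to fracture), and the 0.2
#' percent-offset yield point with the resulting post-yield displacement
#' `PYD = D_fx - D_yield`.
#'
#' The linear region is the longest sliding window between the preload
#' crossing and 80 percent of `F_max` whose linear fit R^2 is within
#' rounding of the best achievable window (and at least `min_r2`); the
#' offset line is the fitted line displaced by `offset_fraction * span`
#' along the displacement axis, and the yield point is its first
#' intersection with the trace. The fracture point is the last sample
#' before the load drops below 50 percent of `F_max` (else the final
#' sample).
#'
#' @param trace an [ld_trace()] or data frame with columns `time_s`,
#'   `load_N`, `disp_mm`.
#' @param offset_fraction strain-equivalent offset; the offset displacement
#'   is `offset_fraction * span` (0.038 mm at the default 19 mm span).
#' @param span,preload protocol metadata; taken from the trace attributes
#'   when present.
#' @param min_points minimum number of samples in the linear-fit window.
#' @param min_r2 minimum acceptable R^2 for the linear region.
#' @return list of class `bending_result`: `F_max` (N), `stiffness` (N/mm),
#'   `work_to_failure` (N*mm), `D_yield`, `F_yield`, `D_fx`, `PYD` (mm),
#'   `r2_linear`, and `flags`.
#' @export
analyze_bending <- function(trace, offset_fraction = 0.002, span = NULL,
                            preload = NULL, min_points = 20L, min_r2 = 0.98) {
  span <- span %||% attr(trace, "span") %||% 19
  preload <- preload %||% attr(trace, "preload") %||% 10
  d <- trace$disp_mm
  f <- trace$load_N
  n <- length(f)
  if (n < 10L) stop("trace too short")
  flags <- character(0)

  # fracture point: last sample before the load falls below 50% of the
  # running maximum; F_max is the global maximum before fracture
  i_pk <- which.max(f)
  F_pk <- f[i_pk]
  post <- which(f[i_pk:n] < 0.5 * F_pk)
  i_fx <- if (length(post)) i_pk + post[1] - 2L else n
  F_max <- max(f[1:i_fx])
  D_fx <- d[i_fx]

  # linear-region search between preload crossing and 80% of F_max
  i_lo <- which(f >= preload)[1]
  if (is.na(i_lo)) stop("trace never reaches the preload")
  i_hi <- which(f[i_lo:i_fx] > 0.8 * F_max)[1]
  i_hi <- if (is.na(i_hi)) i_fx else i_lo + i_hi - 2L
  if (i_hi - i_lo + 1L < min_points)
    stop("no linear region found: fewer than min_points samples between ",
         "preload and 80% of F_max")
  win <- best_linear_window(d[i_lo:i_hi], f[i_lo:i_hi], min_points, min_r2)
  if (is.null(win))
    stop("no linear region found (R^2 of every candidate window < ", min_r2, ")")
  k <- win$slope
  a <- win$intercept

  # 0.2% offset yield: first intersection of the trace with the fitted line
  # displaced by offset_fraction * span along the displacement axis
  delta <- offset_fraction * span
  gdev <- f - (a + k * (d - delta))
  # search beyond the start of the linear window
  i0 <- i_lo + win$start - 1L
  cross <- which(gdev[i0:i_fx] <= 0)
  if (length(cross)) {
    j <- i0 + cross[1] - 1L
    if (j == 1L) {
      D_yield <- d[j]; F_yield <- f[j]
    } else {
      # linear interpolation of the crossing
      w <- gdev[j - 1L] / (gdev[j - 1L] - gdev[j])
      D_yield <- d[j - 1L] + w * (d[j] - d[j - 1L])
      F_yield <- f[j - 1L] + w * (f[j] - f[j - 1L])
    }
  } else {
    D_yield <- D_fx
    F_yield <- f[i_fx]
    flags <- c(flags, "no_offset_intersection")
  }
  PYD <- D_fx - D_yield

  work <- trapz(d[1:i_fx], f[1:i_fx])

  structure(list(F_max = F_max, stiffness = k, work_to_failure = work,
                 D_yield = D_yield, F_yield = F_yield, D_fx = D_fx,
                 PYD = PYD, r2_linear = win$r2, intercept = a,
                 flags = flags),
            class = "bending_result")
}

#' @export
print.bending_result <- function(x, ...) {
  cat(sprintf(paste0("<bending_result> F_max %.2f N, stiffness %.1f N/mm, ",
                     "work %.2f N*mm, PYD %.4f mm%s\n"),
              x$F_max, x$stiffness, x$work_to_failure, x$PYD,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}

# Longest sliding window whose R^2 is indistinguishable from the best
# achievable; all windows of all lengths are scored via cumulative sums.
best_linear_window <- function(x, y, min_points, min_r2) {
  n <- length(x)
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x * x); cyy <- cumsum(y * y); cxy <- cumsum(x * y)
  seg <- function(c, i, j) c[j] - if (i > 1L) c[i - 1L] else 0
  best <- NULL; best_r2 <- -Inf
  stats_for <- function(i, j) {
    m <- j - i + 1L
    sx <- seg(cx, i, j); sy <- seg(cy, i, j)
    sxx <- seg(cxx, i, j) - sx^2 / m
    syy <- seg(cyy, i, j) - sy^2 / m
    sxy <- seg(cxy, i, j) - sx * sy / m
    if (sxx <= 0 || syy <= 0) return(NULL)
    r2 <- (sxy * sxy) / (sxx * syy)
    list(r2 = r2, slope = sxy / sxx,
         intercept = sy / m - sxy / sxx * sx / m)
  }
  # pass 1: best achievable R^2 over all windows (vectorised per length)
  lens <- unique(pmin(n, pmax(min_points, round(exp(seq(log(min_points),
                                                        log(n), length.out = 40))))))
  all_lens <- sort(unique(c(lens, min_points:min(n, min_points + 5L), n)))
  r2max <- -Inf
  for (L in all_lens) {
    i <- seq_len(n - L + 1L); j <- i + L - 1L
    m <- L
    sx <- cx[j] - c(0, cx)[i]; sy <- cy[j] - c(0, cy)[i]
    sxx <- (cxx[j] - c(0, cxx)[i]) - sx^2 / m
    syy <- (cyy[j] - c(0, cyy)[i]) - sy^2 / m
    sxy <- (cxy[j] - c(0, cxy)[i]) - sx * sy / m
    ok <- sxx > 0 & syy > 0
    if (!any(ok)) next
    r2 <- rep(-Inf, length(i))
    r2[ok] <- (sxy[ok]^2) / (sxx[ok] * syy[ok])
    r2max <- max(r2max, max(r2))
  }
  if (!is.finite(r2max) || r2max < min_r2) return(NULL)
  # keep threshold: within 4x of the best window's misfit, floored at min_r2
  # (epsilon guards the exactly-linear case where r2max == 1)
  keep <- max(min_r2, min(1 - 4 * (1 - r2max), 1 - 1e-10))
  # pass 2: longest window meeting the keep threshold (scan lengths downward)
  for (L in rev(seq(min_points, n))) {
    i <- seq_len(n - L + 1L); j <- i + L - 1L
    m <- L
    sx <- cx[j] - c(0, cx)[i]; sy <- cy[j] - c(0, cy)[i]
    sxx <- (cxx[j] - c(0, cxx)[i]) - sx^2 / m
    syy <- (cyy[j] - c(0, cyy)[i]) - sy^2 / m
    sxy <- (cxy[j] - c(0, cxy)[i]) - sx * sy / m
    ok <- sxx > 0 & syy > 0
    if (!any(ok)) next
    r2 <- rep(-Inf, length(i))
    r2[ok] <- (sxy[ok]^2) / (sxx[ok] * syy[ok])
    ib <- which.max(r2)
    if (r2[ib] >= keep) {
      s <- stats_for(i[ib], j[ib])
      return(list(start = i[ib], end = j[ib], slope = s$slope,
                  intercept = s$intercept, r2 = s$r2))
    }
  }
  NULL
}
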