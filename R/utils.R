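# Small shared numerics. Kept internal.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoidal integral of y over x
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Gaussian profile with unit-area parameterisation
#'
#' area * dnorm-like profile; `sigma` is the standard deviation, the FWHM is
#' 2*sqrt(2*log(2))*sigma.
#' @noRd
gauss <- function(x, center, sigma, area) {
  area / (sigma * sqrt(2 * pi)) * exp(-0.5 * ((x - center) / sigma)^2)
}

FWHM_FACTOR <- 2 * sqrt(2 * log(2))  # 2.3548...

#' Simple linear fit returning slope/intercept/R2 without lm overhead
#' @noRd
linfit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) stop("degenerate linear fit: zero variance in x")
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  ssr <- sum((y - intercept - slope * x)^2)
  sst <- sum((y - my)^2)
  r2 <- if (sst == 0) 1 else 1 - ssr / sst
  list(slope = slope, intercept = intercept, r2 = r2)
}

#' Deterministic polynomial rolling hash of a serialised R object
#' (provenance fingerprinting only, not cryptographic)
#' @noRd
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h1 <- 5381
  h2 <- 52711
  for (b in bytes) {
    h1 <- (h1 * 33 + b) %% 2147483647
    h2 <- (h2 * 37 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

#' Truncated-at-zero normal draw for strictly positive latent parameters
#' @noRd
rnorm_pos <- function(n, mean, sd, strict = TRUE, max_tries = 100L) {
  x <- rnorm(n, mean, sd)
  if (!strict) return(x)
  bad <- which(x <= 0)
  tries <- 0L
  while (length(bad) && tries < max_tries) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x <= 0)
    tries <- tries + 1L
  }
  if (length(bad)) {
    warning("truncating non-positive latent draws at a small positive value")
    x[bad] <- mean * 1e-3
  }
  x
}
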