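# Group statistics: outlier screen, test selection, correlation, stepwise
# regression. Reproduces the two-group comparison workflow of a typical
# small-animal bone study.

#' Single-pass 2-SD outlier removal
#'
#' Mean and SD are computed once on the input; points farther than `k` SDs
#' from the mean are removed (non-iterative by design, for determinism).
#'
#' @param values numeric vector.
#' @param k SD multiple (default 2).
#' @param ids optional identifiers aligned with `values`.
#' @return list: `values` (kept), `removed` (ids or indices removed),
#'   `kept` (logical index).
#' @export
remove_outliers <- function(values, k = 2, ids = seq_along(values)) {
  if (length(values) < 3L) stop("need at least 3 values")
  m <- mean(values); s <- sd(values)
  keep <- if (s == 0) rep(TRUE, length(values)) else
    abs(values - m) <= k * s
  list(values = values[keep], removed = ids[!keep], kept = keep)
}

#' Mann-Whitney U test (exact enumeration for small samples)
#'
#' Computes the rank-sum U statistic with midranks for ties. When the number
#' of group labelings is at most `max_enum`, the two-sided p-value is exact:
#' every labeling is enumerated and p is the fraction whose |U - n1 n2 / 2|
#' is at least the observed. Otherwise a tie-corrected normal approximation
#' with continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param max_enum enumeration budget (labelings).
#' @return list: `U` (for `x`), `p`, `method`.
#' @export
mann_whitney_u <- function(x, y, max_enum = 400000) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  z <- c(x, y)
  r <- rank(z)
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (choose(n1 + n2, n1) <= max_enum) {
    combs <- utils::combn(n1 + n2, n1)
    dev_obs <- abs(U1 - mu)
    devs <- apply(combs, 2, function(ix)
      abs(sum(r[ix]) - n1 * (n1 + 1) / 2 - mu))
    p <- mean(devs >= dev_obs - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(z)
    n <- n1 + n2
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    zstat <- (abs(U1 - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-max(zstat, 0)))
    method <- "normal approximation"
  }
  list(U = U1, p = p, method = method)
}

# Levene's test (mean-centered) for two groups: F on absolute deviations
levene_p <- function(x, y) {
  zx <- abs(x - mean(x)); zy <- abs(y - mean(y))
  n1 <- length(zx); n2 <- length(zy)
  zb <- mean(c(zx, zy))
  ssb <- n1 * (mean(zx) - zb)^2 + n2 * (mean(zy) - zb)^2
  ssw <- sum((zx - mean(zx))^2) + sum((zy - mean(zy))^2)
  df2 <- n1 + n2 - 2
  if (ssw == 0) return(if (ssb == 0) 1 else 0)
  f <- ssb / (ssw / df2)
  pf(f, 1, df2, lower.tail = FALSE)
}

# Kolmogorov-Smirnov normality check against N(mean(x), sd(x))
# (Lilliefors-style: parameters estimated from the sample)
ks_normal_p <- function(x) {
  if (sd(x) == 0) return(0)
  suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value)
}

#' Two-group comparison with normality/variance-guided test selection
#'
#' Tests each group for normality (Kolmogorov-Smirnov against a normal with
#' sample mean and SD) and the pair for homogeneity of variances (Levene);
#' then compares with Student's t (both normal, homogeneous variances),
#' Welch's t (both normal, heterogeneous) or the exact-enumeration
#' Mann-Whitney U test (otherwise). The percent difference is signed and
#' referenced to the first (control) group:
#' `(mean_a - mean_b) / mean_a * 100`.
#'
#' @param a,b numeric samples; `a` is the reference (control) group.
#' @param alpha significance level for the normality and variance gates.
#' @param labels group labels (used in printing).
#' @return list of class `comparison_result`: group means/SDs/ns, `test`,
#'   `p`, `percent_difference`, `stars`.
#' @export
compare_groups <- function(a, b, alpha = 0.05, labels = c("control", "T2D")) {
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group")
  norm_a <- ks_normal_p(a) > alpha
  norm_b <- ks_normal_p(b) > alpha
  homo <- levene_p(a, b) > alpha
  if (norm_a && norm_b) {
    tt <- stats::t.test(a, b, var.equal = homo)
    p <- tt$p.value
    test <- if (homo) "Student t" else "Welch t"
  } else {
    mw <- mann_whitney_u(a, b)
    p <- mw$p
    test <- "Mann-Whitney U"
  }
  pd <- (mean(a) - mean(b)) / mean(a) * 100
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else ""
  structure(list(labels = labels,
                 mean_a = mean(a), sd_a = sd(a), n_a = length(a),
                 mean_b = mean(b), sd_b = sd(b), n_b = length(b),
                 test = test, p = p, percent_difference = pd, stars = stars),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s %.4g +/- %.4g vs %s %.4g +/- %.4g: %+.1f%% (%s p = %.4g)%s\n",
              x$labels[1], x$mean_a, x$sd_a, x$labels[2], x$mean_b, x$sd_b,
              x$percent_difference, x$test, x$p, x$stars))
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list: `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Coefficient of determination from a correlation
#' @param r Pearson correlation.
#' @return r squared.
#' @export
r_squared <- function(r) r * r

#' Forward stepwise regression with a partial-F entry criterion
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' predictor with the smallest partial-F entry p-value below `alpha_enter`;
#' stops when no candidate qualifies. No removal step (pure forward).
#' Candidates that would make the design matrix ill-conditioned are skipped
#' with a warning.
#'
#' @param y response vector.
#' @param candidates named list or data frame of candidate predictors.
#' @param alpha_enter entry threshold on the partial-F p-value.
#' @param kappa_max condition-number threshold for collinearity.
#' @return list of class `stepwise_model`: `entered` (ordered names),
#'   `entry_p`, `coefficients`, `r2`, `model` (the final `lm`).
#' @export
forward_stepwise <- function(y, candidates, alpha_enter = 0.05,
                             kappa_max = 1e8) {
  candidates <- as.data.frame(candidates)
  ok <- stats::complete.cases(candidates) & is.finite(y)
  y <- y[ok]; candidates <- candidates[ok, , drop = FALSE]
  entered <- character(0)
  entry_p <- numeric(0)
  remaining <- names(candidates)
  dat <- cbind(.y = y, candidates)
  repeat {
    best_p <- Inf; best <- NULL
    base_formula <- if (length(entered))
      paste(".y ~", paste(entered, collapse = " + ")) else ".y ~ 1"
    fit0 <- lm(stats::as.formula(base_formula), data = dat)
    for (cand in remaining) {
      Xc <- stats::model.matrix(
        stats::as.formula(paste("~", paste(c(entered, cand), collapse = " + "))),
        data = dat)
      if (kappa(Xc, exact = TRUE) > kappa_max) {
        warning("skipping collinear candidate: ", cand)
        next
      }
      fit1 <- lm(stats::as.formula(paste(base_formula, "+", cand)), data = dat)
      an <- stats::anova(fit0, fit1)
      p <- an$`Pr(>F)`[2]
      if (is.finite(p) && p < best_p) {
        best_p <- p; best <- cand
      }
    }
    if (is.null(best) || best_p >= alpha_enter) break
    entered <- c(entered, best)
    entry_p <- c(entry_p, best_p)
    remaining <- setdiff(remaining, best)
    if (!length(remaining)) break
  }
  final <- lm(stats::as.formula(if (length(entered))
    paste(".y ~", paste(entered, collapse = " + ")) else ".y ~ 1"), data = dat)
  structure(list(entered = entered, entry_p = setNames(entry_p, entered),
                 coefficients = coef(final),
                 r2 = summary(final)$r.squared, model = final),
            class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  if (!length(x$entered)) {
    cat("<stepwise_model> no predictor entered\n")
  } else {
    cat(sprintf("<stepwise_model> entered: %s; R2 = %.3f\n",
                paste(x$entered, collapse = " -> "), x$r2))
  }
  invisible(x)
}
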