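# Two-sided p for an estimate/SE pair that tolerates exact fits: an SE of
# (numerically) zero means the data determine the coefficient exactly.
.safe_t_p <- function(est, se, df) {
  if (!is.finite(se) || se < 1e-300) return(if (abs(est) < 1e-300) 1 else 0)
  2 * stats::pt(abs(est / se), df, lower.tail = FALSE)
}

#' Bland-Altman agreement between two measurement methods
#'
#' Differences (method 1 minus method 2) against pairwise means, with the
#' classic bias summaries and a proportional-bias regression: ordinary least
#' squares of the difference on the mean, two-sided t-tests of slope = 0 and
#' intercept = 0, and a systematic-bias verdict (either test significant at
#' \code{alpha}). Limits of agreement are mean difference +/- 1.96 SD.
#'
#' @param m1,m2 Paired numeric vectors (the convention in this package is
#'   ultrasound first, histology second, so differences read EBUS - histology).
#' @param alpha Significance level for the bias verdict.
#' @return Object of class \code{bland_altman}: list with \code{n},
#'   \code{mean_diff}, \code{sd_diff}, \code{loa_low}, \code{loa_high},
#'   \code{mean_of_means}, \code{slope}, \code{slope_p}, \code{intercept},
#'   \code{intercept_p}, \code{systematic_bias}.
#' @export
bland_altman <- function(m1, m2, alpha = 0.05) {
  ok <- is.finite(m1) & is.finite(m2)
  m1 <- m1[ok]; m2 <- m2[ok]
  n <- length(m1)
  if (n < 3L) stop("Bland-Altman needs at least 3 complete pairs")
  d <- m1 - m2
  m <- (m1 + m2) / 2
  fit <- stats::lm(d ~ m)
  cf <- stats::coef(fit)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  # vcov of an exact fit can carry negative rounding noise
  se[!is.finite(se)] <- 0
  df <- fit$df.residual
  slope_p <- .safe_t_p(cf[[2L]], se[[2L]], df)
  int_p <- .safe_t_p(cf[[1L]], se[[1L]], df)
  res <- list(
    n = n,
    mean_diff = mean(d), sd_diff = stats::sd(d),
    loa_low = mean(d) - 1.96 * stats::sd(d),
    loa_high = mean(d) + 1.96 * stats::sd(d),
    mean_of_means = mean(m),
    slope = cf[[2L]], slope_p = slope_p,
    intercept = cf[[1L]], intercept_p = int_p,
    systematic_bias = (slope_p < alpha) || (int_p < alpha),
    alpha = alpha
  )
  class(res) <- "bland_altman"
  res
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean diff %.4g (SD %.4g), LoA [%.4g, %.4g]\n",
              x$n, x$mean_diff, x$sd_diff, x$loa_low, x$loa_high))
  cat(sprintf("  slope %.4g (p = %.3g), intercept %.4g (p = %.3g): systematic bias %s\n",
              x$slope, x$slope_p, x$intercept, x$intercept_p,
              if (x$systematic_bias) "yes" else "no"))
  invisible(x)
}

#' Systematic-bias verdict from printed regression p-values
#'
#' The decision rule applied to a Bland-Altman proportional-bias regression:
#' bias is declared systematic when either the slope or the intercept
#' differs from zero at \code{alpha}. Exposed separately so the rule can be
#' applied to previously reported slope/intercept p-values.
#'
#' @param slope_p,intercept_p Two-sided p-values.
#' @param alpha Significance level.
#' @return Logical vector.
#' @export
bias_verdict <- function(slope_p, intercept_p, alpha = 0.05) {
  (slope_p < alpha) | (intercept_p < alpha)
}

#' Association between paired methods with a subject random effect
#'
#' Random-intercept-per-subject linear model of the first method's value on
#' the second's (measurements from the same subject are not independent).
#' Reports the fixed-slope Wald/t test and an R-squared defined as the
#' squared correlation between fitted and observed values. With a single
#' subject the model collapses to ordinary least squares.
#'
#' @param m1,m2 Paired numeric vectors (response and covariate).
#' @param subject Subject identifier per pair.
#' @return List with \code{slope}, \code{assoc_p}, \code{assoc_r2},
#'   \code{n}, \code{n_subjects}, \code{model}.
#' @export
method_association <- function(m1, m2, subject) {
  ok <- is.finite(m1) & is.finite(m2) & !is.na(subject)
  m1 <- m1[ok]; m2 <- m2[ok]; subject <- factor(subject[ok])
  if (length(m1) < 3L) stop("need at least 3 complete pairs")
  n_sub <- nlevels(subject)
  if (stats::var(m2) < 1e-300)
    stop("singular design: covariate has no variance")

  dat <- data.frame(y = m1, x = m2, subject = subject)
  use_lm <- n_sub < 2L
  if (!use_lm) {
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lmerTest::lmer(y ~ x + (1 | subject), data = dat))),
      error = function(e) NULL)
    if (is.null(fit)) use_lm <- TRUE
  }
  if (use_lm) {
    fit <- stats::lm(y ~ x, data = dat)
    cf <- suppressWarnings(summary(fit))$coefficients
    slope <- cf["x", "Estimate"]
    p <- .safe_t_p(slope, cf["x", "Std. Error"], fit$df.residual)
    fitted_y <- stats::fitted(fit)
    model <- "ols"
  } else {
    cf <- stats::coef(summary(fit))
    slope <- cf["x", "Estimate"]
    p <- cf["x", "Pr(>|t|)"]
    # a (near-)exact fit degenerates the Satterthwaite df; use the Wald test
    if (!is.finite(p) || cf["x", "df"] < 1)
      p <- .safe_t_p(slope, cf["x", "Std. Error"], Inf)
    fitted_y <- stats::fitted(fit)
    model <- "random-intercept"
  }
  r2 <- if (stats::var(fitted_y) < 1e-300) 0 else
    stats::cor(fitted_y, m1)^2
  list(slope = slope, assoc_p = as.numeric(p), assoc_r2 = r2,
       n = length(m1), n_subjects = n_sub, model = model)
}

#' Intraclass correlation for repeated measurements
#'
#' Repeatability of a measurement remeasured by the same observer: one-way
#' random-effects, single-measure ICC
#' \deqn{ICC = \frac{MS_B - MS_W}{MS_B + (k-1) MS_W}}
#' from the one-way ANOVA of value on item, with \eqn{k} repeats per item.
#' Requires a complete design (every item measured the same number of
#' times, at least twice, on at least 5 items).
#'
#' @param values Numeric vector of measurements.
#' @param item Item (e.g. image) identifier per measurement.
#' @return List of class \code{icc_result}: \code{icc}, \code{n_items},
#'   \code{n_repeats}, \code{model}.
#' @export
icc_repeatability <- function(values, item) {
  ok <- is.finite(values) & !is.na(item)
  if (any(!ok)) stop("missing cells: the ICC design must be complete")
  item <- factor(item)
  counts <- table(item)
  if (length(counts) < 5L) stop("need at least 5 items")
  if (length(unique(counts)) != 1L || counts[1L] < 2L)
    stop("missing cells: every item needs the same number (>= 2) of repeats")
  k <- as.integer(counts[1L])
  fit <- stats::aov(values ~ item)
  ms <- summary(fit)[[1L]][["Mean Sq"]]
  msb <- ms[1L]; msw <- ms[2L]
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  structure(list(icc = icc, n_items = nlevels(item), n_repeats = k,
                 model = "one-way random effects, single measure"),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.1f%% (%s; %d items x %d repeats)\n", 100 * x$icc,
              x$model, x$n_items, x$n_repeats))
  invisible(x)
}
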