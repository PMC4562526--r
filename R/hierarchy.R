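#' Nested variance components of a group/subject/airway/image dataset
#'
#' Method-of-moments estimates from the nested ANOVA decomposition, with the
#' group treated as the top stratum: mean squares are computed at the image
#' (within airway), airway (within subject), subject (within group) and group
#' levels, and converted to per-level variances with the balanced
#' expected-mean-square coefficients (average replication numbers are used
#' under mild unbalance). Negative solutions are truncated to zero before
#' normalizing to percentages, so a level can legitimately be reported as 0.
#'
#' @param data Data frame with columns \code{group}, \code{subject},
#'   \code{airway}, \code{value} (one row per image).
#' @return Object of class \code{varcomp}: data frame with columns
#'   \code{level} (group/subject/airway/image), \code{variance}, \code{pct}.
#' @export
nested_varcomp <- function(data) {
  req <- c("group", "subject", "airway", "value")
  if (!all(req %in% names(data)))
    stop("data must have columns: ", paste(req, collapse = ", "))
  y <- data$value
  grp <- factor(data$group)
  sub <- interaction(grp, data$subject, drop = TRUE)
  air <- interaction(sub, data$airway, drop = TRUE)
  G <- nlevels(grp); S <- nlevels(sub); A <- nlevels(air); N <- length(y)
  if (A >= N) stop("need >= 2 images in at least some airways")
  if (S < 2L || A <= S) stop("need >= 2 units at each estimated level")

  gm <- mean(y)
  m_air <- tapply(y, air, mean)
  m_sub <- tapply(y, sub, mean)
  m_grp <- tapply(y, grp, mean)
  n_air <- tapply(y, air, length)
  n_sub <- tapply(y, sub, length)
  n_grp <- tapply(y, grp, length)
  air2sub <- tapply(as.character(sub), air, `[`, 1L)
  sub2grp <- tapply(as.character(grp), sub, `[`, 1L)

  ss_img <- sum((y - m_air[air])^2)
  ss_air <- sum(n_air * (m_air - m_sub[air2sub])^2)
  ss_sub <- sum(n_sub * (m_sub - m_grp[sub2grp])^2)
  ss_grp <- sum(n_grp * (m_grp - gm)^2)

  ms_img <- ss_img / (N - A)
  ms_air <- ss_air / (A - S)
  ms_sub <- ss_sub / (S - G)
  ms_grp <- if (G > 1L) ss_grp / (G - 1L) else NA_real_

  nbar <- N / A            # images per airway
  abar <- N / S            # images per subject
  sbar <- N / G            # images per group

  v_img <- ms_img
  v_air <- (ms_air - ms_img) / nbar
  v_sub <- (ms_sub - ms_img - max(v_air, 0) * nbar) / abar
  v <- c(image = v_img, airway = v_air, subject = v_sub)
  if (G > 1L) {
    v_grp <- (ms_grp - ms_img - max(v_air, 0) * nbar -
                max(v_sub, 0) * abar) / sbar
    v <- c(v, group = v_grp)
  }
  v <- pmax(v, 0)
  lev <- intersect(c("group", "subject", "airway", "image"), names(v))
  out <- data.frame(level = lev, variance = as.numeric(v[lev]),
                    pct = 100 * as.numeric(v[lev]) / sum(v))
  class(out) <- c("varcomp", "data.frame")
  out
}

#' @export
print.varcomp <- function(x, ...) {
  cat("nested variance components:\n")
  print(data.frame(level = x$level, variance = signif(x$variance, 4),
                   pct = round(x$pct, 1)), row.names = FALSE)
  invisible(x)
}

#' Group contrasts within airway size classes
#'
#' Compares the two groups within each airway size class, adjusting the
#' per-class p-values with the sequential Bonferroni (Holm step-down)
#' procedure. The default test aggregates to per-subject class means and
#' applies a pooled-variance two-sample t-test, which for balanced data is
#' exactly the random-subject-intercept analysis; \code{method = "lmer"}
#' fits the mixed model per class instead (REML, Satterthwaite test).
#'
#' @param data Data frame with \code{group} (2 levels), \code{subject},
#'   \code{pi_mm}, \code{value}.
#' @param size_classing \code{"two_way"} (intermediate/large at 31 mm) or
#'   \code{"three_way"} (boundaries 16 and 31 mm).
#' @param alpha Family-wise significance level.
#' @param method \code{"subject_means"} (default) or \code{"lmer"}.
#' @param bounds Size-class boundaries in mm.
#' @return Data frame with one row per populated class: \code{class},
#'   \code{n_subjects}, \code{estimate} (group 2 minus group 1 mean),
#'   \code{p}, \code{p_adj}, \code{significant}. Classes missing a group are
#'   skipped with a warning.
#' @export
group_size_contrasts <- function(data, size_classing = c("two_way", "three_way"),
                                 alpha = 0.05,
                                 method = c("subject_means", "lmer"),
                                 bounds = c(16, 31)) {
  size_classing <- match.arg(size_classing)
  method <- match.arg(method)
  req <- c("group", "subject", "pi_mm", "value")
  if (!all(req %in% names(data)))
    stop("data must have columns: ", paste(req, collapse = ", "))
  grp <- factor(data$group)
  if (nlevels(grp) != 2L) stop("exactly 2 groups are required")
  cls <- classify_size(data$pi_mm, bounds)[[size_classing]]

  rows <- list()
  for (lv in levels(cls)) {
    idx <- which(cls == lv)
    if (!length(idx)) { warning("size class '", lv, "' is empty; skipped"); next }
    d <- data[idx, , drop = FALSE]
    d$group <- factor(d$group, levels = levels(grp))
    if (length(unique(d$group)) < 2L) {
      warning("size class '", lv, "' lacks one group; skipped"); next
    }
    if (method == "subject_means") {
      sm <- stats::aggregate(value ~ subject + group, d, mean)
      if (any(table(sm$group) < 2L)) {
        warning("size class '", lv, "' has < 2 subjects in a group; skipped")
        next
      }
      tt <- stats::t.test(value ~ group, sm, var.equal = TRUE)
      est <- as.numeric(diff(tt$estimate))  # group2 - group1
      p <- tt$p.value
      ns <- nrow(sm)
    } else {
      fit <- suppressMessages(suppressWarnings(
        lmerTest::lmer(value ~ group + (1 | subject), data = d)))
      cf <- stats::coef(summary(fit))
      est <- cf[2L, "Estimate"]
      p <- cf[2L, "Pr(>|t|)"]
      ns <- length(unique(d$subject))
    }
    rows[[lv]] <- data.frame(class = lv, n_subjects = ns,
                             estimate = as.numeric(est), p = p)
  }
  if (!length(rows)) stop("no size class contains both groups")
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "holm")
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Per-group slopes of a measurement against airway size
#'
#' Random-subject-intercept model \code{value ~ group * pi + (1 | subject)}:
#' returns the slope of the value against the internal perimeter in each
#' group with Wald tests against zero, and the group-by-size interaction
#' p-value (the slope-difference test, Satterthwaite when available). If the
#' mixed fit is degenerate (e.g. noise-free data), the model falls back to
#' least squares with fixed subject intercepts.
#'
#' @param data Data frame with \code{group} (2 levels), \code{subject},
#'   \code{pi_mm}, \code{value}.
#' @return List with \code{slopes} (data frame: group, slope, se, p) and
#'   \code{interaction_p}.
#' @export
fit_pi_slopes <- function(data) {
  req <- c("group", "subject", "pi_mm", "value")
  if (!all(req %in% names(data)))
    stop("data must have columns: ", paste(req, collapse = ", "))
  d <- data
  d$group <- factor(d$group)
  if (nlevels(d$group) != 2L) stop("exactly 2 groups are required")
  if (stats::var(d$pi_mm) < 1e-300)
    stop("Pi is constant: slopes are undefined")

  fit <- tryCatch(suppressMessages(suppressWarnings(
    lmerTest::lmer(value ~ group * pi_mm + (1 | subject), data = d))),
    error = function(e) NULL)
  degenerate <- is.null(fit) ||
    stats::sigma(fit) < 1e-8 * stats::sd(d$value)
  if (degenerate) {
    fit2 <- stats::lm(value ~ group * pi_mm + factor(subject), data = d)
    cf <- summary(fit2)$coefficients
    V <- stats::vcov(fit2)
    nm_pi <- "pi_mm"
    nm_int <- grep(":pi_mm$|^group.*:pi_mm", rownames(cf), value = TRUE)[1L]
    b <- stats::coef(fit2)
    df <- fit2$df.residual
    int_p <- .safe_t_p(b[[nm_int]], sqrt(max(V[nm_int, nm_int], 0)), df)
  } else {
    cfs <- stats::coef(summary(fit))
    V <- as.matrix(stats::vcov(fit))
    nm_pi <- "pi_mm"
    nm_int <- grep(":pi_mm$", rownames(cfs), value = TRUE)[1L]
    b <- lme4::fixef(fit)
    df <- Inf
    int_p <- cfs[nm_int, "Pr(>|t|)"]
    if (!is.finite(int_p))
      int_p <- .safe_t_p(b[[nm_int]], sqrt(max(V[nm_int, nm_int], 0)), Inf)
  }
  s1 <- b[[nm_pi]]
  s2 <- b[[nm_pi]] + b[[nm_int]]
  se1 <- sqrt(max(V[nm_pi, nm_pi], 0))
  se2 <- sqrt(max(V[nm_pi, nm_pi] + V[nm_int, nm_int] +
                    2 * V[nm_pi, nm_int], 0))
  slopes <- data.frame(
    group = levels(d$group),
    slope = c(s1, s2),
    se = c(se1, se2),
    p = c(.safe_t_p(s1, se1, df), .safe_t_p(s2, se2, df))
  )
  list(slopes = slopes, interaction_p = as.numeric(int_p))
}

# Finite-sample unbiasing constant for the SD of n Gaussian draws.
.c4 <- function(n) sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2)

#' Coefficient of variation of airway means by number of images
#'
#' How many images per airway are needed for a stable airway mean: for each
#' candidate n, each airway contributes the estimated CV of a mean of n
#' images (bias-corrected SD of an n-image subsample, divided by sqrt(n)
#' times the subsample mean); CVs are averaged over airways. The
#' recommended n is the smallest whose mean CV exceeds the mean CV at the
#' largest n by less than \code{margin} (relative).
#'
#' @param data Data frame with \code{airway} and \code{value} (one row per
#'   image).
#' @param n_values Candidate image counts, default 2:4.
#' @param margin Relative tolerance on the CV vs the largest n.
#' @param seed Integer seed for the subsampling.
#' @return List with \code{cv} (data frame: n, mean_cv, n_airways),
#'   \code{recommended_n}, \code{n_excluded} (airways with too few images).
#' @export
cv_by_n_images <- function(data, n_values = 2:4, margin = 0.2,
                           seed = 20150908L) {
  if (!all(c("airway", "value") %in% names(data)))
    stop("data must have columns: airway, value")
  n_values <- sort(unique(as.integer(n_values)))
  if (any(n_values < 2L)) stop("'n_values' must be >= 2")
  nmax <- max(n_values)
  counts <- table(data$airway)
  usable <- names(counts)[counts >= nmax]
  n_excl <- sum(counts < nmax)
  if (!length(usable))
    stop("no airway has >= ", nmax, " images")
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  vals <- split(data$value, data$airway)[usable]
  res <- vapply(n_values, function(n) {
    cvs <- vapply(vals, function(v) {
      sub <- sample(v, n)
      m <- mean(sub)
      if (abs(m) < 1e-300) return(NA_real_)
      stats::sd(sub) / .c4(n) / (sqrt(n) * abs(m))
    }, numeric(1L))
    mean(cvs, na.rm = TRUE)
  }, numeric(1L))
  cv <- data.frame(n = n_values, mean_cv = res, n_airways = length(usable))
  ref <- res[length(res)]
  ok <- res <= (1 + margin) * ref + 1e-12
  recommended <- n_values[which(ok)[1L]]
  list(cv = cv, recommended_n = recommended, n_excluded = n_excl)
}

#' Simulation-based power analysis for the hierarchical design
#'
#' Estimates, for each group-effect size and each number of subjects per
#' group, the probability of detecting the group effect at level
#' \code{alpha}: datasets are simulated from the hierarchical design and the
#' group contrast is tested on per-subject means (a pooled-variance
#' two-sample t-test, exactly valid for balanced designs). The required N
#' per effect is the smallest grid value reaching \code{target_power}.
#'
#' @param design Template \code{hierarchical_design} (its
#'   \code{n_subjects_per_group} and \code{group_effect_pct} are overridden
#'   by the grids).
#' @param effect_pcts Group effect sizes to scan, percent.
#' @param n_grid Numbers of subjects per group to scan.
#' @param reps Simulated datasets per (effect, N) cell.
#' @param alpha Test level.
#' @param target_power Power the required N must reach.
#' @param seed Integer seed for the whole scan.
#' @return Object of class \code{power_curve}: list with \code{power}
#'   (data frame: effect_pct, n, power), \code{required_n} (data frame:
#'   effect_pct, n_required; NA when the grid is exhausted), \code{alpha},
#'   \code{target_power}, \code{reps}.
#' @export
simulate_power <- function(design = hierarchical_design(),
                           effect_pcts = c(15, 30, 60),
                           n_grid = c(2, 4, 6, 8, 10, 15, 22),
                           reps = 200L, alpha = 0.05, target_power = 0.8,
                           seed = 20150908L) {
  stopifnot(inherits(design, "hierarchical_design"))
  if (reps < 1L) stop("'reps' must be >= 1")
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))

  grid <- expand.grid(effect_pct = effect_pcts, n = sort(n_grid))
  grid$power <- NA_real_
  for (i in seq_len(nrow(grid))) {
    des <- design
    des$group_effect_pct <- grid$effect_pct[i]
    des$n_subjects_per_group <- as.integer(grid$n[i])
    des$n_groups <- 2L
    des$seed <- NULL  # draw from the running RNG stream
    rej <- 0L
    for (r in seq_len(reps)) {
      d <- generate_hierarchical_dataset(des)
      sm <- tapply(d$value, d$subject, mean)
      gi <- tapply(as.character(d$group), d$subject, `[`, 1L)
      p <- stats::t.test(sm[gi == "control"], sm[gi == "heaves"],
                         var.equal = TRUE)$p.value
      if (p < alpha) rej <- rej + 1L
    }
    grid$power[i] <- rej / reps
  }
  required <- do.call(rbind, lapply(effect_pcts, function(e) {
    g <- grid[grid$effect_pct == e, ]
    hit <- g$n[g$power >= target_power]
    data.frame(effect_pct = e,
               n_required = if (length(hit)) min(hit) else NA_integer_)
  }))
  structure(list(power = grid, required_n = required, alpha = alpha,
                 target_power = target_power, reps = as.integer(reps)),
            class = "power_curve")
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("power scan (%d reps, alpha = %g, target %.0f%%):\n", x$reps,
              x$alpha, 100 * x$target_power))
  print(x$required_n, row.names = FALSE)
  invisible(x)
}
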