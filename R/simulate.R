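#' Design of a nested group/subject/airway/image study
#'
#' Captures the hierarchical sampling scheme of an ultrasound remodeling
#' study: two (or more) groups of subjects, several airways sampled per
#' subject, several images analyzed per airway, with a multiplicative group
#' effect on the measured quantity and Gaussian random effects at the
#' subject, airway and image levels.
#'
#' The image stratum is the residual: with one value per image the two are
#' indistinguishable, so any unassigned variance fraction (1 minus the sum of
#' the three fractions) is folded into the image/residual term.
#'
#' Defaults mirror the in vivo optimized protocol of the equine study the
#' package models: about 10 airways of similar size per subject, 3 images per
#' airway, a 30% group effect on an L2-type thickness of about 0.25 mm, a 25%
#' single-image coefficient of variation split mostly between the airway and
#' image levels, and intermediate-size airways (Pi 10-31 mm).
#'
#' @param n_groups,n_subjects_per_group,n_airways_per_subject,n_images_per_airway
#'   Design counts (all >= 1).
#' @param grand_mean Mean of the measured value in group 1, measurement units.
#' @param group_effect_pct Percent difference applied multiplicatively to
#'   group 2.
#' @param variance_fractions Named or ordered fractions
#'   (subject, airway, image) of the total single-image variance; each >= 0,
#'   sum <= 1.
#' @param total_cv Coefficient of variation of one image value within a group.
#' @param pi_range Internal-perimeter range (mm) airways are drawn from.
#' @param seed Integer seed.
#' @return A list of class \code{hierarchical_design}.
#' @export
hierarchical_design <- function(n_groups = 2L, n_subjects_per_group = 7L,
                                n_airways_per_subject = 10L,
                                n_images_per_airway = 3L,
                                grand_mean = 0.25, group_effect_pct = 30,
                                variance_fractions = c(subject = 0.10,
                                                       airway = 0.60,
                                                       image = 0.30),
                                total_cv = 0.25,
                                pi_range = c(10, 31), seed = 20150908L) {
  counts <- c(n_groups, n_subjects_per_group, n_airways_per_subject,
              n_images_per_airway)
  if (any(counts < 1L)) stop("all design counts must be >= 1")
  vf <- rep_len(as.numeric(variance_fractions), 3L)
  if (any(vf < 0)) stop("variance fractions must be >= 0")
  if (sum(vf) > 1 + 1e-12)
    stop("variance fractions must sum to <= 1")
  if (total_cv <= 0) stop("'total_cv' must be > 0")
  structure(list(
    n_groups = as.integer(n_groups),
    n_subjects_per_group = as.integer(n_subjects_per_group),
    n_airways_per_subject = as.integer(n_airways_per_subject),
    n_images_per_airway = as.integer(n_images_per_airway),
    grand_mean = grand_mean, group_effect_pct = group_effect_pct,
    variance_fractions = c(subject = vf[1L], airway = vf[2L], image = vf[3L]),
    total_cv = total_cv, pi_range = pi_range,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "hierarchical_design")
}

#' Simulate a nested group/subject/airway/image dataset
#'
#' Generates one value per image as
#' \deqn{y = \mu_g + b_{subject} + b_{airway} + e_{image}}
#' with \eqn{\mu_g} the group mean (group 2 shifted by
#' \code{group_effect_pct}\%) and independent zero-mean Gaussian effects whose
#' variances realize the design's variance fractions of the total
#' single-image variance \eqn{(\mathrm{CV}\cdot\mu)^2}. Each airway also
#' carries an internal perimeter drawn uniformly from \code{pi_range}.
#'
#' @param design A \code{hierarchical_design}.
#' @return Data frame with columns \code{group}, \code{subject},
#'   \code{airway}, \code{image}, \code{pi_mm}, \code{value}; the design and
#'   the true variance components are attached as attributes
#'   \code{"design"} and \code{"truth"}.
#' @export
generate_hierarchical_dataset <- function(design = hierarchical_design()) {
  stopifnot(inherits(design, "hierarchical_design"))
  if (!is.null(design$seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
    set.seed(design$seed)
  }
  g <- design$n_groups; s <- design$n_subjects_per_group
  a <- design$n_airways_per_subject; m <- design$n_images_per_airway
  sigma_tot2 <- (design$total_cv * design$grand_mean)^2
  vf <- design$variance_fractions
  sd_s <- sqrt(vf[["subject"]] * sigma_tot2)
  sd_a <- sqrt(vf[["airway"]] * sigma_tot2)
  sd_e <- sqrt((1 - vf[["subject"]] - vf[["airway"]]) * sigma_tot2)

  grp <- rep(seq_len(g), each = s * a * m)
  sub <- rep(seq_len(g * s), each = a * m)
  air <- rep(seq_len(g * s * a), each = m)
  img <- rep(seq_len(m), times = g * s * a)

  mu <- design$grand_mean * ifelse(grp == 2L,
                                   1 + design$group_effect_pct / 100, 1)
  b_s <- stats::rnorm(g * s, 0, sd_s)[sub]
  b_a <- stats::rnorm(g * s * a, 0, sd_a)[air]
  e <- stats::rnorm(g * s * a * m, 0, sd_e)
  pi_air <- stats::runif(g * s * a, design$pi_range[1L],
                         design$pi_range[2L])[air]

  out <- data.frame(
    group = factor(if (g == 2L) c("control", "heaves")[grp] else
                     paste0("group", grp)),
    subject = paste0("S", sub),
    airway = paste0("A", air),
    image = img,
    pi_mm = pi_air,
    value = mu + b_s + b_a + e
  )
  attr(out, "design") <- design
  attr(out, "truth") <- list(
    sigma2 = c(subject = sd_s^2, airway = sd_a^2, image = sd_e^2),
    group_means = unique(mu)
  )
  out
}

#' Design for paired ultrasound/histology measurements
#'
#' Parameters of the paired-modality simulator: a proportional (and optional
#' constant) ultrasound underestimation of the internal perimeter, a linear
#' tissue-shrinkage fraction applied to histology, and multiplicative
#' measurement noise. Defaults reflect the study scale: 109 bronchi from 13
#' subjects, a 44% linear shrinkage between in vivo imaging and fixed
#' histology, and airway perimeters of 10-45 mm.
#'
#' @param n_airways,n_subjects Counts.
#' @param pi_bias_slope Proportional ultrasound Pi underestimation (unitless).
#' @param pi_bias_intercept Constant ultrasound Pi underestimation, mm.
#' @param shrink_fraction Linear histology shrinkage in [0, 1); areas shrink
#'   by its square.
#' @param noise_cv Multiplicative measurement noise CV (>= 0), applied to all
#'   measured fields of both modalities.
#' @param pi_range Distended internal-perimeter range, mm.
#' @param ecm_frac_of_l2 True fraction of the second ultrasound layer
#'   occupied by extracellular matrix (rest is smooth muscle).
#' @param seed Integer seed.
#' @return A list of class \code{paired_modality_design}.
#' @export
paired_modality_design <- function(n_airways = 109L, n_subjects = 13L,
                                   pi_bias_slope = 0.18,
                                   pi_bias_intercept = 0,
                                   shrink_fraction = 0.44,
                                   noise_cv = 0.05,
                                   pi_range = c(10, 45),
                                   ecm_frac_of_l2 = 0.22,
                                   seed = 20150908L) {
  if (shrink_fraction < 0 || shrink_fraction >= 1)
    stop("'shrink_fraction' must be in [0, 1)")
  if (noise_cv < 0) stop("'noise_cv' must be >= 0")
  if (n_airways < 1L || n_subjects < 1L) stop("counts must be >= 1")
  structure(list(
    n_airways = as.integer(n_airways), n_subjects = as.integer(n_subjects),
    pi_bias_slope = pi_bias_slope, pi_bias_intercept = pi_bias_intercept,
    shrink_fraction = shrink_fraction, noise_cv = noise_cv,
    pi_range = pi_range, ecm_frac_of_l2 = ecm_frac_of_l2,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "paired_modality_design")
}

#' Simulate paired ultrasound/histology airway records
#'
#' For each airway a distended truth is drawn (Pi uniform in
#' \code{pi_range}; first- and second-layer thicknesses proportional to Pi at
#' ratios matching intermediate equine bronchi; circular cross-section for
#' diameter and lumen area). The histology record shrinks all linear
#' dimensions by \code{shrink_fraction} (areas by its square); its matrix and
#' muscle areas are the concentric-annulus areas of the shrunken thicknesses.
#' The ultrasound record keeps distended dimensions but underestimates Pi by
#' \code{pi_bias_slope} proportionally plus \code{pi_bias_intercept} mm.
#' Multiplicative Gaussian noise of CV \code{noise_cv} is applied to every
#' measured field; the noiseless truth is retained in \code{truth_*} columns.
#'
#' @param design A \code{paired_modality_design}.
#' @return Data frame with one row per airway: \code{subject}, \code{airway},
#'   \code{truth_*}, \code{ebus_*} and \code{histo_*} columns (units mm/mm2).
#' @export
generate_paired_modality <- function(design = paired_modality_design()) {
  stopifnot(inherits(design, "paired_modality_design"))
  if (!is.null(design$seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
    set.seed(design$seed)
  }
  n <- design$n_airways
  pi_t <- stats::runif(n, design$pi_range[1L], design$pi_range[2L])
  # thickness-to-perimeter ratios typical of intermediate equine bronchi
  l1_t <- 0.0068 * pi_t
  l2_t <- 0.0109 * pi_t
  r_t <- pi_t / (2 * base::pi)
  d_t <- 2 * r_t
  la_t <- base::pi * r_t^2

  # distended submucosal split: matrix = all of L1 plus an inner fraction of
  # L2, muscle = the rest of L2
  t_ecm_d <- l1_t + design$ecm_frac_of_l2 * l2_t
  t_asm_d <- (1 - design$ecm_frac_of_l2) * l2_t
  a_ecm_d <- base::pi * ((r_t + t_ecm_d)^2 - r_t^2)
  a_asm_d <- base::pi * ((r_t + t_ecm_d + t_asm_d)^2 - (r_t + t_ecm_d)^2)
  l2_area_d <- base::pi * ((r_t + l1_t + l2_t)^2 - (r_t + l1_t)^2)

  k <- 1 - design$shrink_fraction
  noisy <- function(x) x * (1 + stats::rnorm(n, 0, design$noise_cv))

  out <- data.frame(
    subject = paste0("S", rep_len(seq_len(design$n_subjects), n)),
    airway = paste0("A", seq_len(n)),
    truth_pi_mm = pi_t, truth_d_mm = d_t, truth_la_mm2 = la_t,
    truth_l1_mm = l1_t, truth_l2_mm = l2_t,
    ebus_pi_mm = noisy(pi_t * (1 - design$pi_bias_slope) -
                         design$pi_bias_intercept),
    ebus_d_mm = noisy(d_t), ebus_la_mm2 = noisy(la_t),
    ebus_l1_mm = noisy(l1_t), ebus_l2_mm = noisy(l2_t),
    ebus_l2_area_mm2 = noisy(l2_area_d),
    histo_pi_mm = noisy(k * pi_t), histo_d_mm = noisy(k * d_t),
    histo_la_mm2 = noisy(k^2 * la_t),
    histo_a_ecm_mm2 = noisy(k^2 * a_ecm_d),
    histo_a_asm_mm2 = noisy(k^2 * a_asm_d)
  )
  attr(out, "design") <- design
  out
}
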