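#' Equivalent annulus thickness of a wall layer
#'
#' The concentric-annulus model of a maximally distended airway: a layer of
#' area \eqn{A} wrapped around an inner circle of circumference \eqn{C}
#' (radius \eqn{r = C/2\pi}) has thickness
#' \deqn{t = \sqrt{r^2 + A/\pi} - r,}
#' the exact inverse of \eqn{A = \pi((r+t)^2 - r^2)}. In the thin-layer limit
#' this reduces to the flat-sheet approximation \eqn{t \to A/C}.
#'
#' @param area Layer cross-sectional area, mm^2 (>= 0).
#' @param inner_circumference Circumference of the inner circle, mm (> 0).
#' @return Thickness in mm. Vectorized over both arguments.
#' @examples
#' annulus_thickness(3 * pi, 2 * pi)  # r = 1, R = 2 -> 1
#' @export
annulus_thickness <- function(area, inner_circumference) {
  if (any(area < 0)) stop("'area' must be >= 0")
  if (any(inner_circumference <= 0))
    stop("'inner_circumference' must be > 0")
  r <- inner_circumference / (2 * base::pi)
  sqrt(r^2 + area / base::pi) - r
}

#' Stack the matrix and muscle annuli of the airway wall
#'
#' Converts histological extracellular-matrix and smooth-muscle areas into
#' distended-airway layer thicknesses by stacking two concentric annuli: the
#' internal perimeter is the inner circumference of the matrix annulus
#' (epithelial thickness treated as negligible), and the matrix annulus'
#' outer circle becomes the inner circle of the muscle annulus.
#'
#' @param a_ecm Extracellular matrix (lamina propria) area, mm^2.
#' @param a_asm Airway smooth muscle area, mm^2.
#' @param pi_mm Internal perimeter, mm.
#' @return List with \code{t_ecm_mm}, \code{t_asm_mm}, \code{r_inner_mm},
#'   \code{r_ecm_outer_mm}, \code{r_asm_outer_mm}. Vectorized.
#' @export
stack_layers <- function(a_ecm, a_asm, pi_mm) {
  t_ecm <- annulus_thickness(a_ecm, pi_mm)
  r_in <- pi_mm / (2 * base::pi)
  r_ecm <- r_in + t_ecm
  t_asm <- annulus_thickness(a_asm, 2 * base::pi * r_ecm)
  list(t_ecm_mm = t_ecm, t_asm_mm = t_asm,
       r_inner_mm = r_in, r_ecm_outer_mm = r_ecm,
       r_asm_outer_mm = r_ecm + t_asm)
}

#' Submucosal thickness as a layer sum
#'
#' The submucosal thickness of one modality: at histology the sum of the
#' annulus-model matrix and muscle thicknesses, on ultrasound the sum of the
#' first- and second-layer thicknesses.
#'
#' @param t_inner,t_outer The two layer thicknesses, mm (>= 0).
#' @return Their sum, mm. Vectorized.
#' @export
submucosal_thickness <- function(t_inner, t_outer) {
  if (any(t_inner < 0 | t_outer < 0)) stop("thicknesses must be >= 0")
  t_inner + t_outer
}

#' Linear tissue shrinkage between imaging and histology
#'
#' Percent reduction of the submucosal thickness from the distended in vivo
#' state (ultrasound) to the fixed, embedded histological section, relative
#' to the in vivo value: \code{100 * (ebus - histo) / ebus}.
#'
#' @param ebus_submucosa Ultrasound submucosal thickness, mm (> 0).
#' @param histo_submucosa Histological submucosal thickness, mm.
#' @return Shrinkage in percent. Vectorized.
#' @export
shrinkage_pct <- function(ebus_submucosa, histo_submucosa) {
  if (any(ebus_submucosa <= 0))
    stop("'ebus_submucosa' must be > 0")
  100 * (ebus_submucosa - histo_submucosa) / ebus_submucosa
}

#' Rescale histological layer thicknesses to the distended airway
#'
#' Multiplies the annulus-model matrix and muscle thicknesses by the factor
#' that makes their sum equal the ultrasound submucosal thickness, undoing
#' tissue shrinkage so the two modalities can be compared layer by layer.
#'
#' @param t_ecm,t_asm Histological thicknesses, mm (sum > 0).
#' @param ebus_submucosa Ultrasound submucosal thickness, mm (> 0).
#' @return List with \code{t_ecm_mm}, \code{t_asm_mm} (scaled) and
#'   \code{scale_factor}. Vectorized.
#' @export
scale_histology_to_ebus <- function(t_ecm, t_asm, ebus_submucosa) {
  if (any(t_ecm + t_asm <= 0))
    stop("histologic submucosal thickness must be > 0")
  if (any(ebus_submucosa <= 0)) stop("'ebus_submucosa' must be > 0")
  sf <- ebus_submucosa / (t_ecm + t_asm)
  list(t_ecm_mm = t_ecm * sf, t_asm_mm = t_asm * sf, scale_factor = sf)
}

#' Composition of the second ultrasound layer
#'
#' Partitions the second ultrasound layer (L2) into its extracellular-matrix
#' and smooth-muscle fractions: the first layer (L1) is entirely matrix, so
#' the matrix thickness inside L2 is the distended-scaled matrix thickness
#' minus L1 (clamped at 0 and flagged if the scaled matrix is thinner than
#' L1, a case the model treats as L1 containing all the matrix).
#'
#' @param scaled_t_ecm Matrix thickness rescaled to the distended airway, mm.
#' @param l1,l2 Ultrasound first- and second-layer thicknesses, mm (> 0).
#' @return List with \code{ecm_pct_of_l2}, \code{asm_pct_of_l2} (summing to
#'   100 exactly), \code{l1_ecm_pct}, \code{clamped}. Vectorized.
#' @export
l2_composition <- function(scaled_t_ecm, l1, l2) {
  if (any(l1 <= 0 | l2 <= 0)) stop("'l1' and 'l2' must be > 0")
  if (any(scaled_t_ecm < 0)) stop("'scaled_t_ecm' must be >= 0")
  ecm_in_l2 <- scaled_t_ecm - l1
  clamped <- ecm_in_l2 < 0
  ecm_in_l2 <- pmax(ecm_in_l2, 0)
  ecm_pct <- 100 * ecm_in_l2 / l2
  list(ecm_pct_of_l2 = ecm_pct, asm_pct_of_l2 = 100 - ecm_pct,
       l1_ecm_pct = 100 * pmin(scaled_t_ecm / l1, 1), clamped = clamped)
}

#' Full annulus-model analysis of paired airway records
#'
#' Runs the complete distended-airway reconstruction per airway on a paired
#' ultrasound/histology table: annulus thicknesses from the histological
#' areas and perimeter, submucosal sums for both modalities, shrinkage,
#' rescaling of histology to the ultrasound submucosa, and second-layer
#' composition. Composition fields are only computed for airways below the
#' size cutoff (submucosal thickness varies with airway size, so composition
#' is assessed on size-matched airways).
#'
#' @param pairs Data frame with columns \code{histo_a_ecm_mm2},
#'   \code{histo_a_asm_mm2}, \code{histo_pi_mm}, \code{ebus_l1_mm},
#'   \code{ebus_l2_mm} and optionally \code{subject}, \code{airway}
#'   (as produced by \code{\link{generate_paired_modality}}).
#' @param composition_pi_max Internal-perimeter cutoff (mm, histology Pi) for
#'   the composition analysis; \code{Inf} disables the filter.
#' @return Data frame, one row per airway: \code{subject}, \code{airway},
#'   \code{pi_mm}, \code{t_ecm_mm}, \code{t_asm_mm},
#'   \code{t_submucosa_histo_mm}, \code{t_submucosa_ebus_mm},
#'   \code{scale_factor}, \code{shrinkage_pct}, \code{ecm_pct_of_l2},
#'   \code{asm_pct_of_l2}, \code{clamped}.
#' @export
annulus_analysis <- function(pairs, composition_pi_max = 26) {
  req <- c("histo_a_ecm_mm2", "histo_a_asm_mm2", "histo_pi_mm",
           "ebus_l1_mm", "ebus_l2_mm")
  if (!all(req %in% names(pairs)))
    stop("pairs must have columns: ", paste(req, collapse = ", "))
  st <- stack_layers(pairs$histo_a_ecm_mm2, pairs$histo_a_asm_mm2,
                     pairs$histo_pi_mm)
  sub_h <- submucosal_thickness(st$t_ecm_mm, st$t_asm_mm)
  sub_e <- submucosal_thickness(pairs$ebus_l1_mm, pairs$ebus_l2_mm)
  sc <- scale_histology_to_ebus(st$t_ecm_mm, st$t_asm_mm, sub_e)
  comp <- l2_composition(sc$t_ecm_mm, pairs$ebus_l1_mm, pairs$ebus_l2_mm)
  keep <- pairs$histo_pi_mm < composition_pi_max

  out <- data.frame(
    subject = if ("subject" %in% names(pairs)) pairs$subject else NA,
    airway = if ("airway" %in% names(pairs)) pairs$airway else
      seq_len(nrow(pairs)),
    pi_mm = pairs$histo_pi_mm,
    t_ecm_mm = st$t_ecm_mm, t_asm_mm = st$t_asm_mm,
    t_submucosa_histo_mm = sub_h, t_submucosa_ebus_mm = sub_e,
    scale_factor = sc$scale_factor,
    shrinkage_pct = shrinkage_pct(sub_e, sub_h),
    ecm_pct_of_l2 = ifelse(keep, comp$ecm_pct_of_l2, NA_real_),
    asm_pct_of_l2 = ifelse(keep, comp$asm_pct_of_l2, NA_real_),
    clamped = ifelse(keep, comp$clamped, NA)
  )
  out
}
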