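#' Internal perimeter of an airway contour
#'
#' Polyline length of a lumen (or interface) contour. Closed contours return
#' the closed polygon perimeter with a subtended angle of 360 degrees; open
#' contours (partial scans, detected from anomalously long edges) return the
#' summed visible arc length and the angular extent actually covered about
#' the contour center.
#'
#' @param contour n x 2 matrix of points, mm.
#' @param center Optional ray/angle origin in mm. Defaults to the polygon
#'   centroid for closed contours and to a least-squares circle-fit center
#'   for open ones.
#' @return List with \code{perimeter_mm}, \code{subtended_deg},
#'   \code{closed}.
#' @export
measure_perimeter <- function(contour, center = NULL) {
  p <- .as_contour(contour)
  len_all <- .edge_lengths(p, closed = TRUE)
  if (any(len_all[-length(len_all)] < 1e-12))
    stop("degenerate contour: duplicate consecutive points")
  closed <- .is_closed_contour(p)
  if (is.null(center))
    center <- if (closed) .polygon_centroid(p) else .circle_fit(p)
  if (closed) {
    return(list(perimeter_mm = sum(len_all), subtended_deg = 360,
                closed = TRUE))
  }
  cov <- .angular_coverage(p, center)
  med <- stats::median(len_all)
  keep <- len_all <= .gap_factor * med
  list(perimeter_mm = sum(len_all[keep]),
       subtended_deg = cov$coverage, closed = FALSE)
}

#' Mean of two perpendicular diameters
#'
#' The airway diameter convention used on radial images: the longest chord
#' through the contour center, averaged with the chord perpendicular to it
#' through the same center. Chords are evaluated from the polar radius
#' profile of the contour (valid for star-shaped airway sections). On open
#' contours covering at least 180 degrees, a chord endpoint lying in the
#' hidden arc is completed by point symmetry about the circle-fit center;
#' below 180 degrees of coverage the diameter is undefined and rejected.
#'
#' @inheritParams measure_perimeter
#' @param angle_step_deg Search grid resolution for the longest chord.
#' @return Diameter in mm.
#' @export
measure_diameter <- function(contour, center = NULL, angle_step_deg = 0.25) {
  p <- .as_contour(contour)
  closed <- .is_closed_contour(p)
  if (is.null(center))
    center <- if (closed) .polygon_centroid(p) else .circle_fit(p)
  if (!closed) {
    cov <- .angular_coverage(p, center)$coverage
    if (cov < 180)
      stop("diameters are undefined for contours covering < 180 degrees")
  }
  v <- sweep(p, 2L, center)
  ang <- (atan2(v[, 2L], v[, 1L]) * 180 / base::pi) %% 360
  rad <- sqrt(rowSums(v^2))
  o <- order(ang)
  ang <- ang[o]; rad <- rad[o]
  rfun <- function(q) stats::approx(c(ang - 360, ang, ang + 360), rep(rad, 3L),
                                    xout = q %% 360, rule = 2)$y
  grid <- seq(0, 180 - angle_step_deg, by = angle_step_deg)
  if (closed) {
    chord <- rfun(grid) + rfun(grid + 180)
  } else {
    # a chord endpoint in the hidden arc is completed by point symmetry
    # about the fitted center (exact for circular sections)
    spans <- .covered_spans(p, center)
    both <- seq(0, 360 - angle_step_deg, by = angle_step_deg)
    cov <- vapply(both, .angle_in_spans, logical(1L), spans = spans)
    half <- function(g) {
      c1 <- cov[match(g %% 360, both)]
      c2 <- cov[match((g + 180) %% 360, both)]
      ifelse(c1 & c2, rfun(g) + rfun(g + 180),
             ifelse(c1, 2 * rfun(g), ifelse(c2, 2 * rfun(g + 180), NA_real_)))
    }
    chord <- half(grid)
    if (all(is.na(chord)))
      stop("no diameter direction covered")
  }
  i <- which.max(chord)
  perp <- chord[(i - 1L + round(90 / angle_step_deg)) %% length(grid) + 1L]
  if (is.na(perp))
    stop("perpendicular diameter direction not covered")
  (chord[i] + perp) / 2
}

#' Lumen (or enclosed) area of a closed contour
#'
#' Shoelace polygon area, orientation independent. Self-intersecting
#' contours are rejected: star-shaped contours pass a fast monotone-angle
#' test, anything else is checked by exact pairwise segment intersection.
#'
#' @inheritParams measure_perimeter
#' @return Area in mm^2.
#' @export
measure_lumen_area <- function(contour) {
  p <- .as_contour(contour)
  if (!.is_closed_contour(p))
    stop("area requires a closed contour")
  a <- .shoelace_area(p)
  if (abs(a) < .Machine$double.eps * 100)
    stop("degenerate contour: zero enclosed area")
  ctr <- .polygon_centroid(p)
  if (!.is_star_shaped(p, ctr) && !.is_simple_polygon(p))
    stop("self-intersecting contour rejected")
  abs(a)
}

#' Mean layer thickness at predetermined radial sites
#'
#' Thickness of the layer between two nested contours, measured as the radial
#' distance between their crossings along rays cast from the inner-contour
#' center at predetermined angles (default: 5 sites every 72 degrees starting
#' at 0, the convention for caliper placement on radial ultrasound images).
#' Sites falling in an uncovered arc of either contour are skipped and
#' counted; the mean is taken over the usable sites only.
#'
#' @param inner,outer Nested contours (n x 2 matrices, mm).
#' @param sites Site angles in degrees.
#' @param center Ray origin; defaults to the inner-contour centroid (circle
#'   fit when the inner contour is open).
#' @return List with \code{thickness_mm} (mean), \code{per_site_mm},
#'   \code{sites_used_deg}, \code{n_skipped}.
#' @export
measure_layer_thickness <- function(inner, outer,
                                    sites = seq(0, 288, by = 72),
                                    center = NULL) {
  pin <- .as_contour(inner, "inner")
  pout <- .as_contour(outer, "outer")
  in_closed <- .is_closed_contour(pin)
  out_closed <- .is_closed_contour(pout)
  if (is.null(center))
    center <- if (in_closed) .polygon_centroid(pin) else .circle_fit(pin)
  spans_in <- if (in_closed) matrix(c(0, 360), 1L) else .covered_spans(pin, center)
  spans_out <- if (out_closed) matrix(c(0, 360), 1L) else .covered_spans(pout, center)

  vals <- rep(NA_real_, length(sites))
  for (i in seq_along(sites)) {
    th <- sites[i]
    if (!.angle_in_spans(th, spans_in) || !.angle_in_spans(th, spans_out))
      next
    ri <- .ray_radius(pin, center, th, closed = in_closed)
    ro <- .ray_radius(pout, center, th, closed = out_closed)
    if (is.na(ri) || is.na(ro)) next
    if (ro < ri - 1e-9)
      stop("contours are not nested at site ", th, " degrees")
    vals[i] <- ro - ri
  }
  used <- !is.na(vals)
  if (!any(used)) stop("no usable thickness site on the covered angles")
  list(thickness_mm = mean(vals[used]), per_site_mm = vals,
       sites_used_deg = sites[used], n_skipped = sum(!used))
}

#' Area of the layer between two nested closed contours
#'
#' @inheritParams measure_layer_thickness
#' @return Area in mm^2 (outer area minus inner area).
#' @export
measure_layer_area <- function(inner, outer) {
  ai <- measure_lumen_area(inner)
  ao <- measure_lumen_area(outer)
  if (ao < ai - 1e-9 * max(ai, 1))
    stop("contours are not nested: outer area smaller than inner area")
  max(ao - ai, 0)
}

#' Proportional completion of a partial-scan measurement
#'
#' When only part of the airway circumference is interpretable, arc-length
#' and area measurements taken on the visible sector are transformed into
#' full-circumference values proportionally (\code{value * 360 / angle}).
#' Thickness site-means are averages and must not be completed.
#'
#' @param value Measured quantity on the visible sector.
#' @param subtended_angle Covered angle in degrees, in (0, 360].
#' @param kind One of \code{"arc_length"}, \code{"area"} (same rule; the
#'   argument documents intent and guards against passing thickness means).
#' @return Completed value.
#' @export
complete_partial <- function(value, subtended_angle,
                             kind = c("arc_length", "area")) {
  kind <- match.arg(kind)
  if (!is.numeric(subtended_angle) || any(subtended_angle <= 0) ||
      any(subtended_angle > 360))
    stop("'subtended_angle' must be in (0, 360]")
  value * 360 / subtended_angle
}

#' Quality-control exclusion rules for morphometry records
#'
#' Applies the study's image-exclusion rules. Ultrasound records are excluded
#' when the bronchial wall is not identifiable over more than 180 degrees.
#' Histology records are excluded when the section quality score is 1, or
#' when it is 2 and the missing angle is 90 degrees or more.
#'
#' @param records Data frame with columns \code{modality} ("ebus" or
#'   "histology"), \code{missing_angle_deg}, and \code{quality_score} (1-4,
#'   required for histology rows).
#' @param missing_angle_max Ultrasound missing-angle threshold, degrees.
#' @param score2_angle_max Histology score-2 missing-angle threshold, degrees.
#' @return \code{records} with logical \code{excluded} and character
#'   \code{exclude_reason} columns filled in.
#' @export
qc_filter <- function(records, missing_angle_max = 180,
                      score2_angle_max = 90) {
  req <- c("modality", "missing_angle_deg")
  if (!all(req %in% names(records)))
    stop("records must have columns: ", paste(req, collapse = ", "))
  mod <- tolower(as.character(records$modality))
  if (!all(mod %in% c("ebus", "histology")))
    stop("modality must be 'ebus' or 'histology'")
  ma <- records$missing_angle_deg
  if (anyNA(ma) || any(ma < 0 | ma >= 360))
    stop("missing_angle_deg must be in [0, 360)")
  if (any(mod == "histology")) {
    if (!"quality_score" %in% names(records) ||
        anyNA(records$quality_score[mod == "histology"]))
      stop("histology records require a quality_score (1-4)")
  }
  qs <- if ("quality_score" %in% names(records)) records$quality_score else
    rep(NA_integer_, nrow(records))

  excluded <- logical(nrow(records))
  reason <- rep(NA_character_, nrow(records))

  i <- mod == "ebus" & ma > missing_angle_max
  excluded[i] <- TRUE
  reason[i] <- sprintf("missing angle > %g deg", missing_angle_max)
  i <- mod == "histology" & !is.na(qs) & qs == 1L
  excluded[i] <- TRUE
  reason[i] <- "quality score 1"
  i <- mod == "histology" & !is.na(qs) & qs == 2L & ma >= score2_angle_max
  excluded[i] <- TRUE
  reason[i] <- sprintf("quality score 2 with missing angle >= %g deg",
                       score2_angle_max)

  records$excluded <- excluded
  records$exclude_reason <- reason
  records
}

#' Size-normalized remodeling indices
#'
#' Adds the perimeter-normalized indices to a record table: the second-layer
#' area divided by Pi (mm) and by Pi squared (unitless), and the smooth
#' muscle area divided by Pi squared for histology rows. Division by Pi
#' accounts for the larger absolute wall mass of larger airways; Pi squared
#' makes the index scale free.
#'
#' @param records Data frame with \code{pi_mm} and, where available,
#'   \code{l2_area_mm2} and/or \code{a_asm_mm2}.
#' @return \code{records} with \code{l2_area_over_pi},
#'   \code{l2_area_over_pi2}, \code{a_asm_over_pi2} filled (NA where the
#'   source area is absent).
#' @export
compute_indices <- function(records) {
  if (!"pi_mm" %in% names(records)) stop("records must have a pi_mm column")
  if (any(!is.na(records$pi_mm) & records$pi_mm <= 0))
    stop("pi_mm must be > 0 to form normalized indices")
  getcol <- function(nm) if (nm %in% names(records)) records[[nm]] else
    rep(NA_real_, nrow(records))
  l2a <- getcol("l2_area_mm2")
  asm <- getcol("a_asm_mm2")
  records$l2_area_over_pi <- l2a / records$pi_mm
  records$l2_area_over_pi2 <- l2a / records$pi_mm^2
  records$a_asm_over_pi2 <- asm / records$pi_mm^2
  records
}

#' Airway size classes from the internal perimeter
#'
#' Two classifications used for size-stratified contrasts: a two-way split
#' (intermediate: Pi <= 31 mm; large: Pi > 31 mm) and a three-way split with
#' right-closed intervals (0, 16], (16, 31], (31, Inf) mm.
#'
#' @param pi_mm Numeric vector of internal perimeters, mm (> 0).
#' @param bounds Class boundaries c(16, 31) mm.
#' @return Data frame with factor columns \code{two_way}
#'   (intermediate/large) and \code{three_way} (small/mid/large).
#' @export
classify_size <- function(pi_mm, bounds = c(16, 31)) {
  if (any(!is.na(pi_mm) & pi_mm <= 0)) stop("pi_mm must be > 0")
  two <- factor(ifelse(pi_mm <= bounds[2L], "intermediate", "large"),
                levels = c("intermediate", "large"))
  three <- cut(pi_mm, breaks = c(0, bounds, Inf),
               labels = c("small", "mid", "large"), right = TRUE)
  data.frame(two_way = two, three_way = three)
}

#' Measure an airway phantom as one morphometry record
#'
#' Runs the full per-image measurement set on a phantom's contours: internal
#' perimeter, mean of two perpendicular diameters, lumen area, first- and
#' second-layer thickness (5-site means) and second-layer area for the
#' ultrasound view, or matrix/muscle areas for the histology view. Partial
#' scans have perimeter and areas proportionally completed from the subtended
#' angle; thickness site-means are left as averages over the usable sites.
#'
#' @param phantom An \code{airway_phantom} with at least two layers.
#' @param modality \code{"ebus"} or \code{"histology"}.
#' @param quality_score Histology section quality score (1-4).
#' @return One-row data frame in the standard record schema (see
#'   \code{\link{write_records}}).
#' @export
measure_phantom <- function(phantom, modality = c("ebus", "histology"),
                            quality_score = 4L) {
  stopifnot(inherits(phantom, "airway_phantom"))
  modality <- match.arg(modality)
  if (length(phantom$interface_contours) < 2L)
    stop("phantom must have at least two layers")
  ctr <- phantom$center
  lum <- phantom$lumen_contour
  if1 <- phantom$interface_contours[[1L]]
  if2 <- phantom$interface_contours[[2L]]

  per <- measure_perimeter(lum, center = ctr)
  ang <- per$subtended_deg
  pi_mm <- complete_partial(per$perimeter_mm, ang, "arc_length")
  d_mm <- if (ang >= 180) measure_diameter(lum, center = ctr) else NA_real_
  if (per$closed) {
    la <- measure_lumen_area(lum)
    a1 <- measure_layer_area(lum, if1)
    a2 <- measure_layer_area(if1, if2)
  } else {
    # partial scans: reconstruct areas from the annulus between visible arcs
    # is not supported; report the completed lumen area via the sector rule
    la <- NA_real_
    a1 <- NA_real_
    a2 <- NA_real_
  }
  t1 <- measure_layer_thickness(lum, if1, center = ctr)$thickness_mm
  t2 <- measure_layer_thickness(if1, if2, center = ctr)$thickness_mm

  rec <- data.frame(
    modality = modality,
    pi_mm = pi_mm, d_mm = d_mm, la_mm2 = la,
    l1_mm = NA_real_, l2_mm = NA_real_, l2_area_mm2 = NA_real_,
    a_asm_mm2 = NA_real_, a_ecm_mm2 = NA_real_,
    missing_angle_deg = 360 - ang,
    quality_score = if (modality == "histology") as.integer(quality_score)
                    else NA_integer_,
    l2_area_over_pi = NA_real_, l2_area_over_pi2 = NA_real_,
    a_asm_over_pi2 = NA_real_,
    excluded = FALSE, exclude_reason = NA_character_
  )
  if (modality == "ebus") {
    rec$l1_mm <- t1; rec$l2_mm <- t2; rec$l2_area_mm2 <- a2
  } else {
    rec$a_ecm_mm2 <- a1; rec$a_asm_mm2 <- a2
  }
  compute_indices(qc_filter(rec))
}
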