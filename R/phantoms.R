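#' Synthetic airway phantom with known ground truth
#'
#' Builds a layered airway cross-section from the ellipse-perturbed-circle
#' family: a lumen boundary of prescribed internal perimeter plus outward
#' constant-thickness (parallel-offset) layer interfaces. Because offsets of a
#' convex curve have closed-form perimeter (\eqn{L + 2\pi t}) and area
#' (\eqn{A + tL + \pi t^2}), every geometric truth value is analytic and the
#' phantom can serve as an oracle for contour-based measurement.
#'
#' The radial-ultrasound reading of the layers is: lumen boundary, then the
#' outer edge of the first (hyperechoic, epithelium + inner extracellular
#' matrix) layer L1, then the outer edge of the second (hypoechoic, remaining
#' matrix + airway smooth muscle) layer L2.
#'
#' @param pi_mm Target internal perimeter of the lumen boundary, mm (> 0).
#' @param layer_thicknesses Numeric vector of layer thicknesses, mm (>= 0),
#'   from the innermost layer outward.
#' @param eccentricity Shape parameter in [0, 0.5]; semi-axes are
#'   \code{r * (1 + e)} and \code{r * (1 - e)}, so 0 gives a circle.
#' @param n_points Vertices per contour (>= 64).
#' @param seed Optional integer; randomizes the (physically arbitrary)
#'   orientation of the ellipse. Identical seeds give identical phantoms.
#' @return An object of class \code{airway_phantom}: list with
#'   \code{lumen_contour}, \code{interface_contours} (named list, innermost
#'   outward), \code{center}, \code{coverage_deg}, and \code{truth} (list with
#'   \code{pi_mm}, \code{d_mm}, \code{la_mm2}, \code{thickness_mm},
#'   \code{area_mm2}, \code{interface_perimeter_mm}).
#' @examples
#' ph <- make_airway_phantom(2 * pi, c(0.1, 0.2), n_points = 720)
#' ph$truth$la_mm2   # pi, the unit-circle lumen area
#' @export
make_airway_phantom <- function(pi_mm, layer_thicknesses = c(0.11, 0.18),
                                eccentricity = 0, n_points = 720L,
                                seed = NULL) {
  if (!is.numeric(pi_mm) || length(pi_mm) != 1L || pi_mm <= 0)
    stop("'pi_mm' must be a single positive perimeter in mm")
  if (length(layer_thicknesses) < 1L || any(layer_thicknesses < 0))
    stop("invalid geometry: layer thicknesses must be >= 0")
  if (n_points < 64L)
    stop("invalid geometry: 'n_points' must be >= 64")
  if (eccentricity < 0 || eccentricity > 0.5)
    stop("'eccentricity' must be in [0, 0.5]")

  ax <- 1 + eccentricity
  bx <- 1 - eccentricity
  unit_len <- .ellipse_perimeter(ax, bx)
  r0 <- pi_mm / unit_len
  a <- r0 * ax
  b <- r0 * bx

  phi <- 0
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(as.integer(seed))
    phi <- stats::runif(1, 0, 2 * base::pi)
  }
  rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2L)

  tp <- seq(0, 2 * base::pi, length.out = n_points + 1L)[-(n_points + 1L)]
  base_pts <- cbind(a * cos(tp), b * sin(tp))
  nrm <- cbind(b * cos(tp), a * sin(tp))
  nrm <- nrm / sqrt(rowSums(nrm^2))

  offsets <- cumsum(layer_thicknesses)
  lumen <- base_pts %*% t(rot)
  interfaces <- lapply(offsets, function(o) (base_pts + o * nrm) %*% t(rot))
  names(interfaces) <- paste0("interface_", seq_along(interfaces))

  la <- base::pi * a * b
  inner_per <- c(pi_mm, pi_mm + 2 * base::pi * offsets)
  areas <- layer_thicknesses * inner_per[seq_along(layer_thicknesses)] +
    base::pi * layer_thicknesses^2

  structure(list(
    lumen_contour = lumen,
    interface_contours = interfaces,
    center = c(0, 0),
    coverage_deg = 360,
    hidden_arc = NULL,
    n_points = as.integer(n_points),
    truth = list(
      pi_mm = pi_mm,
      d_mm = a + b,
      la_mm2 = la,
      thickness_mm = as.numeric(layer_thicknesses),
      area_mm2 = as.numeric(areas),
      interface_perimeter_mm = inner_per[-1L],
      semi_axes = c(a, b),
      rotation_rad = phi
    )
  ), class = "airway_phantom")
}

# High-accuracy ellipse perimeter by dense arclength quadrature.
.ellipse_perimeter <- function(a, b, n = 200000L) {
  th <- seq(0, base::pi / 2, length.out = n)
  f <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  h <- th[2L] - th[1L]
  4 * (h * (sum(f) - (f[1L] + f[n]) / 2))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.airway_phantom <- function(x, ...) {
  cat("airway phantom:",
      sprintf("Pi = %.3f mm, D = %.3f mm, LA = %.3f mm^2", x$truth$pi_mm,
              x$truth$d_mm, x$truth$la_mm2), "\n")
  cat(sprintf("  %d layers (thickness mm: %s), coverage %.1f deg, %d pts/contour\n",
              length(x$truth$thickness_mm),
              paste(signif(x$truth$thickness_mm, 4), collapse = ", "),
              x$coverage_deg, x$n_points))
  invisible(x)
}

#' Hide an angular sector of a phantom
#'
#' Removes contour points inside a hidden arc, emulating the part of an
#' ultrasound or histology image where the bronchial wall cannot be traced.
#' Ground truth is unchanged; only the visible point set and the coverage
#' metadata are updated.
#'
#' @param phantom An \code{airway_phantom}.
#' @param hidden_arc Either a single width in degrees (arc starts at 0) or a
#'   \code{c(from, to)} interval in degrees; width must be < 360. Zero width
#'   returns the phantom unchanged.
#' @return The phantom with points in the arc removed and
#'   \code{coverage_deg} reduced accordingly.
#' @export
apply_missing_angle <- function(phantom, hidden_arc) {
  stopifnot(inherits(phantom, "airway_phantom"))
  if (length(hidden_arc) == 1L) hidden_arc <- c(0, hidden_arc)
  if (length(hidden_arc) != 2L || anyNA(hidden_arc))
    stop("'hidden_arc' must be a width or a c(from, to) interval in degrees")
  width <- (hidden_arc[2L] - hidden_arc[1L]) %% 360
  if (width == 0 && hidden_arc[2L] != hidden_arc[1L])
    stop("hidden arc covering the full 360 degrees leaves an empty contour")
  if (width == 0) return(phantom)

  from <- hidden_arc[1L] %% 360
  to <- hidden_arc[2L] %% 360
  keep <- function(p) {
    v <- sweep(p, 2L, phantom$center)
    th <- (atan2(v[, 2L], v[, 1L]) * 180 / base::pi) %% 360
    inside <- if (from <= to) th >= from & th < to else th >= from | th < to
    if (all(inside)) stop("hidden arc removes an entire contour")
    p[!inside, , drop = FALSE]
  }
  phantom$lumen_contour <- keep(phantom$lumen_contour)
  phantom$interface_contours <- lapply(phantom$interface_contours, keep)
  phantom$coverage_deg <- phantom$coverage_deg - width
  phantom$hidden_arc <- c(from, to)
  phantom
}
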