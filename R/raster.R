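#' Rasterize an airway phantom into a grayscale image
#'
#' Renders the phantom on a pixel grid: each pixel takes the intensity of the
#' innermost wall layer containing it, mimicking the alternating
#' hyper-/hypoechoic rings of a radial ultrasound scan. The lumen interior and
#' the region outside the outermost interface are background (0). Pixels whose
#' polar angle falls in a hidden arc are also background, so partial scans
#' rasterize as partial rings.
#'
#' @param phantom An \code{airway_phantom}.
#' @param mm_per_px Pixel size in mm (> 0).
#' @param layer_intensities Gray level per wall layer, innermost first; must
#'   have one value per layer.
#' @param noise_sd Additive Gaussian pixel noise SD in gray levels.
#' @param seed Optional integer seed for the noise.
#' @return Object of class \code{airway_image}: list with \code{pixels}
#'   (matrix, rows = y increasing upward), \code{mm_per_px},
#'   \code{center_px} (x, y of the phantom center in pixel units) and
#'   \code{origin_mm} (mm coordinates of the lower-left pixel corner).
#' @export
rasterize_phantom <- function(phantom, mm_per_px, layer_intensities,
                              noise_sd = 0, seed = NULL) {
  stopifnot(inherits(phantom, "airway_phantom"))
  if (!is.numeric(mm_per_px) || mm_per_px <= 0)
    stop("'mm_per_px' must be > 0")
  n_layers <- length(phantom$interface_contours)
  if (length(layer_intensities) != n_layers)
    stop("'layer_intensities' must supply one gray level per layer")

  outer <- phantom$interface_contours[[n_layers]]
  margin <- 2 * mm_per_px
  xr <- range(outer[, 1L]) + c(-margin, margin)
  yr <- range(outer[, 2L]) + c(-margin, margin)
  nx <- ceiling(diff(xr) / mm_per_px)
  ny <- ceiling(diff(yr) / mm_per_px)

  xs <- xr[1L] + (seq_len(nx) - 0.5) * mm_per_px
  ys <- yr[1L] + (seq_len(ny) - 0.5) * mm_per_px
  gx <- rep(xs, each = ny)
  gy <- rep(ys, times = nx)

  ctr <- phantom$center
  dx <- gx - ctr[1L]; dy <- gy - ctr[2L]
  r <- sqrt(dx^2 + dy^2)
  th <- (atan2(dy, dx) * 180 / base::pi) %% 360

  # boundary radius lookup by periodic interpolation of vertex polar radii;
  # valid because the phantom family is star-shaped about its center
  radius_fun <- function(p) {
    v <- sweep(p, 2L, ctr)
    ang <- (atan2(v[, 2L], v[, 1L]) * 180 / base::pi) %% 360
    o <- order(ang)
    ang <- ang[o]; rad <- sqrt(rowSums(v^2))[o]
    function(q) stats::approx(c(ang - 360, ang, ang + 360),
                              rep(rad, 3L), xout = q, rule = 2)$y
  }
  full_boundaries <- c(list(phantom$lumen_contour), phantom$interface_contours)
  bound_r <- lapply(full_boundaries, radius_fun)

  img <- numeric(length(gx))
  r_lumen <- bound_r[[1L]](th)
  prev <- r_lumen
  for (k in seq_len(n_layers)) {
    rk <- bound_r[[k + 1L]](th)
    img[r >= prev & r < rk] <- layer_intensities[k]
    prev <- rk
  }
  if (!is.null(phantom$hidden_arc)) {
    from <- phantom$hidden_arc[1L]; to <- phantom$hidden_arc[2L]
    inarc <- if (from <= to) th >= from & th < to else th >= from | th < to
    img[inarc] <- 0
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
      set.seed(as.integer(seed))
    }
    img <- img + stats::rnorm(length(img), 0, noise_sd)
  }

  structure(list(
    pixels = matrix(img, nrow = ny, ncol = nx),
    mm_per_px = mm_per_px,
    center_px = c((ctr[1L] - xr[1L]) / mm_per_px,
                  (ctr[2L] - yr[1L]) / mm_per_px),
    origin_mm = c(xr[1L], yr[1L])
  ), class = "airway_image")
}

#' @export
print.airway_image <- function(x, ...) {
  cat(sprintf("airway image: %d x %d px at %.4f mm/px\n",
              ncol(x$pixels), nrow(x$pixels), x$mm_per_px))
  invisible(x)
}

#' Segment layer boundaries from a radial intensity image
#'
#' Casts rays outward from the lumen center and records the radii where the
#' intensity jumps by more than \code{min_jump}, grouping the crossings by
#' transition order into per-interface contours. This is the programmatic
#' stand-in for manual boundary tracing on ultrasound stills.
#'
#' @param image An \code{airway_image} (or a plain matrix, in which case
#'   \code{center} and \code{mm_per_px} must be supplied).
#' @param center Ray origin in mm; defaults to the image metadata center.
#' @param n_rays Number of equally spaced rays (>= 36). Boundary radii are
#'   pixel-quantized, so ray spacing finer than about 2 px of arc inflates
#'   the traced polygon perimeter by zigzag noise; keep
#'   \code{n_rays} below \code{pi * lumen_diameter / (2 * mm_per_px)} when
#'   the contours feed perimeter measurements.
#' @param min_jump Minimum absolute intensity change treated as a boundary.
#' @param mm_per_px Pixel size when \code{image} is a bare matrix.
#' @return List with \code{contours} (list of n x 2 matrices in mm, innermost
#'   interface first), \code{ray_angles_deg}, \code{missing} (logical per ray:
#'   fewer transitions than expected), \code{n_interfaces}.
#' @export
segment_radial <- function(image, center = NULL, n_rays = 360L,
                           min_jump = 10, mm_per_px = NULL) {
  if (inherits(image, "airway_image")) {
    px <- image$pixels
    mm_per_px <- image$mm_per_px
    if (is.null(center))
      center <- image$origin_mm + image$center_px * mm_per_px
    origin <- image$origin_mm
  } else {
    px <- as.matrix(image)
    if (is.null(mm_per_px) || is.null(center))
      stop("matrix input needs 'center' and 'mm_per_px'")
    origin <- c(0, 0)
  }
  if (n_rays < 36L) stop("'n_rays' must be >= 36")

  ny <- nrow(px); nx <- ncol(px)
  rmax <- sqrt((nx * mm_per_px)^2 + (ny * mm_per_px)^2)
  rs <- seq(mm_per_px / 2, rmax, by = mm_per_px / 2)
  angs <- seq(0, 360, length.out = n_rays + 1L)[-(n_rays + 1L)]

  crossings <- vector("list", n_rays)
  for (i in seq_len(n_rays)) {
    th <- angs[i] * base::pi / 180
    x <- center[1L] + rs * cos(th)
    y <- center[2L] + rs * sin(th)
    cx <- ceiling((x - origin[1L]) / mm_per_px)
    cy <- ceiling((y - origin[2L]) / mm_per_px)
    ok <- cx >= 1L & cx <= nx & cy >= 1L & cy <= ny
    val <- rep(0, length(rs))
    val[ok] <- px[cbind(cy[ok], cx[ok])]
    jump <- which(abs(diff(val)) > min_jump)
    crossings[[i]] <- (rs[jump] + rs[jump + 1L]) / 2
  }

  counts <- lengths(crossings)
  if (mean(counts == 0L) > 0.5)
    stop("segmentation failure: no intensity transitions on more than half of the rays")
  n_if <- as.integer(names(which.max(table(counts[counts > 0L]))))
  missing <- counts < n_if

  contours <- vector("list", n_if)
  for (k in seq_len(n_if)) {
    use <- which(counts >= k)
    pts <- t(vapply(use, function(i) {
      r <- crossings[[i]][k]
      c(center[1L] + r * cos(angs[i] * base::pi / 180),
        center[2L] + r * sin(angs[i] * base::pi / 180))
    }, numeric(2L)))
    contours[[k]] <- pts
  }
  names(contours) <- c("lumen", paste0("interface_", seq_len(n_if - 1L)))[seq_len(n_if)]

  list(contours = contours, ray_angles_deg = angs, missing = missing,
       n_interfaces = n_if)
}
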