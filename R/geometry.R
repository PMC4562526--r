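# Internal planar-geometry helpers shared by the phantom generator and the
# contour measurement functions. Contours are n x 2 matrices in mm, stored
# counterclockwise; closed contours do not repeat the first point.

.as_contour <- function(x, arg = "contour") {
  x <- as.matrix(x)
  if (ncol(x) != 2L || nrow(x) < 3L)
    stop(sprintf("'%s' must be a matrix of >= 3 points with 2 columns", arg))
  if (anyNA(x) || any(!is.finite(x)))
    stop(sprintf("'%s' contains non-finite points", arg))
  storage.mode(x) <- "double"
  unname(x)
}

.edge_lengths <- function(p, closed = TRUE) {
  idx <- if (closed) c(seq_len(nrow(p))[-1L], 1L) else seq_len(nrow(p))[-1L]
  from <- if (closed) p else p[-nrow(p), , drop = FALSE]
  sqrt(rowSums((p[idx, , drop = FALSE] - from)^2))
}

.shoelace_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  0.5 * sum(x * yn - xn * y)
}

# Area-weighted centroid of a simple closed polygon.
.polygon_centroid <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- 0.5 * sum(cr)
  if (abs(a) < .Machine$double.eps * 100)
    stop("degenerate contour: zero enclosed area")
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Kasa least-squares circle fit; exact for points on a circle. Used to find a
# sensible ray origin for open (partial-coverage) contours.
.circle_fit <- function(p) {
  A <- cbind(2 * p[, 1L], 2 * p[, 2L], 1)
  b <- rowSums(p^2)
  sol <- qr.solve(A, b)
  c(sol[1L], sol[2L])
}

# Detect whether a contour is closed: a hidden arc shows up as one or more
# edges much longer than the typical vertex spacing.
.gap_factor <- 5

.is_closed_contour <- function(p) {
  len <- .edge_lengths(p, closed = TRUE)
  max(len) <= .gap_factor * stats::median(len)
}

# Covered angular extent (degrees) of a contour about `center`: the sum of
# per-edge angular steps, skipping gap edges. Also returns the gap intervals.
.angular_coverage <- function(p, center) {
  len <- .edge_lengths(p, closed = TRUE)
  med <- stats::median(len)
  v <- sweep(p, 2L, center)
  th <- atan2(v[, 2L], v[, 1L]) * 180 / pi
  thn <- c(th[-1L], th[1L])
  step <- (thn - th) %% 360
  step <- pmin(step, 360 - step)  # unsigned step in [0, 180]
  gap <- len > .gap_factor * med
  covered <- sum(step[!gap])
  # a single gap wider than 180 degrees is not captured by the unsigned step,
  # so report coverage as the covered sum directly (gaps contribute nothing)
  list(coverage = min(covered, 360), gaps = which(gap))
}

# Radii at which a ray from `center` at `theta_deg` crosses polygon edges.
# Exact segment intersection; returns numeric(0) when the ray misses.
.ray_crossings <- function(p, center, theta_deg, closed = TRUE) {
  th <- theta_deg * pi / 180
  d <- c(cos(th), sin(th))
  a <- sweep(p, 2L, center)
  if (closed) {
    b <- a[c(seq_len(nrow(a))[-1L], 1L), , drop = FALSE]
  } else {
    b <- a[-1L, , drop = FALSE]
    a <- a[-nrow(a), , drop = FALSE]
  }
  e <- b - a
  den <- d[1L] * e[, 2L] - d[2L] * e[, 1L]
  ok <- abs(den) > 1e-14
  if (!any(ok)) return(numeric(0))
  a <- a[ok, , drop = FALSE]; e <- e[ok, , drop = FALSE]; den <- den[ok]
  t <- (a[, 1L] * e[, 2L] - a[, 2L] * e[, 1L]) / den
  s <- (a[, 1L] * d[2L] - a[, 2L] * d[1L]) / -den
  hit <- t > 1e-12 & s >= -1e-12 & s < 1 - 1e-12
  sort(t[hit])
}

# Outermost crossing radius, NA when the ray misses the contour.
.ray_radius <- function(p, center, theta_deg, closed = TRUE) {
  r <- .ray_crossings(p, center, theta_deg, closed)
  if (length(r) == 0L) NA_real_ else max(r)
}

# Star-shaped test about a center: polar angles strictly monotone (mod 360).
.is_star_shaped <- function(p, center) {
  v <- sweep(p, 2L, center)
  th <- atan2(v[, 2L], v[, 1L])
  dd <- diff(th)
  dd <- c(dd, th[1L] - th[length(th)])
  dd <- (dd + pi) %% (2 * pi) - pi
  all(dd > 0) || all(dd < 0)
}

# Full O(n^2) simple-polygon check, only used when the star test fails.
.is_simple_polygon <- function(p) {
  n <- nrow(p)
  a1 <- p
  b1 <- p[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]  # skip edges sharing a vertex
    if (!length(js)) next
    if (any(.segments_cross(a1[i, ], b1[i, ], a1[js, , drop = FALSE],
                            b1[js, , drop = FALSE])))
      return(FALSE)
  }
  TRUE
}

.segments_cross <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1
  den <- d1[1L] * (q2[, 2L] - q1[, 2L]) - d1[2L] * (q2[, 1L] - q1[, 1L])
  w <- q1 - matrix(p1, nrow(q1), 2L, byrow = TRUE)
  ok <- abs(den) > 1e-14
  t <- (w[, 1L] * (q2[, 2L] - q1[, 2L]) - w[, 2L] * (q2[, 1L] - q1[, 1L])) / den
  s <- (w[, 1L] * d1[2L] - w[, 2L] * d1[1L]) / den
  ok & t > 1e-12 & t < 1 - 1e-12 & s > 1e-12 & s < 1 - 1e-12
}

# Angular spans (degrees, as [from, to) intervals) covered by a contour about
# a center. Gap edges split the covered set.
.covered_spans <- function(p, center) {
  cov <- .angular_coverage(p, center)
  v <- sweep(p, 2L, center)
  th <- (atan2(v[, 2L], v[, 1L]) * 180 / pi) %% 360
  if (length(cov$gaps) == 0L) return(matrix(c(0, 360), 1L))
  n <- nrow(p)
  spans <- matrix(NA_real_, length(cov$gaps), 2L)
  gaps <- sort(cov$gaps)
  for (k in seq_along(gaps)) {
    # span runs from the end of this gap to the start of the next gap
    from <- th[gaps[k] %% n + 1L]
    nxt <- gaps[if (k == length(gaps)) 1L else k + 1L]
    spans[k, ] <- c(from, th[nxt])
  }
  spans
}

.angle_in_spans <- function(theta_deg, spans) {
  th <- theta_deg %% 360
  for (i in seq_len(nrow(spans))) {
    if (spans[i, 2L] - spans[i, 1L] >= 360) return(TRUE)
    a <- spans[i, 1L] %% 360; b <- spans[i, 2L] %% 360
    inside <- if (a <= b) th >= a - 1e-9 & th <= b + 1e-9
              else th >= a - 1e-9 | th <= b + 1e-9
    if (inside) return(TRUE)
  }
  FALSE
}
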