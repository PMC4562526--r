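# Contour constructors used as independent geometric oracles: built directly
# from parametric curves, not via the phantom generator.

circle_contour <- function(r = 1, n = 720L, center = c(0, 0),
                           theta_range = c(0, 360)) {
  th <- seq(theta_range[1L], theta_range[2L], length.out = n + 1L)
  if (diff(theta_range) >= 360) th <- th[-(n + 1L)]
  th <- th * pi / 180
  cbind(center[1L] + r * cos(th), center[2L] + r * sin(th))
}

ellipse_contour <- function(a, b, n = 720L, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1L] + a * cos(th), center[2L] + b * sin(th))
}

unit_square <- function() {
  rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
}
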