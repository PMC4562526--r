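test_that("perimeter matches polygon closed forms and arc-length oracles", {
  p720 <- circle_contour(1, 720L)
  expect_equal(measure_perimeter(p720)$perimeter_mm, 2 * 720 * sin(pi / 720),
               tolerance = 1e-12)
  expect_equal(measure_perimeter(unit_square())$perimeter_mm, 4.0)
  expect_equal(measure_perimeter(p720)$subtended_deg, 360)

  arc <- circle_contour(1, 720L, theta_range = c(0, 270))
  m <- measure_perimeter(arc)
  expect_false(m$closed)
  expect_equal(m$perimeter_mm, 3 * pi / 2, tolerance = 1e-3)
  expect_equal(m$subtended_deg, 270, tolerance = 0.005)

  expect_error(measure_perimeter(rbind(c(0, 0), c(0, 0), c(1, 1))),
               "duplicate")
  expect_error(measure_perimeter(rbind(c(0, 0), c(1, 1))), ">= 3")
})

test_that("diameter is the mean of the longest chord and its perpendicular", {
  expect_equal(measure_diameter(circle_contour(1, 720L)), 2, tolerance = 5e-3)
  expect_equal(measure_diameter(ellipse_contour(2, 1, 1440L)), 3,
               tolerance = 0.01)
  # brute-force chord oracle on an eccentric phantom
  ph <- make_airway_phantom(20, c(0.2), eccentricity = 0.3, n_points = 1024L)
  a <- ph$truth$semi_axes[1L]; b <- ph$truth$semi_axes[2L]
  r_exact <- function(th) {
    phi <- th * pi / 180 - ph$truth$rotation_rad
    a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
  }
  grid <- seq(0, 179.9, by = 0.1)
  chord <- r_exact(grid) + r_exact(grid + 180)
  i <- which.max(chord)
  oracle <- (chord[i] + chord[(i - 1L + 900L) %% length(grid) + 1L]) / 2
  expect_equal(measure_diameter(ph$lumen_contour), oracle, tolerance = 0.01)
  expect_equal(oracle, ph$truth$d_mm, tolerance = 1e-6)
  # open contour below half coverage has no defined diameter
  expect_error(measure_diameter(circle_contour(1, 720L,
                                               theta_range = c(0, 170))),
               "180")
})

test_that("lumen area follows the shoelace rule and rejects bad contours", {
  expect_equal(measure_lumen_area(unit_square()), 1.0)
  p720 <- circle_contour(1, 720L)
  expect_equal(measure_lumen_area(p720), 0.5 * 720 * sin(2 * pi / 720),
               tolerance = 1e-12)
  expect_equal(measure_lumen_area(p720[rev(seq_len(720L)), ]),
               measure_lumen_area(p720))
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1.5))
  expect_error(measure_lumen_area(bowtie), "self-intersecting")
  expect_error(measure_lumen_area(circle_contour(1, 720L,
                                                 theta_range = c(0, 200))),
               "closed")
})

test_that("layer thickness matches per-ray analytic oracles", {
  inner <- circle_contour(1, 8192L)
  outer <- circle_contour(1.2, 8192L)
  t0 <- measure_layer_thickness(inner, outer)
  expect_equal(t0$thickness_mm, 0.2, tolerance = 5e-3)
  expect_identical(t0$n_skipped, 0L)

  # eccentric annulus: outer circle shifted by 0.05; exact radial distance
  # from the inner center is 0.05 cos(th) + sqrt(R^2 - (0.05 sin(th))^2) - 1
  outer_sh <- circle_contour(1.2, 8192L, center = c(0.05, 0))
  sites <- seq(0, 288, by = 72)
  exact <- 0.05 * cos(sites * pi / 180) +
    sqrt(1.2^2 - (0.05 * sin(sites * pi / 180))^2) - 1
  t1 <- measure_layer_thickness(inner, outer_sh, sites = sites,
                                center = c(0, 0))
  expect_lt(max(abs(t1$per_site_mm - exact)), 1e-6)
  expect_lt(abs(t1$thickness_mm - mean(exact)), 1e-6)

  # a hidden arc drops the site it contains; the mean uses the rest
  ph <- make_airway_phantom(2 * pi, c(0.1, 0.2), n_points = 720L)
  ph_h <- apply_missing_angle(ph, c(30, 120))
  th <- measure_layer_thickness(ph_h$lumen_contour,
                                ph_h$interface_contours[[1L]],
                                center = ph$center)
  expect_identical(th$n_skipped, 1L)
  expect_identical(th$sites_used_deg, c(0, 144, 216, 288))
  expect_equal(th$thickness_mm, 0.1, tolerance = 1e-6)

  expect_error(measure_layer_thickness(outer, inner), "not nested")
})

test_that("layer area is the nested-area difference", {
  expect_equal(measure_layer_area(circle_contour(1, 1024L),
                                  circle_contour(2, 1024L)), 3 * pi,
               tolerance = 2e-3)
  p <- circle_contour(1.5, 256L)
  expect_equal(measure_layer_area(p, p), 0)
  expect_error(measure_layer_area(circle_contour(2, 256L),
                                  circle_contour(1, 256L)), "not nested")
  ph <- make_airway_phantom(18, c(0.2, 0.3), eccentricity = 0.2,
                            n_points = 1024L)
  expect_equal(measure_layer_area(ph$lumen_contour,
                                  ph$interface_contours[[1L]]),
               ph$truth$area_mm2[1L], tolerance = 5e-3)
})

test_that("partial measurements complete proportionally", {
  expect_equal(complete_partial(15, 270, "arc_length"), 20)
  expect_equal(complete_partial(1.23, 360, "area"), 1.23)
  half <- circle_contour(1, 720L, theta_range = c(0, 180))
  m <- measure_perimeter(half)
  expect_equal(complete_partial(m$perimeter_mm, m$subtended_deg), 2 * pi,
               tolerance = 2e-3)
  expect_error(complete_partial(1, 0), "subtended_angle")
  expect_error(complete_partial(1, 361), "subtended_angle")
})

test_that("quality control applies the exclusion rules and is total", {
  recs <- data.frame(
    modality = c(rep("ebus", 6L), rep("histology", 4L)),
    pi_mm = 20,
    missing_angle_deg = c(0, 90, 179, 180, 181, 270, 0, 89, 90, 0),
    quality_score = c(rep(NA, 6L), 1L, 2L, 2L, 4L)
  )
  out <- qc_filter(recs)
  expect_identical(out$excluded,
                   c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                     TRUE, FALSE, TRUE, FALSE))
  # totality: excluded records carry a reason, kept records none
  expect_true(all(!is.na(out$exclude_reason[out$excluded])))
  expect_true(all(is.na(out$exclude_reason[!out$excluded])))
  expect_error(qc_filter(data.frame(modality = "histology", pi_mm = 1,
                                    missing_angle_deg = 0)), "quality_score")
})

test_that("normalized indices follow their definitions and dimensions", {
  r <- data.frame(modality = "ebus", pi_mm = 10, l2_area_mm2 = 2,
                  missing_angle_deg = 0)
  out <- compute_indices(r)
  expect_equal(out$l2_area_over_pi, 0.2)
  expect_equal(out$l2_area_over_pi2, 0.02)

  h <- compute_indices(data.frame(modality = "histology", pi_mm = 18.94,
                                  a_asm_mm2 = 1.599, missing_angle_deg = 0))
  expect_equal(h$a_asm_over_pi2, 1.599 / 18.94^2, tolerance = 1e-12)
  expect_equal(h$a_asm_over_pi2, 0.004458, tolerance = 1e-3)

  # uniform scaling: /Pi index scales by k, /Pi^2 index is invariant
  k <- 3.7
  sc <- compute_indices(data.frame(modality = "ebus", pi_mm = 10 * k,
                                   l2_area_mm2 = 2 * k^2,
                                   missing_angle_deg = 0))
  expect_equal(sc$l2_area_over_pi, out$l2_area_over_pi * k, tolerance = 1e-12)
  expect_equal(sc$l2_area_over_pi2, out$l2_area_over_pi2, tolerance = 1e-12)
  expect_error(compute_indices(data.frame(modality = "ebus", pi_mm = 0,
                                          l2_area_mm2 = 1,
                                          missing_angle_deg = 0)), "pi_mm")
})

test_that("size classes use right-closed boundaries", {
  cl <- classify_size(c(31, 31.01, 16, 15.99, 40))
  expect_identical(as.character(cl$two_way),
                   c("intermediate", "large", "intermediate", "intermediate",
                     "large"))
  expect_identical(as.character(cl$three_way),
                   c("mid", "large", "small", "small", "large"))
  expect_error(classify_size(-1), "pi_mm")
})

test_that("measured n-gon values converge to closed forms", {
  per_err <- area_err <- numeric(0)
  for (n in c(64L, 256L, 1024L)) {
    p <- circle_contour(1, n)
    per_err <- c(per_err, abs(measure_perimeter(p)$perimeter_mm - 2 * pi))
    area_err <- c(area_err, abs(measure_lumen_area(p) - pi))
  }
  expect_true(all(diff(per_err) < 0))
  expect_true(all(diff(area_err) < 0))
})

test_that("measurements are homogeneous under uniform scaling", {
  ph <- make_airway_phantom(22, c(0.2, 0.3), eccentricity = 0.15,
                            n_points = 512L)
  k <- 2.6
  lum <- ph$lumen_contour; i1 <- ph$interface_contours[[1L]]
  i2 <- ph$interface_contours[[2L]]
  expect_equal(measure_perimeter(k * lum)$perimeter_mm,
               k * measure_perimeter(lum)$perimeter_mm, tolerance = 1e-9)
  expect_equal(measure_diameter(k * lum), k * measure_diameter(lum),
               tolerance = 1e-9)
  expect_equal(measure_lumen_area(k * lum), k^2 * measure_lumen_area(lum),
               tolerance = 1e-9)
  expect_equal(measure_layer_thickness(k * lum, k * i1)$thickness_mm,
               k * measure_layer_thickness(lum, i1)$thickness_mm,
               tolerance = 1e-9)
  expect_equal(measure_layer_area(k * i1, k * i2),
               k^2 * measure_layer_area(i1, i2), tolerance = 1e-9)
})

test_that("completed perimeters of partial phantoms stay near the full value", {
  for (ecc in c(0, 0.1, 0.2)) {
    ph <- make_airway_phantom(24, c(0.2), eccentricity = ecc,
                              n_points = 1024L, seed = 11L)
    full <- measure_perimeter(ph$lumen_contour)$perimeter_mm
    for (hide in list(c(10, 100), c(120, 300))) {
      php <- apply_missing_angle(ph, hide)
      m <- measure_perimeter(php$lumen_contour, center = ph$center)
      done <- complete_partial(m$perimeter_mm, m$subtended_deg)
      expect_equal(done, full, tolerance = 0.02)
    }
  }
})
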