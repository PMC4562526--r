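test_that("circle phantom truth matches closed forms and is deterministic", {
  ph <- make_airway_phantom(2 * pi, c(0.1, 0.2), eccentricity = 0,
                            n_points = 720L, seed = 42L)
  expect_equal(ph$truth$pi_mm, 2 * pi, tolerance = 1e-3)
  expect_equal(ph$truth$la_mm2, pi, tolerance = 1e-3)
  expect_equal(ph$truth$d_mm, 2, tolerance = 1e-3)
  # polygon renditions agree with the analytic truth to 0.1%
  expect_equal(measure_perimeter(ph$lumen_contour)$perimeter_mm,
               ph$truth$pi_mm, tolerance = 1e-3)
  expect_equal(measure_lumen_area(ph$lumen_contour), ph$truth$la_mm2,
               tolerance = 1e-3)

  ph2 <- make_airway_phantom(2 * pi, c(0.1, 0.2), eccentricity = 0,
                             n_points = 720L, seed = 42L)
  expect_identical(ph, ph2)
  ph3 <- make_airway_phantom(2 * pi, c(0.1, 0.2), eccentricity = 0.2,
                             n_points = 720L, seed = 43L)
  expect_false(isTRUE(all.equal(ph3$truth$rotation_rad,
                                make_airway_phantom(2 * pi, c(0.1, 0.2),
                                  eccentricity = 0.2, n_points = 720L,
                                  seed = 44L)$truth$rotation_rad)))
})

test_that("layer truth areas equal analytic annulus areas and the shoelace oracle", {
  ph <- make_airway_phantom(18.94, c(0.0833, 0.0762), eccentricity = 0,
                            n_points = 1440L)
  # analytic annulus: pi*(R^2 - r^2) with r = Pi/2pi
  r <- 18.94 / (2 * pi)
  expect_equal(ph$truth$area_mm2[1L], pi * ((r + 0.0833)^2 - r^2),
               tolerance = 1e-12)
  expect_equal(ph$truth$area_mm2[1L], 1.599, tolerance = 2e-3)
  # polygon shoelace cross-check
  shoelace <- function(p) {
    x <- p[, 1L]; y <- p[, 2L]
    0.5 * abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y))
  }
  a1 <- shoelace(ph$interface_contours[[1L]]) - shoelace(ph$lumen_contour)
  expect_equal(a1, ph$truth$area_mm2[1L], tolerance = 2e-3)
})

test_that("elliptical phantoms keep truth consistent with their contours", {
  for (ecc in c(0.1, 0.3, 0.5)) {
    ph <- make_airway_phantom(25, c(0.2, 0.35), eccentricity = ecc,
                              n_points = 1024L, seed = 7L)
    expect_equal(measure_perimeter(ph$lumen_contour)$perimeter_mm,
                 ph$truth$pi_mm, tolerance = 1e-3)
    expect_equal(measure_lumen_area(ph$lumen_contour), ph$truth$la_mm2,
                 tolerance = 1e-3)
    a <- vapply(seq_along(ph$interface_contours), function(k) {
      inner <- if (k == 1L) ph$lumen_contour else
        ph$interface_contours[[k - 1L]]
      measure_layer_area(inner, ph$interface_contours[[k]])
    }, numeric(1L))
    expect_equal(a, ph$truth$area_mm2, tolerance = 1e-3)
  }
})

test_that("phantom construction rejects invalid geometry", {
  expect_error(make_airway_phantom(-1, c(0.1)), "positive")
  expect_error(make_airway_phantom(10, c(-0.1, 0.2)), ">= 0")
  expect_error(make_airway_phantom(10, c(0.1), n_points = 32L), "n_points")
  expect_error(make_airway_phantom(10, c(0.1), eccentricity = 0.7),
               "eccentricity")
})

test_that("contours are nested along random rays", {
  set.seed(99)
  for (ecc in c(0, 0.25, 0.5)) {
    ph <- make_airway_phantom(20, c(0.15, 0.4), eccentricity = ecc,
                              n_points = 512L)
    th <- runif(100, 0, 360)
    r0 <- vapply(th, function(a)
      airwaymorph:::.ray_radius(ph$lumen_contour, ph$center, a), numeric(1L))
    r1 <- vapply(th, function(a)
      airwaymorph:::.ray_radius(ph$interface_contours[[1L]], ph$center, a),
      numeric(1L))
    r2 <- vapply(th, function(a)
      airwaymorph:::.ray_radius(ph$interface_contours[[2L]], ph$center, a),
      numeric(1L))
    expect_true(all(r0 < r1 & r1 < r2))
  }
})

test_that("hiding an arc updates coverage but not truth", {
  ph <- make_airway_phantom(2 * pi, c(0.1, 0.2), n_points = 720L)
  expect_identical(apply_missing_angle(ph, 0), ph)
  ph90 <- apply_missing_angle(ph, 90)
  expect_equal(ph90$coverage_deg, 270)
  expect_identical(ph90$truth, ph$truth)
  expect_lt(nrow(ph90$lumen_contour), nrow(ph$lumen_contour))
  expect_error(apply_missing_angle(ph, c(0, 360)), "360")
})

test_that("a phantom hidden over more than half its wall is excluded downstream", {
  ph <- make_airway_phantom(20, c(0.14, 0.22), n_points = 720L)
  rec <- qc_filter(measure_phantom(apply_missing_angle(ph, 181), "ebus"))
  expect_true(rec$excluded)
  rec2 <- qc_filter(measure_phantom(apply_missing_angle(ph, 179), "ebus"))
  expect_false(rec2$excluded)
})

test_that("hierarchical generator realizes its design exactly in degenerate cases", {
  # group effect with (numerically) no noise: exact 1.3x ratio
  des <- hierarchical_design(2, 3, 4, 2, grand_mean = 0.2,
                             group_effect_pct = 30,
                             variance_fractions = c(0, 0, 1),
                             total_cv = 1e-9, seed = 5L)
  d <- generate_hierarchical_dataset(des)
  m <- tapply(d$value, d$group, mean)
  expect_equal(unname(m[["heaves"]] / m[["control"]]), 1.3, tolerance = 1e-6)

  # identical seed, identical table
  expect_identical(generate_hierarchical_dataset(des),
                   generate_hierarchical_dataset(des))

  # image-only noise: variance of subject means ~ total_var/(n_air*n_img)
  des2 <- hierarchical_design(1, 400, 5, 3, grand_mean = 1,
                              group_effect_pct = 0,
                              variance_fractions = c(0, 0, 1),
                              total_cv = 0.3, seed = 6L)
  d2 <- generate_hierarchical_dataset(des2)
  vs <- var(tapply(d2$value, d2$subject, mean))
  expect_equal(vs, 0.3^2 / (5 * 3), tolerance = 0.2)

  expect_error(hierarchical_design(variance_fractions = c(0.5, 0.4, 0.3)),
               "sum")
})

test_that("generator realizes variance fractions over many subjects", {
  des <- hierarchical_design(1, 2000, 2, 2, grand_mean = 1,
                             group_effect_pct = 0,
                             variance_fractions = c(0.30, 0.40, 0.30),
                             total_cv = 0.25, seed = 77L)
  vc <- nested_varcomp(generate_hierarchical_dataset(des))
  pct <- setNames(vc$pct, vc$level)
  expect_lt(max(abs(unname(pct[c("subject", "airway", "image")]) -
                      c(30, 40, 30))), 3)  # +/- 3 points on percentages
})

test_that("paired-modality generator honors biases, shrinkage and determinism", {
  d0 <- paired_modality_design(n_airways = 20, pi_bias_slope = 0,
                               pi_bias_intercept = 0, shrink_fraction = 0,
                               noise_cv = 0, seed = 1L)
  p0 <- generate_paired_modality(d0)
  expect_equal(p0$ebus_pi_mm, p0$truth_pi_mm)
  expect_equal(p0$histo_pi_mm, p0$truth_pi_mm)
  expect_identical(generate_paired_modality(d0), p0)

  d1 <- paired_modality_design(n_airways = 30, shrink_fraction = 0.44,
                               noise_cv = 0, seed = 2L)
  an <- annulus_analysis(generate_paired_modality(d1), Inf)
  expect_equal(an$shrinkage_pct, rep(44, 30), tolerance = 1e-9)
})
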