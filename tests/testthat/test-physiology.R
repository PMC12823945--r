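test_that("percent_difference reproduces the phantom-validation arithmetic", {
  expect_equal(percent_difference(1.30, 1.32), 100 * 0.02 / 1.30)
  expect_equal(round(percent_difference(1.30, 1.32), 2), 1.54)
  expect_equal(percent_difference(1.00, 1.02), 2.00)
  expect_equal(percent_difference(4.90, 4.90), 0)
  # symmetric under common scaling
  expect_equal(percent_difference(3 * 1.3, 3 * 1.32),
               percent_difference(1.3, 1.32))
  expect_error(percent_difference(0, 1), "positive")
  expect_error(percent_difference(1.3, -1), "positive")
})

test_that("validation_summary groups mean percent differences by quantity", {
  pairs <- default_validation_pairs()
  vs <- validation_summary(pairs)
  s <- vs$summary
  expect_setequal(s$quantity, c("diameter", "area"))
  expect_equal(s$mean_pct_difference[s$quantity == "diameter"],
               mean(c(100 * 0.02 / 1.30, 100 * 0.01 / 0.70,
                      2, 100 * 0.02 / 0.78)))
  expect_equal(round(s$mean_pct_difference[s$quantity == "diameter"], 2), 1.88)
  # area mean recomputed from raw printed areas
  expect_equal(s$mean_pct_difference[s$quantity == "area"],
               mean(100 * c(0.11 / 4.90, 0.06 / 1.43, 0.12 / 2.51,
                            0.06 / 1.47)))
  # identical pairs give 0
  same <- data.frame(label = "X", quantity = "area",
                     reference_value = 4.9, measured_value = 4.9)
  expect_equal(validation_summary(same)$summary$mean_pct_difference, 0)
  expect_error(validation_summary(pairs[0, ]), "no validation pairs")
})

test_that("geometry interpolation is exact at stations and linear between", {
  geom <- default_geometry()
  st <- geom$stations
  at_node <- interpolate_geometry(geom, st$position_cm[3])
  expect_equal(at_node$major_radius_cm, st$major_radius_cm[3])
  expect_equal(at_node$minor_radius_cm, st$minor_radius_cm[3])
  expect_equal(at_node$tissue_fraction, st$tissue_fraction[3])
  mid <- (st$position_cm[1] + st$position_cm[2]) / 2
  at_mid <- interpolate_geometry(geom, mid)
  expect_equal(at_mid$major_radius_cm,
               mean(st$major_radius_cm[1:2]))
  expect_equal(at_mid$minor_radius_cm,
               mean(st$minor_radius_cm[1:2]))
  expect_error(interpolate_geometry(geom, -1), "out of station range")
  expect_error(interpolate_geometry(geom, 1e4), "out of station range")
})

test_that("CSF area follows the elliptical cross-section formula", {
  geom <- neuraxis_geometry(data.frame(
    label = c("A", "B"), position_cm = c(0, 10),
    major_radius_cm = c(0.6, 0.6), minor_radius_cm = c(0.3, 0.3),
    tissue_fraction = c(0.5, 0.5)))
  out <- interpolate_geometry(geom, 5)
  expect_equal(out$csf_area_cm2, pi * 0.6 * 0.3 * 0.5, tolerance = 1e-12)
})

test_that("default geometry matches the validated landmark dimensions", {
  st <- default_geometry()$stations
  landmark <- function(lbl) st[st$label == lbl, ]
  # in-vivo diameters are twice the minor radius; areas are pi*a*b
  expect_equal(2 * landmark("CM")$minor_radius_cm, 1.30)
  expect_equal(2 * landmark("T2")$minor_radius_cm, 0.70)
  area <- function(lbl) {
    s <- landmark(lbl); pi * s$major_radius_cm * s$minor_radius_cm
  }
  expect_equal(area("CM"), 4.90, tolerance = 0.01)
  expect_equal(area("L1"), 2.51, tolerance = 0.01)
  expect_equal(area("S3"), 1.47, tolerance = 0.01)
})

test_that("csf_state computes pulsation descriptors and dimensionless numbers", {
  ct <- physiology_constants(A_ref = 2)
  st <- csf_state(72, 1.0, ct)
  expect_equal(st$omega, 2 * pi * 72 / 60, tolerance = 1e-12)
  expect_equal(st$alpha, 0.25 * sqrt(st$omega / 0.01), tolerance = 1e-12)
  expect_equal(st$urms, (st$omega / 2) / (2 * sqrt(2)), tolerance = 1e-12)
  expect_equal(st$eps_amp, st$urms / (st$omega * 65), tolerance = 1e-12)
  expect_equal(st$pe, st$urms * 0.5 / (1.938e-6 / 60), tolerance = 1e-12)

  # scaling properties
  st2 <- csf_state(72, 2.0, ct)
  expect_equal(st2$urms, 2 * st$urms, tolerance = 1e-12)
  st4 <- csf_state(4 * 72 / 4, 1.0, ct)   # same
  stf <- csf_state(144, 1.0, ct)
  expect_equal(stf$alpha, st$alpha * sqrt(2), tolerance = 1e-12)
  expect_error(csf_state(-5, 1, ct), "frequency")
  expect_error(csf_state(72, -1, ct), "stroke_volume")
})
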