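# Cuboid partial-volume geometry, curvature correction, exact oracles.

test_that("ideal partial volume is proportional to depth and saturates", {
  st <- cuboid_structure()
  expect_equal(st$volume, 1.25)
  expect_equal(ideal_volume_fraction(st, 1), 20)
  expect_equal(ideal_volume_fraction(st, 0), 0)
  expect_equal(ideal_volume_fraction(st, 7), 100)
  expect_equal(ideal_volume_fraction(st, 1:5), seq(20, 100, by = 20))
  expect_error(ideal_volume_fraction(st, -1),
               class = "brachyqa_invalid_parameter")
})

test_that("published curvature factors correct the ideal fractions to the standard values", {
  st <- cuboid_structure()
  f <- correction_factors()
  expect_equal(f$factor, c(1.045, 1.021, 1.014, 1.010, 1.008))
  expect_true(all(f$factor >= 1))
  expect_true(all(diff(f$factor) < 0))  # non-increasing with r
  got <- round_half_away(corrected_volume_fraction(st, 1:5, f), 1)
  expect_equal(got, c(19.1, 39.2, 59.2, 79.2, 99.2))
  # identity factors reduce to the ideal fraction
  f1 <- f; f1$factor <- rep(1, 5)
  expect_equal(corrected_volume_fraction(st, 1:5, f1),
               ideal_volume_fraction(st, 1:5))
  # factors interpolate linearly between tabulated radii
  expect_equal(corrected_volume_fraction(st, 1.5, f),
               ideal_volume_fraction(st, 1.5) / mean(c(1.045, 1.021)))
  expect_error(corrected_volume_fraction(st, 0.5, f),
               class = "brachyqa_out_of_range")
  # correction always removes volume at tabulated radii
  expect_true(all(corrected_volume_fraction(st, 1:5, f) <
                    ideal_volume_fraction(st, 1:5)))
})

test_that("exact sphere-cuboid volume matches its independent oracles", {
  st <- cuboid_structure()
  expect_equal(exact_partial_volume(st, 0), 0)
  # circumscribing radius covers everything
  rmax <- sqrt(5^2 + 0.25^2 + 0.25^2)
  expect_equal(exact_partial_volume(st, rmax + 0.01), 1.25)
  # frozen from two agreeing oracles (adaptive quadrature and dense
  # voxel counting, dev-time scipy dblquad cross-check)
  v1 <- exact_partial_volume(st, 1)
  expect_equal(v1, 0.2447, tolerance = 5e-4)
  expect_equal(100 * v1 / st$volume, 19.58, tolerance = 1e-3)
  # quadrature and voxel counting agree within 0.1% relative at 0.01 cm
  for (r in c(1, 3, 5)) {
    q <- exact_partial_volume(st, r)
    v <- exact_partial_volume(st, r, method = "voxel", pitch = 0.01)
    expect_lt(abs(q - v) / q, 1e-3)
  }
  # half-ball closed form when the sphere fits inside the cross-section
  expect_equal(exact_partial_volume(st, 0.2), 2 / 3 * pi * 0.2^3)
})

test_that("exact partial volume is monotone, bounded, and below the flat-cut fraction", {
  st <- cuboid_structure()
  r <- c(0.1, 0.5, 1, 2, 3, 4, 5, 5.2)
  v <- exact_partial_volume(st, r)
  expect_true(all(diff(v) > 0))
  expect_true(all(v <= 0.5 * 0.5 * pmin(r, 5) + 1e-12))
  inside <- r <= 5
  expect_true(all(100 * v[inside] / st$volume <=
                    ideal_volume_fraction(st, r[inside])))
})

test_that("exact-mode correction factors are smaller than the published ones", {
  f <- correction_factors("exact")
  expect_true(all(f$factor >= 1))
  expect_equal(f$factor[1], 1.022, tolerance = 1e-3)
  expect_true(all(f$factor < correction_factors()$factor))
})

test_that("voxel-count ROI volume implements the half-edge formula", {
  expect_equal(pinnacle_roi_volume(1, 0, 2), 1.0)
  expect_equal(pinnacle_roi_volume(0.000625, 3000, 0), 1.875)
  expect_error(pinnacle_roi_volume(1, -1, 0),
               class = "brachyqa_invalid_parameter")
  expect_error(pinnacle_roi_volume(0, 1, 0),
               class = "brachyqa_invalid_parameter")
})

test_that("thick-slice contouring inflates the cuboid ROI volume to 1.88 cm^3", {
  v <- pinnacle_slab_volume()
  expect_equal(v, 3 * 0.25 * 0.5 * 5)  # 1.875
  expect_equal(round_half_away(v, 2), 1.88)
  # five 0.1-cm slices instead: nominal-volume regime
  expect_equal(pinnacle_slab_volume(n_slices = 5, slice_thickness = 0.1),
               1.25)
})

test_that("thin-slab disc fraction is the disc-to-square area ratio", {
  expect_equal(disc_volume_fraction(12, 1), 100 * pi / 144)
  expect_equal(round_half_away(disc_volume_fraction(12, 1), 2), 2.18)
  expect_equal(disc_volume_fraction(12, 0), 0)
  expect_equal(disc_volume_fraction(12, 6 / sqrt(pi)), 25)
  expect_error(disc_volume_fraction(12, 6.5),
               class = "brachyqa_unsupported_geometry")
})
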