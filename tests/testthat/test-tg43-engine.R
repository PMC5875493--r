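# TG-43 dose engine: decay, geometry function, radial dose, dose values.

test_that("mean lifetime is 1.44 half-lives and rejects bad input", {
  expect_equal(mean_lifetime(59.4 * 24), 2052.864)         # I-125: ~2053 h
  expect_equal(round_half_away(mean_lifetime(59.4 * 24), 0), 2053)
  expect_equal(mean_lifetime(1), 1.44)
  expect_equal(mean_lifetime(10), 14.4)
  expect_error(mean_lifetime(0), class = "brachyqa_invalid_parameter")
  expect_error(mean_lifetime(-3), class = "brachyqa_invalid_parameter")
})

test_that("transverse geometry-function ratio matches the reduced line-source form", {
  expect_equal(geometry_ratio_line(1, 0.5), 1.0)
  expect_equal(round_half_away(geometry_ratio_line(2, 0.5), 4), 0.2538)
  expect_equal(round_half_away(geometry_ratio_line(2, 0.5), 3), 0.254)
  expect_equal(round_half_away(geometry_ratio_line(5, 0.5), 3), 0.041)
  # direct evaluation of the reduced form, independent arithmetic
  expect_equal(geometry_ratio_line(3, 0.5),
               atan(0.5 / 6) / (3 * atan(0.25)))
  expect_error(geometry_ratio_line(0, 0.5),
               class = "brachyqa_invalid_parameter")
  expect_error(geometry_ratio_line(2, -1),
               class = "brachyqa_invalid_parameter")
})

test_that("geometry ratio tends to inverse square as the line shrinks to a point", {
  for (r in 1:5)
    expect_lt(abs(geometry_ratio_line(r, 1e-4) - (1 / r)^2), 1e-6)
})

test_that("general-angle geometry ratio reduces to the transverse form at 90 degrees", {
  for (L in c(0.36, 0.5, 1.0))
    expect_equal(geometry_ratio_general(1:5, 90, L),
                 geometry_ratio_line(1:5, L), tolerance = 1e-12)
  # symmetric about the bisector
  expect_equal(geometry_ratio_general(2, 60, 0.5),
               geometry_ratio_general(2, 120, 0.5))
  # on-axis limiting form 1/(r^2 - L^2/4), normalized to G_L(1, 90 deg)
  expect_equal(geometry_ratio_general(2, 0, 0.5),
               (1 / (4 - 0.25^2)) / (2 * atan(0.25) / 0.5))
  expect_error(geometry_ratio_general(0.2, 0, 0.5),
               class = "brachyqa_invalid_parameter")
})

test_that("radial dose function interpolates its table and refuses extrapolation", {
  src <- brachy_source("6711")
  expect_equal(radial_dose(src, 3), 0.636)
  expect_equal(radial_dose(src, 1), 1.000)
  expect_equal(radial_dose(src, 2.5), (0.819 + 0.636) / 2)  # 0.7275
  expect_error(radial_dose(src, 0.5), class = "brachyqa_out_of_range")
  expect_error(radial_dose(src, 6), class = "brachyqa_out_of_range")
  # clamp rule holds endpoints (synthetic-TPS path)
  expect_equal(radial_dose(src, 0.5, rule = "clamp"), 1.000)
  expect_equal(radial_dose(src, 6, rule = "clamp"), 0.367)
})

test_that("point-source doses reproduce the LDR hand-calculation values", {
  src <- brachy_source("6711")
  d <- dose_point_source(src, r = 1:5)
  expect_equal(round_half_away(d, 2), c(20.01, 4.10, 1.41, 0.62, 0.29))
  expect_error(dose_point_source(src, r = -1),
               class = "brachyqa_invalid_parameter")
  # multiplicative zero through g(r)
  src0 <- source_model("z", "I-125", "point", 1.01, 0.965,
                       data.frame(r = c(1, 2), g = c(1, 1e-12)),
                       half_life = 59.4 * 24)
  expect_lt(dose_point_source(src0, r = 2), 1e-9)
})

test_that("line-source doses reproduce the HDR hand-calculation values", {
  src <- brachy_source("VS2000")
  d <- dose_line_source(src, r = 1:5)
  expect_equal(round_half_away(d, 2), c(100.16, 25.55, 11.40, 6.39, 4.06))
  # reference consistency: all ratio terms unity at (1 cm, 90 deg)
  expect_equal(dose_line_source(src, r = 1),
               27292 * 1.101 * (1 / 3) / 100)
  # zero dwell time gives zero dose
  p0 <- implant_prescription("temporary", dwell_time = 0)
  expect_equal(dose_line_source(src, p0, r = 2), 0)
  expect_error(implant_prescription("temporary", dwell_time = -1),
               class = "brachyqa_invalid_parameter")
})

test_that("dose scales linearly in source strength, dose-rate constant, and time", {
  set.seed(42)
  for (i in 1:5) {
    sk <- runif(1, 0.5, 3e4); lam <- runif(1, 0.5, 1.5)
    hl <- runif(1, 10, 2000); k <- runif(1, 1.1, 4)
    g <- data.frame(r = 1:5, g = c(1, sort(runif(4, 0.3, 1.2), TRUE)))
    base <- source_model("a", "x", "point", sk, lam, g, half_life = hl)
    r <- runif(1, 1, 5)
    d <- dose_point_source(base, r = r)
    for (fld in c("air_kerma_strength", "dose_rate_constant", "half_life")) {
      sc <- base; sc[[fld]] <- sc[[fld]] * k
      sc <- do.call(source_model, c(list("a", "x", "point"),
        list(sc$air_kerma_strength, sc$dose_rate_constant, g,
             half_life = sc$half_life)))
      expect_equal(dose_point_source(sc, r = r), k * d, tolerance = 1e-12)
    }
  }
})

test_that("relative dose is independent of strength, constant, and time", {
  set.seed(7)
  g <- data.frame(r = 1:5, g = c(1, 0.9, 0.7, 0.5, 0.4))
  for (i in 1:5) {
    src <- source_model("a", "x", "point", runif(1, 0.1, 100),
                        runif(1, 0.1, 2), g, half_life = runif(1, 1, 5000))
    d <- dose_point_source(src, r = 1:5)
    expect_equal(100 * d / d[1], 100 * (1 / (1:5))^2 * g$g,
                 tolerance = 1e-12)
  }
})

test_that("point-source dose is strictly decreasing for a non-increasing g table", {
  src <- brachy_source("6711")
  r <- seq(1, 5, by = 0.05)
  d <- dose_point_source(src, r = r)
  expect_true(all(diff(d) < 0))
})
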