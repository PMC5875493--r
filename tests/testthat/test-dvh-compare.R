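# DVH curve lookup, variance metrics, and pass/fail gates.

ref_6711 <- build_reference_table(brachy_source("6711"))

# TPS fixture: the reference curve with known per-radius volume offsets
offset_curve <- function(ref, diffs) {
  dvh_curve(pct_dose = ref$pct_dose, pct_vol = ref$pct_vol + diffs)
}

test_that("cumulative DVH lookup is exact at nodes and linear between them", {
  cv <- dvh_curve(c(100, 20.5), c(19.1, 39.2))
  expect_equal(volume_at_dose(cv, 100), 19.1)
  expect_equal(volume_at_dose(cv, 20.5), 39.2)
  expect_equal(volume_at_dose(cv, 60.25), 29.15)  # midpoint
  expect_error(volume_at_dose(cv, 10), class = "brachyqa_out_of_range")
  expect_error(volume_at_dose(cv, 101), class = "brachyqa_out_of_range")
})

test_that("DVH curve construction enforces cumulative monotonicity", {
  expect_error(dvh_curve(c(10, 20), c(5, 10)),
               class = "brachyqa_invalid_parameter")  # dose not decreasing
  expect_error(dvh_curve(c(20, 10), c(30, 20)),
               class = "brachyqa_invalid_parameter")  # volume decreasing
  expect_error(dvh_curve(c(20, 10), c(30, 120)),
               class = "brachyqa_invalid_parameter")  # volume out of range
})

test_that("actual variance is the signed per-radius volume difference", {
  same <- dvh_curve_from_table(ref_6711)
  expect_equal(actual_variance(ref_6711, same, 1:5), rep(0, 5))
  shifted <- offset_curve(ref_6711, c(0.3, 0.2, 0.3, 0.5, 0.6))
  expect_equal(actual_variance(ref_6711, shifted, 1), 0.3)
  expect_equal(actual_variance(ref_6711, shifted, 4), 0.5)
  expect_error(actual_variance(ref_6711, shifted, 2.5),
               class = "brachyqa_invalid_parameter")
})

test_that("average variance is the signed arithmetic mean", {
  expect_equal(average_variance(c(0.3, 0.2, 0.3, 0.5, 0.6)), 0.38)
  expect_equal(round_half_away(average_variance(c(0.3, 0.2, 0.3, 0.5, 0.6)), 1),
               0.4)
  expect_equal(average_variance(c(0.8, 0.9, 2.0, 3.6, -4.3)), 0.6)
  expect_equal(average_variance(rep(0, 4)), 0)
  expect_error(average_variance(numeric(0)),
               class = "brachyqa_invalid_parameter")
})

test_that("individual and average gates fail independently", {
  mk <- function(diffs) compare_dvh(ref_6711, offset_curve(ref_6711, diffs))
  expect_equal(mk(c(0.3, 0.2, 0.3, 0.5, 0.6))$verdict, "pass")
  # one spike: individual gate only
  spike <- mk(c(0, 0, 6, 0, 0))
  expect_equal(spike$verdict, "fail")
  expect_match(spike$reasons, "individual", all = FALSE)
  expect_no_match(spike$reasons, "average")
  # uniform 3-pp shift: average gate only (built directly, since +3 on the
  # last reference volume exceeds 100% and is no longer a valid curve)
  shift <- comparison_report(1:5, ref_6711$pct_dose, ref_6711$pct_vol,
                             ref_6711$pct_vol + 3)
  expect_equal(shift$verdict, "fail")
  expect_match(shift$reasons, "average", all = FALSE)
  expect_no_match(shift$reasons, "individual")
  # boundary: exactly at tolerance passes, just over fails
  expect_equal(mk(c(0, 0, 5, 0, -5))$verdict, "pass")
  expect_equal(mk(c(0, 0, 5.1, 0, -5.1))$verdict, "fail")
})

test_that("swapping reference and TPS volumes negates every variance", {
  set.seed(3)
  for (i in 1:5) {
    diffs <- runif(5, -4, 4)
    a <- comparison_report(1:5, ref_6711$pct_dose, ref_6711$pct_vol,
                           ref_6711$pct_vol + diffs)
    b <- comparison_report(1:5, ref_6711$pct_dose, ref_6711$pct_vol + diffs,
                           ref_6711$pct_vol)
    expect_equal(a$records$actual_variance, -b$records$actual_variance)
    expect_equal(a$average_variance, -b$average_variance)
  }
})

test_that("every surveyed TPS column passes and its recomputed average matches", {
  expected <- list(
    list("6711", "VariSeed", 0.4), list("6711", "BrachyVision", 0.6),
    list("6711", "Pinnacle", 0.2), list("6711", "MIM", 0.7),
    list("VS2000", "BrachyVision", 0.6), list("VS2000", "Pinnacle", 0.0),
    list("mHDRv2", "Pinnacle", 0.3), list("mHDRv2", "Oncentra", -0.1))
  for (e in expected) {
    rep <- tps_survey_report(e[[1]], e[[2]])
    expect_equal(round_half_away(rep$average_variance, 1), e[[3]],
                 info = paste(e[[1]], e[[2]]))
    expect_equal(rep$verdict, "pass", info = paste(e[[1]], e[[2]]))
    expect_lte(max(abs(rep$records$actual_variance)), 5)
  }
  expect_error(tps_survey_report("6711", "Oncentra"),
               class = "brachyqa_invalid_parameter")
})

test_that("DVH CSV reader handles relative and absolute dose columns", {
  cv <- dvh_curve_from_table(ref_6711)
  p <- withr::local_tempfile(fileext = ".csv")
  write_dvh_csv(cv, p)
  back <- read_dvh_csv(p)
  expect_equal(back$pct_dose, cv$pct_dose, tolerance = 1e-12)
  expect_equal(back$pct_vol, cv$pct_vol, tolerance = 1e-12)
  # absolute-dose dialect with prescription normalization
  p2 <- withr::local_tempfile(fileext = ".csv")
  d0 <- ref_6711$dose_Gy[1]
  utils::write.csv(data.frame(dose_Gy = ref_6711$dose_Gy,
                              pct_vol = cv$pct_vol), p2, row.names = FALSE)
  abs_back <- read_dvh_csv(p2, prescription_gy = d0)
  expect_equal(abs_back$pct_dose, cv$pct_dose, tolerance = 1e-9)
  expect_error(read_dvh_csv(p2), class = "brachyqa_invalid_parameter")
})

test_that("comparison reports round-trip to text plus key-value documents", {
  rep <- tps_survey_report("6711", "VariSeed")
  p <- withr::local_tempfile(fileext = ".txt")
  write_comparison_report(rep, p)
  expect_match(readLines(p), "PASS", all = FALSE)
  y <- yaml::read_yaml(paste0(sub("\\.txt$", "", p), ".yaml"))
  expect_equal(y$verdict, "pass")
  expect_equal(y$average_variance, rep$average_variance)
  expect_length(y$records, 5)
})
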