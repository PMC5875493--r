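# Desk-scale planning-system emulator: voxelize the QA cuboid, compute
# per-voxel TG-43 dose, bin a cumulative DVH — so the comparison pipeline
# can be exercised end to end without a commercial TPS.

#' Synthetic-TPS simulation configuration
#'
#' @param voxel_pitch dose-grid voxel pitch in cm (default 0.05; pitches that
#'   divide the cuboid dimensions reproduce its volume exactly).
#' @param dvh_bin_width cumulative-DVH dose bin width, percent of
#'   prescription (default 0.5; commercial exports are nominally ~2%-volume
#'   steps, i.e. much coarser).
#' @param contour_perturbation uniform inward shrink of every cuboid face in
#'   cm (default 0) mimicking the contouring loss seen when drawing tools do
#'   not hold the intended shape.
#' @param max_pct_dose cap on the binned relative-dose axis (default 150%);
#'   near-source voxels far above the cap are accumulated into the top bin,
#'   which only ever sits above any queried dose level.
#' @param random_seed integer seed, reserved for stochastic perturbations.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(voxel_pitch = 0.05, dvh_bin_width = 0.5,
                              contour_perturbation = 0,
                              max_pct_dose = 150, random_seed = NULL) {
  check_scalar(voxel_pitch, "voxel_pitch")
  check_scalar(dvh_bin_width, "dvh_bin_width")
  check_scalar(max_pct_dose, "max_pct_dose")
  if (contour_perturbation < 0)
    stop_invalid("contour_perturbation must be >= 0")
  structure(list(voxel_pitch = voxel_pitch, dvh_bin_width = dvh_bin_width,
                 contour_perturbation = contour_perturbation,
                 max_pct_dose = max_pct_dose, random_seed = random_seed),
            class = "simulation_config")
}

#' Voxelize the QA cuboid
#'
#' Regular grid anchored at the cuboid corner with half-open cells
#' `[lo, hi)` per axis; a voxel belongs to the structure when its center
#' lies inside the (optionally shrunk) cuboid.  For pitches dividing the
#' cuboid dimensions the reported volume `count * pitch^3` is exact.
#'
#' @param structure a [cuboid_structure()].
#' @param pitch voxel pitch in cm; must not exceed any cuboid dimension.
#' @param perturbation uniform inward shrink in cm applied to every face.
#' @return a list with `centers` (matrix of voxel-center x, y, z in the
#'   source-at-origin frame), `pitch`, and `volume` (cm^3).
#' @export
voxelize <- function(structure, pitch, perturbation = 0) {
  stopifnot(inherits(structure, "cuboid_structure"))
  check_scalar(pitch, "pitch")
  dims <- c(structure$length, structure$width, structure$height)
  if (pitch > min(dims))
    stop(errorCondition(
      paste0("pitch ", pitch, " cm exceeds a cuboid dimension: degenerate grid"),
      class = c("brachyqa_degenerate_grid", "brachyqa_error")))
  if (perturbation < 0) stop_invalid("perturbation must be >= 0")
  n <- floor(dims / pitch + 1e-9)
  cx <- (seq_len(n[1]) - 0.5) * pitch
  cy <- (seq_len(n[2]) - 0.5) * pitch - structure$width / 2
  cz <- (seq_len(n[3]) - 0.5) * pitch - structure$height / 2
  centers <- as.matrix(expand.grid(x = cx, y = cy, z = cz,
                                   KEEP.OUT.ATTRS = FALSE))
  if (perturbation > 0) {
    p <- perturbation
    keep <- centers[, "x"] >= p & centers[, "x"] <= structure$length - p &
      abs(centers[, "y"]) <= structure$width / 2 - p &
      abs(centers[, "z"]) <= structure$height / 2 - p
    centers <- centers[keep, , drop = FALSE]
  }
  list(centers = centers, pitch = pitch, volume = nrow(centers) * pitch^3)
}

# per-voxel relative dose (% of the dose at the reference position).
# Line sources are oriented along z through the origin, perpendicular to the
# cuboid's +x long axis; g(r) is endpoint-clamped because corner radii
# slightly exceed the tabulated range.
voxel_relative_dose <- function(source, prescription, centers) {
  r <- sqrt(rowSums(centers^2))
  d0 <- tg43_dose(source, prescription, prescription$reference_distance)
  if (source$mode == "point") {
    g <- radial_dose(source, r, rule = "clamp")
    d <- source$air_kerma_strength * source$dose_rate_constant *
      (1 / r)^2 * g * anisotropy_value(source, r) *
      prescription$effective_time / 100
  } else {
    theta <- acos(pmin(pmax(centers[, "z"] / r, -1), 1)) * 180 / pi
    gr <- geometry_ratio_general(r, theta, source$active_length)
    g <- radial_dose(source, r, rule = "clamp")
    d <- source$air_kerma_strength * source$dose_rate_constant *
      gr * g * anisotropy_value(source, r, theta) *
      prescription$effective_time / 100
  }
  100 * d / d0
}

#' Cumulative DVH from a set of voxel doses
#'
#' Empirical cumulative curve sampled at dose-bin edges: at each edge d the
#' volume is `100 * mean(dose >= d)`.  Doses above `max_pct_dose` accumulate
#' into the top edge.
#'
#' @param rel_dose per-voxel relative dose, percent of prescription.
#' @param bin_width dose bin width in percent.
#' @param max_pct_dose top of the binned axis in percent.
#' @param ... metadata passed to [dvh_curve()].
#' @return a [dvh_curve()] in descending dose order.
#' @export
dvh_from_doses <- function(rel_dose, bin_width = 0.5, max_pct_dose = 150,
                           ...) {
  if (length(rel_dose) < 1L) stop_invalid("no voxel doses supplied")
  edges <- seq(0, max_pct_dose, by = bin_width)
  n <- length(rel_dose)
  # counts of doses >= each edge via a right-closed histogram complement
  idx <- findInterval(rel_dose, edges, left.open = TRUE)  # edge index below
  cum_below <- cumsum(tabulate(idx, nbins = length(edges)))
  at_least <- n - c(0, cum_below[-length(cum_below)])
  # edge k has doses >= edges[k]: doses in bins k..end plus anything > top
  vol <- 100 * at_least / n
  dvh_curve(pct_dose = rev(edges), pct_vol = rev(vol),
            bin_width = bin_width, ...)
}

#' Simulate a planning-system DVH
#'
#' Voxelizes the structure, evaluates the TG-43 dose at every voxel center
#' (point-source form, or line-source form at general angle with the source
#' axis along z), normalizes to the reference-position dose, and bins the
#' cumulative DVH.
#'
#' @param source a [source_model()].
#' @param prescription an [implant_prescription()].
#' @param structure a [cuboid_structure()].
#' @param config a [simulation_config()].
#' @return a [dvh_curve()].
#' @examples
#' cv <- simulate_dvh(brachy_source("6711"))
#' volume_at_dose(cv, 100)  # ~19.6% of the cuboid receives >= 100% dose
#' @export
simulate_dvh <- function(source, prescription = default_prescription(source),
                         structure = cuboid_structure(),
                         config = simulation_config()) {
  vox <- voxelize(structure, config$voxel_pitch, config$contour_perturbation)
  rel <- voxel_relative_dose(source, prescription, vox$centers)
  dvh_from_doses(rel, bin_width = config$dvh_bin_width,
                 max_pct_dose = config$max_pct_dose,
                 tps = "synthetic TPS", source = source$name)
}

#' End-to-end QA self-check against the synthetic TPS
#'
#' Runs the full commissioning loop at desk scale: build the
#' hand-calculation reference table, simulate a TPS DVH, and evaluate the
#' comparison gates.  `volume_bias` injects a synthetic TPS volume error
#' (percentage points) at `bias_radius` (or at every radius when `NULL`) to
#' exercise the failure branches.
#'
#' @inheritParams simulate_dvh
#' @param factors a [correction_factors()] table for the reference.
#' @param radii comparison radii in cm.
#' @param volume_bias percentage points added to the simulated %Vol.
#' @param bias_radius radius (cm) receiving the bias; `NULL` = all radii.
#' @inheritParams comparison_report
#' @return a `comparison_report`.
#' @export
end_to_end_selfcheck <- function(source,
                                 prescription = default_prescription(source),
                                 structure = cuboid_structure(),
                                 config = simulation_config(),
                                 factors = correction_factors(),
                                 radii = 1:5,
                                 volume_bias = 0, bias_radius = NULL,
                                 individual_tolerance = 5,
                                 average_tolerance = 2) {
  ref <- build_reference_table(source, prescription, structure, factors,
                               radii)
  tps <- simulate_dvh(source, prescription, structure, config)
  vol_tps <- volume_at_dose(tps, ref$pct_dose)
  if (volume_bias != 0) {
    at <- if (is.null(bias_radius)) rep(TRUE, length(radii))
          else radii %in% bias_radius
    vol_tps[at] <- vol_tps[at] + volume_bias
  }
  comparison_report(r = ref$r_cm, pct_dose = ref$pct_dose,
                    pct_vol_ref = ref$pct_vol, pct_vol_tps = vol_tps,
                    individual_tolerance = individual_tolerance,
                    average_tolerance = average_tolerance,
                    label = paste("synthetic TPS /", source$name))
}
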