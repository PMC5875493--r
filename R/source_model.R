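# Sealed-source models and implant prescriptions for the TG-43 engine.

#' Construct a sealed brachytherapy source model
#'
#' Bundles every TG-43 quantity needed to compute dose around one sealed
#' source: air-kerma strength \eqn{S_K} (U, 1 U = 1 cGy cm^2 h^-1), the
#' dose-rate constant \eqn{\Lambda} (cGy h^-1 U^-1), the radial dose function
#' \eqn{g(r)} tabulated on the transverse axis, the active length for the
#' line-source approximation, and the decay/dwell information that converts an
#' initial dose rate into total dose.
#'
#' The anisotropy function defaults to exactly unity everywhere, the usual
#' commissioning simplification when planning systems restrict anisotropy data
#' entry; a per-source override hook (`anisotropy`) exists but no preset
#' ships data for it.
#'
#' @param name character identifier, e.g. `"6711"`.
#' @param radionuclide character, e.g. `"I-125"` or `"Ir-192"`.
#' @param mode `"point"` (1D approximation) or `"line"` (2D approximation).
#' @param air_kerma_strength \eqn{S_K} in U; must be positive.
#' @param dose_rate_constant \eqn{\Lambda} in cGy h^-1 U^-1; must be positive.
#' @param radial_dose_table two-column data frame (`r` in cm, `g`
#'   dimensionless) with strictly increasing radii and `g = 1` at
#'   `r = 1` cm.
#' @param active_length active length `L` in cm; required when
#'   `mode = "line"`.
#' @param half_life half-life in hours (permanent implants).
#' @param dwell_time dwell time in hours (temporary implants).
#' @param anisotropy optional function `f(r, theta)` returning a
#'   dimensionless anisotropy value in (0, 2]; `NULL` means unity.
#' @param geometry_ratio_table optional two-column data frame (`r`, `ratio`)
#'   of transverse-plane geometry-function ratios to use verbatim instead of
#'   the analytic line-source form (see [brachy_source()] for why a vendor
#'   table may be preferred).
#' @return an object of class `source_model`.
#' @seealso [brachy_source()] for the built-in presets,
#'   [read_source_config()] for the file interface.
#' @export
source_model <- function(name, radionuclide, mode = c("point", "line"),
                         air_kerma_strength, dose_rate_constant,
                         radial_dose_table,
                         active_length = NULL,
                         half_life = NULL, dwell_time = NULL,
                         anisotropy = NULL,
                         geometry_ratio_table = NULL) {
  mode <- match.arg(mode)
  check_scalar(air_kerma_strength, "air_kerma_strength")
  check_scalar(dose_rate_constant, "dose_rate_constant")
  if (mode == "line") {
    if (is.null(active_length))
      stop_invalid("active_length is required for a line-mode source")
    check_scalar(active_length, "active_length")
  }
  if (!is.null(half_life)) check_scalar(half_life, "half_life")
  if (!is.null(dwell_time)) check_scalar(dwell_time, "dwell_time")

  tb <- as.data.frame(radial_dose_table)
  if (ncol(tb) < 2L) stop_invalid("radial_dose_table needs columns r and g")
  names(tb)[1:2] <- c("r", "g")
  if (any(diff(tb$r) <= 0))
    stop_invalid("radial_dose_table radii must be strictly increasing")
  if (any(tb$g <= 0))
    stop_invalid("radial dose values must be positive")
  at1 <- which(tb$r == 1)
  if (length(at1) == 1L && abs(tb$g[at1] - 1) > 1e-9)
    stop_invalid("g(r0 = 1 cm) must equal 1 (normalization of g)")
  if (!is.null(anisotropy) && !is.function(anisotropy))
    stop_invalid("anisotropy must be NULL or a function of (r, theta)")
  if (!is.null(geometry_ratio_table)) {
    gt <- as.data.frame(geometry_ratio_table)
    names(gt)[1:2] <- c("r", "ratio")
    if (any(diff(gt$r) <= 0) || any(gt$ratio <= 0))
      stop_invalid("geometry_ratio_table needs increasing radii, positive ratios")
    geometry_ratio_table <- gt[c("r", "ratio")]
  }

  structure(
    list(name = as.character(name),
         radionuclide = as.character(radionuclide),
         mode = mode,
         air_kerma_strength = air_kerma_strength,
         dose_rate_constant = dose_rate_constant,
         active_length = active_length,
         radial_dose_table = tb[c("r", "g")],
         half_life = half_life,
         dwell_time = dwell_time,
         anisotropy = anisotropy,
         geometry_ratio_table = geometry_ratio_table),
    class = "source_model")
}

#' @export
print.source_model <- function(x, ...) {
  cat(sprintf("<source_model> %s (%s, %s-source)\n",
              x$name, x$radionuclide, x$mode))
  cat(sprintf("  S_K = %g U, Lambda = %g cGy/h/U", x$air_kerma_strength,
              x$dose_rate_constant))
  if (!is.null(x$active_length)) cat(sprintf(", L = %g cm", x$active_length))
  cat("\n")
  if (!is.null(x$half_life))
    cat(sprintf("  half-life %g h (tau = %g h)\n", x$half_life,
                mean_lifetime(x$half_life)))
  if (!is.null(x$dwell_time))
    cat(sprintf("  dwell time %g h\n", x$dwell_time))
  cat(sprintf("  g(r) tabulated on [%g, %g] cm (%d nodes)\n",
              min(x$radial_dose_table$r), max(x$radial_dose_table$r),
              nrow(x$radial_dose_table)))
  invisible(x)
}

#' Built-in commissioning source presets
#'
#' Three sources commonly commissioned for DVH QA, with the constants used in
#' multi-TPS commissioning practice:
#'
#' \describe{
#'   \item{`"6711"`}{LDR I-125 seed (point-source mode), \eqn{S_K} = 1.01 U,
#'     \eqn{\Lambda} = 0.965, half-life 59.4 d; delivers 20 Gy at 1 cm over a
#'     permanent implant.}
#'   \item{`"VS2000"`}{HDR Ir-192 (line-source mode, L = 0.5 cm),
#'     \eqn{S_K} = 27292 U, \eqn{\Lambda} = 1.101, 20-min (1/3 h) dwell;
#'     delivers 100 Gy at 1 cm.}
#'   \item{`"mHDRv2"`}{HDR Ir-192 (line-source mode, L = 0.36 cm),
#'     \eqn{S_K} = 27076 U, \eqn{\Lambda} = 1.108, 1/3 h dwell.}
#' }
#'
#' The mHDR-v2 vendor documentation tabulates transverse geometry-function
#' ratios that do not agree with the analytic line-source expression for
#' L = 0.36 cm (printed 0.256 at r = 2 cm versus 0.252 analytic).
#' `geometry = "printed"` (the default for this preset) uses the tabulated
#' ratios verbatim; `geometry = "eq"` uses the analytic form.  The other two
#' presets ignore `geometry`.
#'
#' @param name one of `"6711"`, `"VS2000"`, `"mHDRv2"`.
#' @param geometry for `"mHDRv2"` only: `"printed"` or `"eq"`.
#' @return a [source_model()].
#' @examples
#' src <- brachy_source("6711")
#' radial_dose(src, 2)  # 0.819
#' @export
brachy_source <- function(name = c("6711", "VS2000", "mHDRv2"),
                          geometry = c("printed", "eq")) {
  name <- match.arg(name)
  geometry <- match.arg(geometry)
  switch(name,
    "6711" = source_model(
      name = "6711", radionuclide = "I-125", mode = "point",
      air_kerma_strength = 1.01, dose_rate_constant = 0.965,
      half_life = 59.4 * 24,
      radial_dose_table = data.frame(
        r = 1:5, g = c(1.000, 0.819, 0.636, 0.499, 0.367))),
    "VS2000" = source_model(
      name = "VS2000", radionuclide = "Ir-192", mode = "line",
      air_kerma_strength = 27292, dose_rate_constant = 1.101,
      active_length = 0.5, dwell_time = 1 / 3,
      radial_dose_table = data.frame(
        r = 1:5, g = c(1.000, 1.005, 1.006, 1.002, 0.993))),
    "mHDRv2" = source_model(
      name = "mHDRv2", radionuclide = "Ir-192", mode = "line",
      air_kerma_strength = 27076, dose_rate_constant = 1.108,
      active_length = 0.36, dwell_time = 1 / 3,
      radial_dose_table = data.frame(
        r = 1:5, g = c(1.000, 1.007, 1.008, 1.004, 0.995)),
      geometry_ratio_table = if (geometry == "printed")
        data.frame(r = 1:5, ratio = c(1.000, 0.256, 0.115, 0.065, 0.041))))
}

#' Mean lifetime of a decaying source
#'
#' For a permanent implant the initial dose rate integrates over all time to
#' initial rate times the mean lifetime \eqn{\tau = 1.44 \times t_{1/2}}
#' (1.44 approximating \eqn{1/\ln 2}).
#'
#' @param half_life half-life in hours; must be positive.
#' @return mean lifetime in hours.
#' @examples
#' mean_lifetime(59.4 * 24)  # I-125: 2052.9 h, quoted as 2053 h
#' @export
mean_lifetime <- function(half_life) {
  check_scalar(half_life, "half_life")
  1.44 * half_life
}

#' Construct an implant prescription
#'
#' Pairs an implant kind with the time factor that converts dose rate into
#' dose: permanent implants integrate over the source's mean lifetime,
#' temporary implants multiply by the dwell time.  Reference position is
#' fixed at \eqn{r_0 = 1} cm, \eqn{\theta_0 = 90^\circ}.
#'
#' @param kind `"permanent"` or `"temporary"`.
#' @param dwell_time dwell time in hours (temporary implants only).
#' @param half_life half-life in hours (permanent implants only).
#' @return an object of class `implant_prescription` with an
#'   `effective_time` field in hours.
#' @examples
#' implant_prescription("temporary", dwell_time = 1 / 3)
#' @export
implant_prescription <- function(kind = c("permanent", "temporary"),
                                 dwell_time = NULL, half_life = NULL) {
  kind <- match.arg(kind)
  if (kind == "permanent") {
    if (is.null(half_life))
      stop_invalid("permanent implant prescriptions need half_life")
    eff <- mean_lifetime(half_life)
  } else {
    if (is.null(dwell_time))
      stop_invalid("temporary implant prescriptions need dwell_time")
    check_scalar(dwell_time, "dwell_time", positive = FALSE)
    if (dwell_time < 0) stop_invalid("dwell_time must be non-negative")
    eff <- dwell_time
  }
  structure(list(kind = kind, dwell_time = dwell_time, half_life = half_life,
                 effective_time = eff,
                 reference_distance = 1, reference_angle = 90),
            class = "implant_prescription")
}

#' @export
print.implant_prescription <- function(x, ...) {
  cat(sprintf("<implant_prescription> %s, effective time %g h\n",
              x$kind, x$effective_time))
  invisible(x)
}

#' Default prescription for a source model
#'
#' Permanent (mean-lifetime) for sources carrying a half-life, temporary
#' (dwell-time) for sources carrying a dwell time.
#'
#' @param source a [source_model()].
#' @return an [implant_prescription()].
#' @export
default_prescription <- function(source) {
  stopifnot(inherits(source, "source_model"))
  if (!is.null(source$half_life))
    implant_prescription("permanent", half_life = source$half_life)
  else if (!is.null(source$dwell_time))
    implant_prescription("temporary", dwell_time = source$dwell_time)
  else stop_invalid("source carries neither half_life nor dwell_time")
}

#' Radial dose function lookup
#'
#' Evaluates the dimensionless radial dose function g(r) from the source's
#' table: exact at a table node, linear interpolation in r between nodes.
#' Outside the tabulated range the default is an error (hand calculations
#' must not extrapolate); `rule = "clamp"` holds the endpoint values, which
#' the synthetic-TPS voxel grid uses for the few millimetres its corner
#' radii extend past the table.
#'
#' @param source a [source_model()].
#' @param r radial distance(s) in cm.
#' @param rule `"strict"` (error outside the table) or `"clamp"`.
#' @return g(r), dimensionless, same length as `r`.
#' @examples
#' radial_dose(brachy_source("6711"), 2.5)  # 0.7275 by interpolation
#' @export
radial_dose <- function(source, r, rule = c("strict", "clamp")) {
  stopifnot(inherits(source, "source_model"))
  rule <- match.arg(rule)
  tb <- source$radial_dose_table
  if (rule == "strict" && (any(r < min(tb$r)) || any(r > max(tb$r))))
    stop_range("r outside radial dose table range [", min(tb$r), ", ",
               max(tb$r), "] cm; no extrapolation")
  if (nrow(tb) == 1L) return(rep(tb$g, length(r)))
  stats::approx(tb$r, tb$g, xout = r, rule = 2)$y
}

anisotropy_value <- function(source, r, theta = 90) {
  if (is.null(source$anisotropy)) return(rep(1, length.out = max(length(r), length(theta))))
  source$anisotropy(r, theta)
}
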