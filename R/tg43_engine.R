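# TG-43 point- and line-source dose computation.
#
# Internal dose unit is cGy (native to U and Lambda); conversion to Gy
# happens only at the reporting boundary of the exported dose functions.

#' Line-source geometry-function ratio on the transverse plane
#'
#' The TG-43 line-source geometry function \eqn{G_L(r,\theta)} generalizes
#' inverse-square falloff to a distributed line.  On the transverse bisector
#' (\eqn{\theta = 90^\circ}) the ratio to the reference position
#' (\eqn{r_0 = 1} cm, \eqn{\theta_0 = 90^\circ}) reduces to
#' \deqn{\frac{G_L(r,90^\circ)}{G_L(r_0,90^\circ)} =
#'   \frac{r_0 \arctan(L/2r)}{r \arctan(L/2r_0)}}
#' which tends to the point-source inverse square \eqn{(r_0/r)^2} as
#' \eqn{L \to 0}.
#'
#' @param r radial distance(s) in cm, > 0.
#' @param L active length in cm, > 0.
#' @return dimensionless ratio, 1 at r = 1 cm.
#' @examples
#' geometry_ratio_line(2, 0.5)  # 0.2538, tabulated as 0.254
#' @export
geometry_ratio_line <- function(r, L) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0))
    stop_invalid("r must be positive and finite")
  check_scalar(L, "L")
  atan(L / (2 * r)) / (r * atan(L / 2))
}

#' Line-source geometry-function ratio at general angle
#'
#' Off the bisector the geometry function is
#' \eqn{G_L(r,\theta) = \beta / (L r \sin\theta)}, where \eqn{\beta} is the
#' angle the active line subtends at the calculation point; on the axis
#' (\eqn{\sin\theta = 0}) the limiting form \eqn{1/(r^2 - L^2/4)} applies.
#' The returned value is normalized to the reference position
#' \eqn{G_L(1, 90^\circ)}, so it reduces to [geometry_ratio_line()] at
#' \eqn{\theta = 90^\circ}.  Used by the synthetic-TPS voxel grid; hand
#' calculations stay on the bisector.
#'
#' @param r radial distance(s) in cm, > 0.
#' @param theta polar angle(s) from the source axis, degrees in (0, 180)
#'   or exactly 0/180 for the on-axis limit (requires r > L/2).
#' @param L active length in cm.
#' @return dimensionless normalized ratio.
#' @export
geometry_ratio_general <- function(r, theta, L) {
  if (any(r <= 0)) stop_invalid("r must be positive")
  check_scalar(L, "L")
  th <- theta * pi / 180
  z <- r * cos(th)
  rho <- r * sin(th)
  g_ref <- 2 * atan(L / 2) / L            # G_L(1, 90 deg) numerator form
  on_axis <- rho < 1e-12
  if (any(on_axis & abs(z) <= L / 2))
    stop_invalid("point lies on the active line (r <= L/2 on axis)")
  beta <- atan2(L / 2 - z, rho) + atan2(L / 2 + z, rho)
  g <- beta / (L * rho)
  if (any(on_axis)) g[on_axis] <- 1 / (r[on_axis]^2 - L^2 / 4)
  g / g_ref
}

geometry_term <- function(source, r) {
  # transverse-plane geometry term used in hand-calculation tables:
  # inverse square for point sources, G-ratio for line sources (vendor
  # tabulated ratios take precedence when the source carries them)
  if (source$mode == "point") return((1 / r)^2)
  gt <- source$geometry_ratio_table
  if (!is.null(gt)) {
    if (any(r < min(gt$r)) || any(r > max(gt$r)))
      stop_range("r outside the source's tabulated geometry-ratio range")
    stats::approx(gt$r, gt$ratio, xout = r)$y
  } else {
    geometry_ratio_line(r, source$active_length)
  }
}

#' Point-source TG-43 dose
#'
#' Absorbed dose at transverse distance r from a point-approximated source
#' over a permanent implant:
#' \deqn{D(r) = S_K \Lambda (r_0/r)^2 g_p(r) \phi_{an}(r) \tau}
#' with \eqn{\tau} the mean lifetime.  Result converted from cGy to Gy.
#'
#' @param source a [source_model()] with `mode = "point"`.
#' @param prescription a permanent [implant_prescription()].
#' @param r radial distance(s) in cm, > 0, within the radial dose table.
#' @return dose in Gy.
#' @examples
#' d <- dose_point_source(brachy_source("6711"), r = 1)  # ~20.01 Gy
#' @export
dose_point_source <- function(source, prescription = default_prescription(source), r) {
  stopifnot(inherits(source, "source_model"))
  if (source$mode != "point")
    stop_invalid("dose_point_source needs a point-mode source")
  if (prescription$kind != "permanent")
    stop_invalid("point-source mode models a permanent implant")
  if (any(r <= 0)) stop_invalid("r must be positive")
  g <- radial_dose(source, r)
  cgy <- source$air_kerma_strength * source$dose_rate_constant *
    (1 / r)^2 * g * anisotropy_value(source, r) * prescription$effective_time
  cgy / 100
}

#' Line-source TG-43 dose
#'
#' Absorbed dose around a line-approximated source over a temporary implant:
#' \deqn{D(r) = S_K \Lambda \frac{G_L(r,\theta)}{G_L(r_0,\theta_0)}
#'   g_L(r) F(r,\theta) t}
#' At \eqn{\theta = 90^\circ} the geometry ratio is the reduced transverse
#' form (or the source's vendor-tabulated ratios, when present); off the
#' bisector the general \eqn{\beta/(L r \sin\theta)} form is used.
#' \eqn{F(r,\theta)} defaults to unity.  Result in Gy.
#'
#' @param source a [source_model()] with `mode = "line"`.
#' @param prescription a temporary [implant_prescription()].
#' @param r radial distance(s) in cm, > 0.
#' @param theta polar angle(s) in degrees, default 90 (transverse plane).
#' @param g_rule radial-dose lookup rule, see [radial_dose()].
#' @return dose in Gy.
#' @examples
#' dose_line_source(brachy_source("VS2000"), r = 1)  # ~100.16 Gy
#' @export
dose_line_source <- function(source, prescription = default_prescription(source),
                             r, theta = 90, g_rule = "strict") {
  stopifnot(inherits(source, "source_model"))
  if (source$mode != "line")
    stop_invalid("dose_line_source needs a line-mode source")
  if (prescription$kind != "temporary")
    stop_invalid("line-source mode models a temporary implant")
  if (any(r <= 0)) stop_invalid("r must be positive")
  if (prescription$effective_time < 0)
    stop_invalid("dwell time must be non-negative")
  gr <- if (all(theta == 90)) geometry_term(source, r)
        else geometry_ratio_general(r, theta, source$active_length)
  g <- radial_dose(source, r, rule = g_rule)
  cgy <- source$air_kerma_strength * source$dose_rate_constant *
    gr * g * anisotropy_value(source, r, theta) * prescription$effective_time
  cgy / 100
}

#' TG-43 dose dispatch
#'
#' Calls [dose_point_source()] or [dose_line_source()] according to the
#' source's mode.
#'
#' @inheritParams dose_line_source
#' @return dose in Gy.
#' @export
tg43_dose <- function(source, prescription = default_prescription(source),
                      r, theta = 90, g_rule = "strict") {
  if (source$mode == "point")
    dose_point_source(source, prescription, r)
  else
    dose_line_source(source, prescription, r, theta, g_rule)
}
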