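# Cumulative DVH curves: construction, validation, lookup, CSV I/O, plotting.

#' Construct a cumulative DVH curve
#'
#' A cumulative dose-volume histogram: ordered points (pct_dose, pct_vol)
#' meaning pct_vol percent of the structure receives at least pct_dose
#' percent of the prescription dose.  Dose must be strictly decreasing along
#' the point order and volume non-decreasing (a curve violating cumulative
#' monotonicity is rejected).
#'
#' @param pct_dose percent of prescription, strictly decreasing.
#' @param pct_vol percent of structure volume in \[0, 100\], non-decreasing
#'   along the point order.
#' @param tps optional planning-system label.
#' @param source optional source label.
#' @param bin_width optional dose bin width (percent) recorded as metadata.
#' @return a data frame of class `dvh_curve`.
#' @export
dvh_curve <- function(pct_dose, pct_vol, tps = NULL, source = NULL,
                      bin_width = NULL) {
  if (length(pct_dose) != length(pct_vol) || length(pct_dose) < 1L)
    stop_invalid("pct_dose and pct_vol must be equal-length, non-empty")
  if (any(diff(pct_dose) >= 0))
    stop_invalid("pct_dose must be strictly decreasing")
  if (any(pct_vol < -1e-9) || any(pct_vol > 100 + 1e-9))
    stop_invalid("pct_vol must lie in [0, 100]")
  if (any(diff(pct_vol) < -1e-9))
    stop_invalid("pct_vol must be non-decreasing as dose decreases ",
                 "(cumulative DVH monotonicity)")
  structure(data.frame(pct_dose = pct_dose,
                       pct_vol = pmin(pmax(pct_vol, 0), 100)),
            class = c("dvh_curve", "data.frame"),
            tps = tps, source = source, bin_width = bin_width)
}

#' @export
print.dvh_curve <- function(x, ...) {
  lab <- c(attr(x, "tps"), attr(x, "source"))
  cat(sprintf("<dvh_curve> %d points%s\n", nrow(x),
              if (length(lab)) paste0(" (", paste(lab, collapse = ", "), ")")
              else ""))
  utils::str(as.data.frame(x), give.attr = FALSE)
  invisible(x)
}

#' Volume receiving at least a given relative dose
#'
#' Cumulative-DVH lookup: exact at a curve node, linear interpolation in dose
#' between bracketing nodes; querying outside the curve's dose range is an
#' error (the curve carries no information there).
#'
#' @param curve a [dvh_curve()].
#' @param pct_dose query dose level(s), percent of prescription.
#' @return percent of structure volume.
#' @examples
#' cv <- dvh_curve(c(100, 20.5), c(19.1, 39.2))
#' volume_at_dose(cv, 60.25)  # 29.15 by linear interpolation
#' @export
volume_at_dose <- function(curve, pct_dose) {
  stopifnot(inherits(curve, "dvh_curve"))
  lo <- min(curve$pct_dose); hi <- max(curve$pct_dose)
  if (any(pct_dose < lo - 1e-9) || any(pct_dose > hi + 1e-9))
    stop_range("queried dose ", paste(signif(pct_dose, 6), collapse = ", "),
               " outside curve range [", signif(lo, 6), ", ", signif(hi, 6), "]%")
  o <- order(curve$pct_dose)
  stats::approx(curve$pct_dose[o], curve$pct_vol[o],
                xout = pmin(pmax(pct_dose, lo), hi), ties = "ordered")$y
}

#' DVH curve CSV I/O
#'
#' The exchange dialect is a two-column CSV, header `pct_dose,pct_vol`, one
#' point per line in descending dose.  `read_dvh_csv` also accepts exports
#' with an absolute-dose column `dose_Gy` instead of `pct_dose`, normalized
#' by `prescription_gy`.
#'
#' @param curve a [dvh_curve()].
#' @param path file path.
#' @param prescription_gy prescription dose in Gy used to normalize a
#'   `dose_Gy` column; required for absolute-dose files.
#' @return `write_dvh_csv` returns `path` invisibly; `read_dvh_csv` a
#'   [dvh_curve()].
#' @export
write_dvh_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[c("pct_dose", "pct_vol")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dvh_csv
#' @export
read_dvh_csv <- function(path, prescription_gy = NULL) {
  tb <- utils::read.csv(path)
  if ("pct_dose" %in% names(tb)) {
    pd <- tb$pct_dose
  } else if ("dose_Gy" %in% names(tb)) {
    if (is.null(prescription_gy))
      stop_invalid("absolute-dose DVH file needs prescription_gy for normalization")
    check_scalar(prescription_gy, "prescription_gy")
    pd <- 100 * tb$dose_Gy / prescription_gy
  } else {
    stop_invalid("DVH CSV must have a pct_dose or dose_Gy column")
  }
  if (!"pct_vol" %in% names(tb)) stop_invalid("DVH CSV must have a pct_vol column")
  o <- order(pd, decreasing = TRUE)
  dvh_curve(pct_dose = pd[o], pct_vol = tb$pct_vol[o])
}

#' Plot cumulative DVH curves
#'
#' Draws the curve with relative dose on x and relative volume on y, the
#' conventional DVH presentation; additional curves can be overlaid for
#' hand-calculation versus TPS comparison.
#'
#' @param x a [dvh_curve()].
#' @param add logical, overlay on an existing plot.
#' @param ... further arguments passed to [graphics::lines()] /
#'   [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dvh_curve <- function(x, add = FALSE, ...) {
  if (add) {
    graphics::lines(x$pct_dose, x$pct_vol, ...)
  } else {
    graphics::plot(x$pct_dose, x$pct_vol, type = "l",
                   xlab = "Dose (% of prescription)",
                   ylab = "Volume (% of structure)",
                   ylim = c(0, 100), ...)
  }
  invisible(x)
}
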