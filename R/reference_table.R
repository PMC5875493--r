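# Hand-calculation reference tables: per-radius geometry term, g(r), dose,
# %Dose and %Vol — the independent standard a TPS DVH is compared against.

#' Build the hand-calculation reference table
#'
#' For each radius the table holds the transverse geometry term (inverse
#' square or line-source G-ratio), the radial dose function, the TG-43 dose,
#' the curvature-corrected partial volume %Vol and the relative dose
#' %Dose = 100 D(r)/D(r0).  %Dose is computed from unrounded doses and
#' rounded only for display; sub-radius variation of r across the narrow
#' cuboid width is ignored (negligible and shrinking with r).
#'
#' @param source a [source_model()].
#' @param prescription an [implant_prescription()]; defaults to the source's
#'   natural one.
#' @param structure a [cuboid_structure()].
#' @param factors a [correction_factors()] table.
#' @param radii radii in cm, strictly increasing; default 1..5.
#' @return a data frame of class `reference_table` with columns `r_cm`,
#'   `geometry_term`, `g`, `dose_Gy`, `pct_vol`, `pct_dose` (full precision;
#'   the print method applies display rounding).
#' @examples
#' build_reference_table(brachy_source("6711"))
#' @export
build_reference_table <- function(source,
                                  prescription = default_prescription(source),
                                  structure = cuboid_structure(),
                                  factors = correction_factors(),
                                  radii = 1:5) {
  stopifnot(inherits(source, "source_model"))
  if (length(radii) < 1L || any(diff(radii) <= 0))
    stop_invalid("radii must be non-empty and strictly increasing")
  dose <- tg43_dose(source, prescription, radii)
  d0 <- tg43_dose(source, prescription, prescription$reference_distance)
  tb <- data.frame(
    r_cm = radii,
    geometry_term = geometry_term(source, radii),
    g = radial_dose(source, radii),
    dose_Gy = dose,
    pct_vol = corrected_volume_fraction(structure, radii, factors),
    pct_dose = 100 * dose / d0)
  structure(tb,
            class = c("reference_table", "data.frame"),
            source_name = source$name, mode = source$mode,
            prescription = prescription)
}

#' @export
print.reference_table <- function(x, ...) {
  cat(sprintf("Hand-calculation reference table: source %s (%s mode)\n",
              attr(x, "source_name"), attr(x, "mode")))
  print(format_reference_table(x), row.names = FALSE)
  invisible(x)
}

#' Display rounding of a reference table
#'
#' Applies the conventional display rounding of dosimetry tables: doses to
#' 2 decimals, dimensionless ratios to 3, percentages to 1, ties away from
#' zero.
#'
#' @param table a [build_reference_table()] result.
#' @return a plain data frame of rounded values.
#' @export
format_reference_table <- function(table) {
  data.frame(
    r_cm = table$r_cm,
    geometry_term = round_half_away(table$geometry_term, 3),
    g = round_half_away(table$g, 3),
    dose_Gy = round_half_away(table$dose_Gy, 2),
    pct_vol = round_half_away(table$pct_vol, 1),
    pct_dose = round_half_away(table$pct_dose, 1))
}

#' Reference table CSV round trip
#'
#' Writes/reads the `r_cm,geometry_term,g,dose_Gy,pct_vol,pct_dose` dialect
#' at full precision (rounding belongs to the console display only, so
#' downstream comparisons are not quantized twice).
#'
#' @param table a `reference_table`.
#' @param path file path.
#' @return `write_reference_table` returns `path` invisibly;
#'   `read_reference_table` returns a `reference_table`.
#' @export
write_reference_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[c("r_cm", "geometry_term", "g",
                                          "dose_Gy", "pct_vol", "pct_dose")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  tb <- utils::read.csv(path)
  need <- c("r_cm", "geometry_term", "g", "dose_Gy", "pct_vol", "pct_dose")
  if (!all(need %in% names(tb)))
    stop_invalid("reference table CSV must have columns ",
                 paste(need, collapse = ","))
  structure(tb[need], class = c("reference_table", "data.frame"),
            source_name = NA_character_, mode = NA_character_)
}

#' Cumulative DVH curve from a reference table
#'
#' Each row maps to the cumulative-DVH point (x = %Dose, y = %Vol): pct_vol
#' percent of the structure receives at least pct_dose percent of the
#' prescription.  Points are ordered by strictly decreasing dose.
#'
#' @param table a `reference_table`.
#' @return a [dvh_curve()].
#' @export
dvh_curve_from_table <- function(table) {
  if (nrow(table) < 1L) stop_invalid("reference table is empty")
  o <- order(table$pct_dose, decreasing = TRUE)
  dvh_curve(pct_dose = table$pct_dose[o], pct_vol = table$pct_vol[o],
            tps = "TG-43 hand calculation",
            source = attr(table, "source_name"))
}
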