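# Key-value (YAML) configuration files for sources, structures and
# correction-factor tables, so a clinic can keep its commissioning
# constants under version control next to the QA scripts.

#' Source configuration file I/O
#'
#' Serializes a [source_model()] to a YAML key-value document with fields
#' `name`, `radionuclide`, `mode`, `Sk_U`, `Lambda_cGy_per_hU`,
#' `active_length_cm`, `half_life_h`, `dwell_time_h`, `radial_dose` (list of
#' `[r, g]` pairs) and optional `geometry_ratio` pairs.  Anisotropy override
#' functions are not serializable and are dropped with a warning.
#'
#' @param source a [source_model()].
#' @param path file path.
#' @return `write_source_config` returns `path` invisibly;
#'   `read_source_config` returns a [source_model()].
#' @examples
#' p <- tempfile(fileext = ".yaml")
#' write_source_config(brachy_source("VS2000"), p)
#' read_source_config(p)
#' @export
write_source_config <- function(source, path) {
  stopifnot(inherits(source, "source_model"))
  if (!is.null(source$anisotropy))
    warning("anisotropy override function is not serialized")
  cfg <- list(name = source$name, radionuclide = source$radionuclide,
              mode = source$mode,
              Sk_U = source$air_kerma_strength,
              Lambda_cGy_per_hU = source$dose_rate_constant,
              active_length_cm = source$active_length,
              half_life_h = source$half_life,
              dwell_time_h = source$dwell_time,
              radial_dose = unname(apply(source$radial_dose_table, 1, as.list)))
  if (!is.null(source$geometry_ratio_table))
    cfg$geometry_ratio <-
      unname(apply(source$geometry_ratio_table, 1, as.list))
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path, precision = 15)
  invisible(path)
}

#' @rdname write_source_config
#' @export
read_source_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("name", "mode", "Sk_U", "Lambda_cGy_per_hU", "radial_dose")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop_invalid("source config missing field(s): ", paste(miss, collapse = ", "))
  pairs <- do.call(rbind, lapply(cfg$radial_dose, function(p)
    data.frame(r = as.numeric(p[[1]]), g = as.numeric(p[[2]]))))
  gt <- if (!is.null(cfg$geometry_ratio))
    do.call(rbind, lapply(cfg$geometry_ratio, function(p)
      data.frame(r = as.numeric(p[[1]]), ratio = as.numeric(p[[2]]))))
  source_model(name = cfg$name,
               radionuclide = cfg$radionuclide %||% "unknown",
               mode = cfg$mode,
               air_kerma_strength = cfg$Sk_U,
               dose_rate_constant = cfg$Lambda_cGy_per_hU,
               active_length = cfg$active_length_cm,
               half_life = cfg$half_life_h,
               dwell_time = cfg$dwell_time_h,
               radial_dose_table = pairs,
               geometry_ratio_table = gt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Structure and correction-factor configuration I/O
#'
#' Same YAML dialect as [write_source_config()]: the structure document
#' carries `width_cm`, `height_cm`, `length_cm`; the factor document a list
#' of `[r, factor]` pairs, so site-specific factors can override the
#' published defaults per run.
#'
#' @param structure a [cuboid_structure()].
#' @param factors a [correction_factors()] table.
#' @param path file path.
#' @return writers return `path` invisibly; readers the parsed object.
#' @export
write_structure_config <- function(structure, path) {
  stopifnot(inherits(structure, "cuboid_structure"))
  yaml::write_yaml(list(width_cm = structure$width,
                        height_cm = structure$height,
                        length_cm = structure$length), path)
  invisible(path)
}

#' @rdname write_structure_config
#' @export
read_structure_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cuboid_structure(width = cfg$width_cm %||% 0.5,
                   height = cfg$height_cm %||% 0.5,
                   length = cfg$length_cm %||% 5.0)
}

#' @rdname write_structure_config
#' @export
write_factor_config <- function(factors, path) {
  yaml::write_yaml(list(factors = unname(apply(
    as.data.frame(factors)[c("r", "factor")], 1, as.list))), path)
  invisible(path)
}

#' @rdname write_structure_config
#' @export
read_factor_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  tb <- do.call(rbind, lapply(cfg$factors, function(p)
    data.frame(r = as.numeric(p[[1]]), factor = as.numeric(p[[2]]))))
  if (any(diff(tb$r) <= 0) || any(tb$factor < 1))
    stop_invalid("factor table needs increasing radii and factors >= 1")
  class(tb) <- c("correction_factor_table", "data.frame")
  tb
}
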