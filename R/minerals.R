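# Mineral definitions: reporting unit, molar mass, reference interval and
# reporting precision for each element of the serum panel.

.panel_units <- c("mmol/L", "mg/dL", "ug/dL")

normalize_unit <- function(unit) {
  u <- gsub("μ|µ", "u", unit)  # Greek mu / micro sign -> "u"
  if (!u %in% .panel_units)
    panel_error(sprintf("unknown unit '%s' (expected one of %s)",
                        unit, paste(.panel_units, collapse = ", ")),
                "unit_error")
  u
}

#' Define a serum mineral
#'
#' A mineral definition collects everything the pipeline needs to know about
#' one element of the panel: the reporting unit, the molar mass (for
#' mass-to-molar conversion), the population reference interval in the
#' reporting unit, and the number of decimals the routine clinical assay
#' reports (0 for elements reported to the integer, 1 for those reported to
#' the first decimal).
#'
#' @param name short element label, e.g. `"Na"`.
#' @param unit reporting unit; one of `"mmol/L"`, `"mg/dL"`, `"ug/dL"`
#'   (`"μg/dL"` is accepted and normalised).
#' @param molar_mass molar mass in g/mol; must be positive.
#' @param ri_low,ri_high reference-interval limits in `unit`; `ri_low` must
#'   be strictly below `ri_high`.
#' @param reporting_decimals 0 or 1; decimals retained by the standard assay.
#' @return An object of class `"mineral"`.
#' @examples
#' zn <- mineral("Zn", "ug/dL", 65.38, 80, 130, 0)
#' ri_flag(75, zn)
#' @export
mineral <- function(name, unit, molar_mass, ri_low, ri_high,
                    reporting_decimals) {
  unit <- normalize_unit(unit)
  if (!is.numeric(molar_mass) || molar_mass <= 0)
    panel_error("molar_mass must be positive", "invalid_definition")
  if (!is.numeric(ri_low) || !is.numeric(ri_high) || !(ri_low < ri_high))
    panel_error("reference interval requires ri_low < ri_high",
                "invalid_definition")
  if (!reporting_decimals %in% c(0, 1))
    panel_error("reporting_decimals must be 0 or 1", "invalid_definition")
  structure(
    list(name = as.character(name), unit = unit,
         molar_mass = as.numeric(molar_mass),
         ri_low = as.numeric(ri_low), ri_high = as.numeric(ri_high),
         reporting_decimals = as.integer(reporting_decimals)),
    class = "mineral")
}

#' @export
print.mineral <- function(x, ...) {
  cat(sprintf("<mineral> %s [%s]  RI %g-%g  M %g g/mol  %d decimal(s)\n",
              x$name, x$unit, x$ri_low, x$ri_high, x$molar_mass,
              x$reporting_decimals))
  invisible(x)
}

#' Default eight-mineral serum panel
#'
#' The shipped panel covers Na, K, Ca, P (inorganic phosphorus by the
#' standard assay), Mg, Fe, Zn and Cu with Japanese clinical reference
#' intervals and the reporting precision of the routine assays. Molar
#' masses are standard atomic weights.
#'
#' @return Named list of [mineral()] definitions.
#' @export
default_minerals <- function() {
  defs <- list(
    mineral("Na", "mmol/L", 22.99, 138, 145, 0),
    mineral("K",  "mmol/L", 39.10, 3.6, 4.8, 1),
    mineral("Ca", "mg/dL",  40.08, 8.8, 10.1, 1),
    mineral("P",  "mg/dL",  30.97, 2.7, 4.6, 1),
    mineral("Mg", "mg/dL",  24.31, 1.8, 2.5, 1),
    mineral("Fe", "ug/dL",  55.85, 40, 188, 0),
    mineral("Zn", "ug/dL",  65.38, 80, 130, 0),
    mineral("Cu", "ug/dL",  63.55, 71, 132, 0))
  stats::setNames(defs, vapply(defs, `[[`, "", "name"))
}

#' Load mineral definitions from a JSON config
#'
#' Expects a JSON array of objects with fields `name`, `unit`, `molar_mass`,
#' `ri_low`, `ri_high`, `reporting_decimals`.
#'
#' @param path file path to the JSON config.
#' @return Named list of [mineral()] definitions.
#' @export
read_minerals_json <- function(path) {
  if (!file.exists(path))
    panel_error(sprintf("config file '%s' not found", path), "io_error")
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  defs <- lapply(raw, function(d) {
    need <- c("name", "unit", "molar_mass", "ri_low", "ri_high",
              "reporting_decimals")
    miss <- setdiff(need, names(d))
    if (length(miss))
      panel_error(paste("mineral config missing fields:",
                        paste(miss, collapse = ", ")), "invalid_definition")
    mineral(d$name, d$unit, d$molar_mass, d$ri_low, d$ri_high,
            d$reporting_decimals)
  })
  stats::setNames(defs, vapply(defs, `[[`, "", "name"))
}

#' Convert a mass concentration to a molar concentration
#'
#' @param value concentration in mg/L; must be non-negative.
#' @param molar_mass molar mass in g/mol; must be positive.
#' @return Concentration in mmol/L (`value / molar_mass`).
#' @export
mass_to_molar <- function(value, molar_mass) {
  if (!is.numeric(molar_mass) || any(molar_mass <= 0))
    panel_error("molar_mass must be positive", "invalid_definition")
  if (any(value < 0, na.rm = TRUE))
    panel_error("mass concentration must be non-negative", "data_error")
  value / molar_mass
}

#' Convert a per-litre concentration to per-decilitre
#'
#' @param value concentration per litre (any amount unit); non-negative.
#' @return The same amount per decilitre (`value / 10`).
#' @export
per_liter_to_per_deciliter <- function(value) {
  if (any(value < 0, na.rm = TRUE))
    panel_error("concentration must be non-negative", "data_error")
  value / 10
}

#' Round to the standard assay's reporting precision
#'
#' Rounds half away from zero at 0 or 1 decimals, the convention of
#' clinical result reporting (base `round()` rounds half to even).
#'
#' @param value numeric vector.
#' @param decimals 0 or 1.
#' @return Rounded values.
#' @export
round_reported <- function(value, decimals) {
  if (length(decimals) != 1L || !decimals %in% c(0, 1))
    panel_error("reporting decimals must be 0 or 1", "invalid_definition")
  round_half_away(value, decimals)
}

#' Flag a value against a mineral's reference interval
#'
#' Values strictly below the lower limit are `"below"`, strictly above the
#' upper limit `"above"`; boundary values count as `"within"`.
#'
#' @param value numeric vector in the mineral's reporting unit.
#' @param definition a [mineral()].
#' @return Ordered factor with levels `below < within < above`.
#' @export
ri_flag <- function(value, definition) {
  stopifnot(inherits(definition, "mineral"))
  out <- ifelse(value < definition$ri_low, "below",
                ifelse(value > definition$ri_high, "above", "within"))
  factor(out, levels = c("below", "within", "above"), ordered = TRUE)
}

#' Construct a paired measurement panel for one mineral
#'
#' Binds per-subject paired measurements (standard assay vs ICP-MS) to a
#' mineral definition. `hemolyzed` marks visually hemolyzed sera;
#' `provenance` is an optional ground-truth tag set by the synthetic
#' generator (`clean`, `hemolysis`, `contamination`).
#'
#' @param definition a [mineral()].
#' @param subject_id unique subject identifiers.
#' @param standard_value,icpms_value paired concentrations in the reporting
#'   unit; finite and non-negative.
#' @param hemolyzed logical; defaults to all `FALSE`.
#' @param provenance optional character tags.
#' @return An object of class `"paired_panel"`: a list with the mineral
#'   definition and a data frame `data`.
#' @export
paired_panel <- function(definition, subject_id, standard_value, icpms_value,
                         hemolyzed = NULL, provenance = NULL) {
  stopifnot(inherits(definition, "mineral"))
  n <- length(subject_id)
  if (length(standard_value) != n || length(icpms_value) != n)
    panel_error("subject_id, standard_value, icpms_value lengths differ",
                "data_error")
  if (anyDuplicated(subject_id))
    panel_error("subject_ids must be unique within a panel", "data_error")
  vals <- c(standard_value, icpms_value)
  if (any(!is.finite(vals)) || any(vals < 0))
    panel_error("measurements must be finite and non-negative", "data_error")
  hemolyzed <- if (is.null(hemolyzed)) rep(FALSE, n) else as.logical(hemolyzed)
  provenance <- if (is.null(provenance)) rep("clean", n)
                else as.character(provenance)
  structure(
    list(mineral = definition,
         data = data.frame(subject_id = as.character(subject_id),
                           standard_value = as.numeric(standard_value),
                           icpms_value = as.numeric(icpms_value),
                           hemolyzed = hemolyzed,
                           provenance = provenance,
                           stringsAsFactors = FALSE)),
    class = "paired_panel")
}

#' @export
print.paired_panel <- function(x, ...) {
  cat(sprintf("<paired_panel> %s [%s], n = %d (%d hemolyzed)\n",
              x$mineral$name, x$mineral$unit, nrow(x$data),
              sum(x$data$hemolyzed)))
  invisible(x)
}

#' @export
nobs.paired_panel <- function(object, ...) nrow(object$data)
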