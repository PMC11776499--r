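# Long-format panel CSV reading/writing and JSON report assembly.

#' Write panels to a long-format CSV
#'
#' Columns: `subject_id, mineral, standard_value, icpms_value, unit,
#' hemolyzed, provenance`. Values are written at 6 significant digits;
#' RFC-4180, UTF-8, "." decimal separator.
#'
#' @param panels named list of [paired_panel()]s.
#' @param path output path.
#' @export
write_panel_csv <- function(panels, path) {
  rows <- lapply(panels, function(p) {
    d <- p$data
    data.frame(subject_id = d$subject_id, mineral = p$mineral$name,
               standard_value = signif(d$standard_value, 6),
               icpms_value = signif(d$icpms_value, 6),
               unit = p$mineral$unit,
               hemolyzed = as.integer(d$hemolyzed),
               provenance = d$provenance, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a long-format panel CSV
#'
#' Expects the header `subject_id, mineral, standard_value, icpms_value,
#' unit, hemolyzed[, provenance]`. Rows are grouped by mineral, units are
#' validated against the mineral definitions, and `hemolyzed` accepts
#' 0/1/true/false. A file without a `hemolyzed` column loads with all flags
#' false (a warning is emitted).
#'
#' @param path CSV path.
#' @param minerals named list of [mineral()] definitions (default the
#'   shipped panel).
#' @return Named list of [paired_panel()]s.
#' @export
read_panel_csv <- function(path, minerals = default_minerals()) {
  if (!file.exists(path))
    panel_error(sprintf("panel file '%s' not found", path), "io_error")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "mineral", "standard_value", "icpms_value", "unit")
  miss <- setdiff(need, names(d))
  if (length(miss))
    panel_error(paste("panel CSV missing columns:",
                      paste(miss, collapse = ", ")), "schema_error")
  if (!"hemolyzed" %in% names(d)) {
    warning("panel CSV has no 'hemolyzed' column; assuming all false")
    d$hemolyzed <- FALSE
  }
  if (!"provenance" %in% names(d)) d$provenance <- "clean"
  bad <- setdiff(unique(d$mineral), names(minerals))
  if (length(bad)) {
    row <- which(d$mineral %in% bad)[1]
    panel_error(sprintf("unknown mineral '%s' at row %d", d$mineral[row], row),
                "schema_error")
  }
  dup <- duplicated(d[, c("subject_id", "mineral")])
  if (any(dup))
    panel_error(sprintf("duplicate (subject, mineral) at row %d", which(dup)[1]),
                "schema_error")
  hemo <- tolower(as.character(d$hemolyzed)) %in% c("1", "true")

  present <- intersect(names(minerals), unique(d$mineral))
  panels <- lapply(present, function(nm) {
    def <- minerals[[nm]]
    rows <- d$mineral == nm
    units <- vapply(unique(d$unit[rows]), normalize_unit, "")
    if (any(units != def$unit))
      panel_error(sprintf("unit '%s' for %s does not match definition '%s'",
                          units[units != def$unit][1], nm, def$unit),
                  "unit_error")
    paired_panel(def, d$subject_id[rows], d$standard_value[rows],
                 d$icpms_value[rows], hemolyzed = hemo[rows],
                 provenance = d$provenance[rows])
  })
  stats::setNames(panels, present)
}

report_payload <- function(x) {
  if (inherits(x, "agreement_report")) {
    list(mineral = x$mineral, unit = x$unit,
         fit = if (is.null(x$fit)) NULL else
           list(slope = unname(coef(x$fit)["slope"]),
                intercept = unname(coef(x$fit)["intercept"]),
                slope_ci = as.list(x$fit$slope_ci),
                intercept_ci = as.list(x$fit$intercept_ci),
                n_obs = x$fit$n_obs, n_pairs_used = x$fit$n_pairs_used,
                offset_k = x$fit$offset_k, level = x$fit$level),
         fit_error = x$fit_error,
         verdict = x$verdict,
         correlation = if (is.null(x$correlation)) NULL else
           list(pearson_r = x$correlation$pearson_r,
                pearson_ci = as.list(x$correlation$pearson_ci),
                spearman_rho = x$correlation$spearman_rho,
                spearman_ci = as.list(x$correlation$spearman_ci),
                strength_category = x$correlation$strength_category),
         outliers = list(hemolyzed_ids = x$outliers$hemolyzed_ids,
                         residual_outlier_ids = x$outliers$residual_outlier_ids,
                         threshold = x$outliers$threshold,
                         degenerate = x$outliers$degenerate),
         relative_error_pre = x$ba_pre[c("n_used", "mean_re", "sd_re",
                                         "loa_lower", "loa_upper")],
         relative_error_post = c(x$ba_post[c("n_used", "mean_re", "sd_re",
                                             "loa_lower", "loa_upper")],
                                 list(mean_ci = as.list(x$ba_post$mean_ci),
                                      loa_lower_ci = as.list(x$ba_post$loa_lower_ci),
                                      loa_upper_ci = as.list(x$ba_post$loa_upper_ci),
                                      excluded_ids = x$ba_post$excluded_ids)),
         seed = x$seed, B = x$B)
  } else if (inherits(x, "screening_result")) {
    list(mineral = x$mineral, kind = x$kind, direction = x$direction,
         n_positive = x$n_positive, n_negative = x$n_negative,
         auc = x$auc, auc_ci = as.list(x$auc_ci),
         cutoff = x$cutoff, cutoff_ci = as.list(x$cutoff_ci),
         sensitivity = x$sensitivity,
         sensitivity_ci = as.list(x$sensitivity_ci),
         specificity = x$specificity,
         specificity_ci = as.list(x$specificity_ci),
         seed = x$seed, B = x$B)
  } else if (inherits(x, "mineral_summary")) {
    out <- unclass(x)
    out$qcd_ci <- as.list(x$qcd_ci)
    out$cv_ci <- as.list(x$cv_ci)
    out
  } else panel_error("unknown report type", "io_error")
}

#' Write analysis reports to disk
#'
#' One JSON document per mineral (carrying the package version, seeds, and
#' config echo for reproducibility) plus, for agreement reports, a combined
#' flat CSV. Timestamps are deliberately excluded so reruns with the same
#' config are byte-identical.
#'
#' @param reports named list of `agreement_report`, `screening_result`
#'   and/or `mineral_summary` objects.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(reports, dir) {
  if (length(reports) == 0L) {
    warning("no reports to write")
    return(invisible(character()))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  version <- as.character(utils::packageVersion("serumpanel"))
  paths <- character()
  for (nm in names(reports)) {
    payload <- c(list(package_version = version), report_payload(reports[[nm]]))
    p <- file.path(dir, paste0(nm, ".json"))
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    paths <- c(paths, p)
  }
  ag <- Filter(function(x) inherits(x, "agreement_report"), reports)
  if (length(ag)) {
    flat <- do.call(rbind, lapply(ag, agreement_row))
    p <- file.path(dir, "agreement_summary.csv")
    utils::write.csv(flat, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  sm <- Filter(function(x) inherits(x, "mineral_summary"), reports)
  if (length(sm)) {
    flat <- do.call(rbind, lapply(sm, summary_row))
    p <- file.path(dir, "descriptives.csv")
    utils::write.csv(flat, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
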