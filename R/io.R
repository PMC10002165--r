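# Reading and writing long-format section-level expression tables.
#
# The on-disk format is one row per (animal, group, ROI, section) optical
# density value in relative dpm, with a header line:
#   animal_id,group,roi,section,value

.required_cols <- c("animal_id", "group", "roi", "section", "value")

#' Read a long-format section-level expression table
#'
#' Parses a CSV or TSV file with one row per (animal, treatment group, ROI,
#' section replicate) measurement. Values are relative-dpm optical densities
#' and must be non-negative. Every ROI must be either an analysis ROI of the
#' registry or its reference channel.
#'
#' @param path Path to a delimited text file with header columns
#'   `animal_id`, `group`, `roi`, `section`, `value`. Files ending in
#'   `.tsv`/`.txt` are read as tab-separated, anything else as
#'   comma-separated.
#' @param registry A [roi_registry()]. Rows whose `roi` is neither in the
#'   registry nor equal to its reference channel are rejected.
#' @param groups Optional character vector of allowed group labels; when
#'   given, any other label is a validation error. The default (`NULL`)
#'   accepts arbitrary labels.
#'
#' @return A tibble of section measurements with columns `animal`, `group`,
#'   `roi`, `section`, `value`, one row per input row.
#' @seealso [average_sections()], [normalize_by_reference()]
#' @export
read_expression_long <- function(path, registry = roi_registry(),
                                 groups = NULL) {
  .assert_registry(registry)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "iegnet_format_error")
  }
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(.required_cols, names(raw))
  if (length(missing_cols)) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "iegnet_format_error")
  }
  out <- tibble(
    animal  = as.character(raw$animal_id),
    group   = as.character(raw$group),
    roi     = as.character(raw$roi),
    section = as.integer(raw$section),
    value   = as.numeric(raw$value)
  )
  validate_measurements(out, registry, groups = groups)
  out
}

#' Write section measurements back to the long CSV format
#'
#' @param measurements A tibble as returned by [read_expression_long()] or
#'   [generate_study()].
#' @param path Output file path; comma-separated with the canonical header.
#' @return `path`, invisibly.
#' @export
write_expression_long <- function(measurements, path) {
  df <- data.frame(
    animal_id = measurements$animal,
    group     = measurements$group,
    roi       = measurements$roi,
    section   = measurements$section,
    value     = measurements$value
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a tibble of section measurements against a registry
#'
#' @inheritParams read_expression_long
#' @param measurements Tibble with columns `animal`, `group`, `roi`,
#'   `section`, `value`.
#' @return The measurements, invisibly, after checks.
#' @export
validate_measurements <- function(measurements, registry = roi_registry(),
                                  groups = NULL) {
  .assert_registry(registry)
  known <- c(registry_rois(registry), reference_roi(registry))
  bad_roi <- setdiff(unique(measurements$roi), known)
  if (length(bad_roi)) {
    abort(paste0("Unknown ROI abbreviation(s): ",
                 paste(bad_roi, collapse = ", ")),
          class = "iegnet_validation_error")
  }
  if (!is.null(groups)) {
    bad_grp <- setdiff(unique(measurements$group), groups)
    if (length(bad_grp)) {
      abort(paste0("Unknown group label(s): ",
                   paste(bad_grp, collapse = ", ")),
            class = "iegnet_validation_error")
    }
  }
  if (anyNA(measurements$value)) {
    abort("Measurement values contain missing entries.",
          class = "iegnet_validation_error")
  }
  if (any(measurements$value < 0)) {
    abort("Measurement values must be non-negative (relative dpm).",
          class = "iegnet_validation_error")
  }
  if (anyNA(measurements$section) || any(measurements$section < 1)) {
    abort("Section indices must be positive integers.",
          class = "iegnet_validation_error")
  }
  invisible(measurements)
}

#' Average section replicates per animal and ROI
#'
#' Adjacent-section replicates of the same animal and ROI are combined into
#' their arithmetic mean, reported with the sample standard deviation
#' (0 when only a single replicate is present). The canonical design uses
#' three adjacent sections; a warning is emitted when any (animal, ROI) cell
#' deviates from that replicate count.
#'
#' @param measurements Section-level tibble (columns `animal`, `group`,
#'   `roi`, `section`, `value`).
#' @param expected_sections Replicate count that triggers a warning when not
#'   matched (default 3). Use `NA` to silence the check.
#' @return Tibble with one row per (animal, roi): columns `animal`, `group`,
#'   `roi`, `value` (the mean), `sd`, `n_sections`.
#' @export
average_sections <- function(measurements, expected_sections = 3) {
  if (nrow(measurements) == 0) {
    abort("No measurements to average.", class = "iegnet_validation_error")
  }
  out <- measurements |>
    group_by(.data$animal, .data$group, .data$roi) |>
    summarise(
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
      n_sections = dplyr::n(),
      value = mean(.data$value),
      .groups = "drop"
    ) |>
    select("animal", "group", "roi", "value", "sd", "n_sections")
  if (!is.na(expected_sections) && any(out$n_sections != expected_sections)) {
    warn(paste0("Some (animal, ROI) cells have a replicate count other than ",
                expected_sections, "."))
  }
  out
}
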