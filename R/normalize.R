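# Reference-region normalization and the study-dataset container.

#' Normalize averaged expression against the reference region
#'
#' Each animal's ROI values are put on a common scale using that animal's
#' own reference-channel value (the genu of the corpus callosum in the
#' default registry, a region expected to carry no signal). In `"ratio"`
#' mode (default) every ROI value is divided by the animal's reference
#' value; in `"subtract"` mode the reference value is subtracted. The
#' reference channel itself is removed from the analysis table.
#'
#' Ratio scaling is the default because published group means on the
#' normalized scale sit near 0–1 with differences of roughly 0.1–0.7,
#' which is consistent with a ratio rather than a difference scale; the
#' subtractive variant is kept behind the `mode` flag.
#'
#' @param averaged Per-(animal, ROI) tibble as returned by
#'   [average_sections()] (columns `animal`, `group`, `roi`, `value`; extra
#'   columns are ignored). Must contain one reference-channel row per
#'   animal.
#' @param registry A [roi_registry()]; its reference channel is used.
#' @param mode `"ratio"` (per-animal division) or `"subtract"`.
#' @return An `ieg_study`: a long tibble (`animal`, `group`, `roi`,
#'   `value`) of normalized values covering every registry ROI for every
#'   animal, with the registry and normalization settings attached as
#'   attributes.
#' @export
normalize_by_reference <- function(averaged, registry = roi_registry(),
                                   mode = c("ratio", "subtract")) {
  .assert_registry(registry)
  mode <- match.arg(mode)
  ref <- reference_roi(registry)

  refs <- averaged |> filter(.data$roi == ref)
  if (anyDuplicated(refs$animal)) {
    abort("Multiple reference-channel rows for one animal; average sections first.",
          class = "iegnet_validation_error")
  }
  analysis <- averaged |> filter(.data$roi != ref)
  no_ref <- setdiff(unique(analysis$animal), refs$animal)
  if (length(no_ref)) {
    abort(paste0("No reference ('", ref, "') value for animal(s): ",
                 paste(no_ref, collapse = ", ")),
          class = "iegnet_validation_error")
  }
  if (mode == "ratio" && any(refs$value == 0)) {
    zero <- refs$animal[refs$value == 0]
    abort(paste0("Reference value is 0 in ratio mode for animal(s): ",
                 paste(zero, collapse = ", ")),
          class = "iegnet_validation_error")
  }

  ref_lookup <- setNames(refs$value, refs$animal)
  normalized <- analysis |>
    mutate(value = if (mode == "ratio") {
      .data$value / ref_lookup[.data$animal]
    } else {
      .data$value - ref_lookup[.data$animal]
    }) |>
    select("animal", "group", "roi", "value")

  ieg_study(normalized, registry,
            provenance = list(normalization = mode, reference_roi = ref))
}

#' Construct a study dataset of normalized expression values
#'
#' An `ieg_study` is the container the correlation, contrast and network
#' stages operate on: a long tibble of normalized per-animal, per-ROI
#' expression values whose ROI set is complete against a shared registry.
#'
#' @param normalized Long tibble with columns `animal`, `group`, `roi`,
#'   `value` and no missing cells: every animal must have a value for every
#'   registry ROI.
#' @param registry A [roi_registry()].
#' @param provenance Named list of free-form metadata (normalization mode,
#'   generator settings, ...).
#' @return The validated `ieg_study` tibble.
#' @export
ieg_study <- function(normalized, registry = roi_registry(),
                      provenance = list()) {
  .assert_registry(registry)
  normalized <- as_tibble(normalized)[, c("animal", "group", "roi", "value")]
  extra <- setdiff(unique(normalized$roi), registry_rois(registry))
  if (length(extra)) {
    abort(paste0("ROIs not in registry: ", paste(extra, collapse = ", ")),
          class = "iegnet_validation_error")
  }
  cells <- normalized |> count(.data$animal, .data$roi)
  if (any(cells$n > 1)) {
    abort("Duplicated (animal, ROI) cells in study data.",
          class = "iegnet_validation_error")
  }
  n_animals <- length(unique(normalized$animal))
  if (nrow(cells) != n_animals * nrow(registry)) {
    abort("Incomplete study data: every animal needs a value for every registry ROI.",
          class = "iegnet_validation_error")
  }
  structure(normalized,
            registry = registry,
            provenance = provenance,
            class = c("ieg_study", class(tibble())))
}

#' @rdname ieg_study
#' @param study An `ieg_study`.
#' @export
study_registry <- function(study) {
  attr(study, "registry")
}

#' @rdname ieg_study
#' @export
study_groups <- function(study) {
  unique(study$group)
}

#' Extract one group's animals-by-ROIs expression matrix
#'
#' @param study An [ieg_study()].
#' @param group Group label present in the study.
#' @return Numeric matrix with one row per animal and one column per
#'   registry ROI, columns in registry order; attribute `group` carries the
#'   label. At least 3 animals are required (the correlation p-value needs
#'   `n - 2 >= 1` degrees of freedom).
#' @export
expression_table <- function(study, group) {
  registry <- study_registry(study)
  g <- group
  sub <- study |> filter(.data$group == g)
  if (nrow(sub) == 0) {
    abort(paste0("Group not present in study: ", group),
          class = "iegnet_validation_error")
  }
  animals <- unique(sub$animal)
  rois <- registry_rois(registry)
  m <- matrix(NA_real_, nrow = length(animals), ncol = length(rois),
              dimnames = list(animals, rois))
  m[cbind(match(sub$animal, animals), match(sub$roi, rois))] <- sub$value
  if (anyNA(m)) {
    abort(paste0("Missing (animal, ROI) cells for group ", group),
          class = "iegnet_validation_error")
  }
  if (nrow(m) < 3) {
    abort("At least 3 animals per group are required.",
          class = "iegnet_validation_error")
  }
  attr(m, "group") <- group
  m
}

#' Write per-group wide tables of normalized values
#'
#' One CSV per group, animals in rows and registry ROIs in columns.
#'
#' @param study An [ieg_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_study_wide <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(study_groups(study), function(g) {
    m <- expression_table(study, g)
    path <- file.path(dir, paste0("normalized_", .slug(g), ".csv"))
    utils::write.csv(data.frame(animal_id = rownames(m), m,
                                check.names = FALSE),
                     path, row.names = FALSE)
    path
  }, character(1))
  invisible(paths)
}

.slug <- function(x) gsub("[^A-Za-z0-9]+", "-", x)
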