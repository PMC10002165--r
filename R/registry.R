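# ROI registry: the ordered set of analysis regions plus the reference
# (white-matter) channel used for normalization.

.default_rois <- function() {
  tibble::tribble(
    ~roi,     ~region,
    "LSV",    "Lateral septal nucleus, ventral",
    "Tu",     "Olfactory tubercle",
    "LSD",    "Lateral septal nucleus, dorsal",
    "LSI",    "Lateral septal nucleus, intermediate",
    "Icj",    "Islands of Calleja",
    "VP",     "Ventral pallidum",
    "Shi",    "Septohippocampal nucleus",
    "MS",     "Medial septum",
    "VDB",    "Nucleus of the vertical limb of the diagonal band",
    "Ig",     "Indusium griseum",
    "S1dz",   "Somatosensory 1, dysgranular zone",
    "AIV",    "Agranular insular area, ventral",
    "S1ULp",  "Upper lip of the primary somatosensory cortex",
    "GI",     "Granular insular cortex",
    "DI",     "Dysgranular insular cortex",
    "AcSh",   "Accumbens nucleus, shell",
    "Pir",    "Piriform cortex",
    "AID",    "Agranular insular area, dorsal",
    "LSS",    "Lateral stripe of striatum",
    "Cg2",    "Cingulate cortex, area 2",
    "CPDL",   "Dorsolateral caudate putamen",
    "CPVL",   "Ventrolateral caudate putamen",
    "CPVM",   "Ventromedial caudate putamen",
    "Cg1",    "Cingulate cortex, area 1",
    "M2",     "Supplementary motor cortex",
    "CPDM",   "Dorsomedial caudate putamen",
    "Den",    "Dorsal endopiriform nucleus",
    "M1",     "Primary motor cortex",
    "S1Fl",   "Somatosensory 1, forelimb region",
    "AcCo",   "Accumbens nucleus, core",
    "Cl",     "Claustrum",
    "S1j",    "Somatosensory 1, jaw region",
    "S1jO",   "Primary somatosensory cortex, jaw region, oral surface"
  )
}

#' ROI registry
#'
#' The registry fixes the identity and display order of the analysis regions
#' of interest (ROIs) and names the reference channel used for normalization.
#' The default registry holds the 33 striatal-level ROIs of the rodent
#' forebrain densitometry design, with the genu of the corpus callosum
#' (`"gcc"`) — a white-matter region expected to carry no hybridization
#' signal — as reference.
#'
#' @param rois A data frame with columns `roi` (unique short abbreviation)
#'   and `region` (full anatomical name), in the desired display order.
#'   `NULL` (default) uses the built-in 33-ROI registry.
#' @param reference_roi Abbreviation of the reference channel. Must not be
#'   among the analysis ROIs.
#'
#' @return A tibble of class `roi_registry` with columns `roi` and `region`
#'   and attribute `reference_roi`.
#' @examples
#' reg <- roi_registry()
#' nrow(reg)            # 33
#' reference_roi(reg)   # "gcc"
#' @export
roi_registry <- function(rois = NULL, reference_roi = "gcc") {
  rois <- rois %||% .default_rois()
  rois <- as_tibble(rois)
  if (!all(c("roi", "region") %in% names(rois))) {
    abort("`rois` must have columns `roi` and `region`.",
          class = "iegnet_format_error")
  }
  rois$roi <- as.character(rois$roi)
  if (anyDuplicated(rois$roi)) {
    abort("ROI abbreviations must be unique.", class = "iegnet_validation_error")
  }
  if (reference_roi %in% rois$roi) {
    abort("`reference_roi` must not be among the analysis ROIs.",
          class = "iegnet_validation_error")
  }
  structure(rois[, c("roi", "region")],
            reference_roi = as.character(reference_roi),
            class = c("roi_registry", class(tibble())))
}

#' @rdname roi_registry
#' @param registry A `roi_registry`.
#' @export
reference_roi <- function(registry) {
  attr(registry, "reference_roi")
}

#' @rdname roi_registry
#' @export
registry_rois <- function(registry) {
  registry$roi
}

.assert_registry <- function(registry) {
  if (!inherits(registry, "roi_registry")) {
    abort("Expected a `roi_registry` object (see `roi_registry()`).",
          class = "iegnet_validation_error")
  }
  invisible(registry)
}
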