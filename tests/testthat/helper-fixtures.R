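# Small in-code fixtures shared across test files.

# A registry of k generic ROIs (reference "gcc"), for fast tests that do
# not need the full 33-ROI anatomy.
small_registry <- function(k = 4) {
  roi_registry(
    tibble::tibble(roi = paste0("R", seq_len(k)),
                   region = paste("Region", seq_len(k)))
  )
}

# Build an ieg_study directly from named animals-by-ROIs matrices
# (one per group).
study_from_matrices <- function(mats, registry = NULL) {
  k <- ncol(mats[[1]])
  registry <- registry %||% small_registry(k)
  rois <- registry_rois(registry)
  long <- purrr::imap(mats, function(m, g) {
    animals <- rownames(m) %||% paste0(gsub("[^A-Za-z0-9]+", "", g), "_",
                                       seq_len(nrow(m)))
    tibble::tibble(
      animal = rep(animals, times = k),
      group = g,
      roi = rep(rois, each = nrow(m)),
      value = as.vector(m)
    )
  }) |> dplyr::bind_rows()
  ieg_study(long, registry)
}

# Long-format section measurements for a couple of animals, with the
# reference channel included.
tiny_measurements <- function() {
  tibble::tibble(
    animal = rep(c("a1", "a2"), each = 6),
    group = "G1",
    roi = rep(c("R1", "R2", "gcc"), times = 4),
    section = rep(rep(1:2, each = 3), times = 2),
    value = c(1, 2, 2, 3, 4, 2,   2, 6, 4, 4, 8, 4)
  )
}
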