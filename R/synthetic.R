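# Synthetic study generator: multivariate-normal animal-level expression
# with a target inter-ROI correlation structure, plus section-replicate
# noise and an independent reference (gcc) channel.

# Symmetric PSD square root via eigendecomposition; tiny negative
# eigenvalues (numerical) are clamped at 0.
.sqrt_psd <- function(R, tol = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -tol) {
    abort("Target correlation matrix is not positive semi-definite.",
          class = "iegnet_validation_error")
  }
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' Per-group configuration of the synthetic generator
#'
#' @param label Group label (free string).
#' @param roi_means Named numeric vector of expected normalized expression
#'   per ROI (length = number of registry ROIs).
#' @param correlation Target inter-ROI correlation matrix (symmetric, unit
#'   diagonal, positive semi-definite).
#' @param animal_sd Per-ROI marginal standard deviation of the animal-level
#'   values; a scalar is recycled.
#' @param n_animals Animals in the group (>= 3; study default 5).
#' @param section_sd Standard deviation of independent within-animal
#'   replicate noise added to each section (default 0: sections replicate
#'   the animal value exactly, so the imposed correlation is observed
#'   undiluted).
#' @param n_sections Section replicates per animal (default 3).
#' @param reference_mean,reference_sd Mean and sd of the independently
#'   drawn reference (gcc) channel. The defaults (1, 0) make ratio
#'   normalization exact, so the target correlation structure survives the
#'   normalization stage unchanged.
#' @return A validated `synthetic_group_config` list.
#' @export
synthetic_group_config <- function(label, roi_means, correlation, animal_sd,
                                   n_animals = 5, section_sd = 0,
                                   n_sections = 3, reference_mean = 1,
                                   reference_sd = 0) {
  k <- length(roi_means)
  animal_sd <- rep_len(animal_sd, k)
  stopifnot(is.matrix(correlation), nrow(correlation) == k,
            ncol(correlation) == k)
  if (max(abs(correlation - t(correlation))) > 1e-12 ||
      max(abs(diag(correlation) - 1)) > 1e-12) {
    abort("Correlation matrix must be symmetric with unit diagonal.",
          class = "iegnet_validation_error")
  }
  if (min(eigen(correlation, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8) {
    abort("Correlation matrix must be positive semi-definite.",
          class = "iegnet_validation_error")
  }
  if (any(c(animal_sd, section_sd, reference_sd) < 0)) {
    abort("Standard deviations must be >= 0.",
          class = "iegnet_validation_error")
  }
  if (n_animals < 3) {
    abort("n_animals must be >= 3.", class = "iegnet_validation_error")
  }
  structure(list(label = label, n_animals = as.integer(n_animals),
                 roi_means = roi_means, correlation = correlation,
                 animal_sd = animal_sd, section_sd = section_sd,
                 n_sections = as.integer(n_sections),
                 reference_mean = reference_mean,
                 reference_sd = reference_sd),
            class = "synthetic_group_config")
}

.block_correlation <- function(rois, background, blocks, block_extra) {
  k <- length(rois)
  R <- matrix(background, k, k, dimnames = list(rois, rois))
  for (b in blocks) {
    idx <- match(b, rois)
    R[idx, idx] <- R[idx, idx] + block_extra
  }
  diag(R) <- 1
  R
}

# Sign-flip a set of variables: D R D with D = diag(+-1). Exactly preserves
# positive semi-definiteness while negating the flipped rows/columns.
.flip_rois <- function(R, rois_to_flip) {
  d <- ifelse(rownames(R) %in% rois_to_flip, -1, 1)
  R2 <- R * outer(d, d)
  diag(R2) <- 1
  R2
}

#' Build a synthetic study configuration from a named preset
#'
#' Three structural presets cover the situations the analysis stages need
#' to be exercised against:
#'
#' * `"null"` — four identically configured groups with *no* inter-ROI
#'   correlation (identity target matrix) and no group differences; the
#'   reference for type-I-error calibration of every test.
#' * `"paper_like"` — four groups emulating the qualitative structure of a
#'   ketamine/asenapine design: strongly coupled striatal and insular
#'   blocks and a limbic row in the control-like groups; the KET-like group
#'   has the indusium griseum (Ig) and medial cingulate (Cg2) rows
#'   sign-flipped (negative correlations with the rest), restored to
#'   positive in the KET/ASE-like group, whose mean expression is also
#'   restored from the lowered KET level.
#' * `"edge_difference"` — two groups (`"A"`, `"B"`) identical except for a
#'   single ROI pair whose correlation is `delta_r` in `A` and 0 in `B`;
#'   the minimal differential-edge scenario.
#'
#' Within-system coupling in `paper_like` is set to r = 0.8 over a 0.2
#' background: with only 5 animals per group, only strong coupling is
#' detectable at all, matching the dense dark blocks such designs display.
#'
#' @param preset One of `"null"`, `"paper_like"`, `"edge_difference"`.
#' @param registry A [roi_registry()].
#' @param n_animals Animals per group (default 5, the study design).
#' @param n_sections Sections per animal (default 3).
#' @param pair Length-2 ROI vector, the differing pair for
#'   `"edge_difference"`.
#' @param delta_r Correlation difference injected at `pair` (default 0.9).
#' @param seed Optional default seed stored in the configuration.
#' @return A `synthetic_study_config`: list with elements `registry`,
#'   `groups` (named list of [synthetic_group_config()]) and `seed`.
#' @export
study_template <- function(preset = c("null", "paper_like", "edge_difference"),
                           registry = roi_registry(), n_animals = 5,
                           n_sections = 3, pair = NULL, delta_r = 0.9,
                           seed = NULL) {
  preset <- match.arg(preset)
  .assert_registry(registry)
  rois <- registry_rois(registry)
  k <- length(rois)
  base_means <- setNames(rep(0.5, k), rois)
  base_sd <- 0.15

  mk <- function(label, correlation, means = base_means) {
    synthetic_group_config(label, roi_means = means,
                           correlation = correlation, animal_sd = base_sd,
                           n_animals = n_animals, n_sections = n_sections)
  }

  groups <- switch(
    preset,
    null = {
      R <- diag(k); dimnames(R) <- list(rois, rois)
      labs <- c("VEH/VEH", "VEH/ASE", "KET/VEH", "KET/ASE")
      setNames(lapply(labs, mk, correlation = R), labs)
    },
    paper_like = {
      striatal <- c("LSS", "CPDM", "CPDL", "CPVL", "CPVM", "AcCo", "AcSh")
      insular  <- c("GI", "DI", "AID", "AIV", "Cl")
      limbic   <- c("Ig", "Cg2", "LSD", "LSI", "LSV", "MS", "Shi")
      blocks <- list(striatal, insular, limbic)
      base  <- .block_correlation(rois, 0.2, blocks, 0.6)
      weak  <- .block_correlation(rois, 0.0, blocks, 0.5)
      ket   <- .flip_rois(base, c("Ig", "Cg2"))
      ket_means <- base_means - 0.2
      list("VEH/VEH" = mk("VEH/VEH", base),
           "VEH/ASE" = mk("VEH/ASE", weak),
           "KET/VEH" = mk("KET/VEH", ket, means = ket_means),
           "KET/ASE" = mk("KET/ASE", base))
    },
    edge_difference = {
      pair <- pair %||% rois[1:2]
      if (!all(pair %in% rois) || length(pair) != 2) {
        abort("`pair` must name two registry ROIs.",
              class = "iegnet_validation_error")
      }
      RA <- diag(k); dimnames(RA) <- list(rois, rois)
      RB <- RA
      RA[pair[1], pair[2]] <- RA[pair[2], pair[1]] <- delta_r
      list("A" = mk("A", RA), "B" = mk("B", RB))
    }
  )

  structure(list(registry = registry, groups = groups, seed = seed,
                 preset = preset),
            class = "synthetic_study_config")
}

#' Generate a synthetic study dataset
#'
#' Animal-level ROI vectors are drawn from a multivariate normal with the
#' group's target correlation (imposed through the symmetric square root of
#' the correlation matrix), scaled by the marginal `animal_sd` and shifted
#' by `roi_means`. Each section value is the animal value plus independent
#' Gaussian replicate noise; the reference (gcc) channel is drawn
#' independently per animal. The raw section table is then pushed through
#' the actual pipeline stages ([average_sections()] and
#' [normalize_by_reference()]) to produce the normalized study dataset.
#'
#' @param config A [study_template()] / `synthetic_study_config`.
#' @param seed Integer seed; mandatory whenever any configured sd is
#'   positive. Identical seeds give identical datasets.
#' @param strict_positive Clip negative section values at 0 (default FALSE:
#'   clipping would distort the imposed correlation structure).
#' @return List with elements `measurements` (long section-level tibble
#'   including the reference channel) and `study` (the normalized
#'   [ieg_study()]).
#' @export
generate_study <- function(config, seed = config$seed,
                           strict_positive = FALSE) {
  if (!inherits(config, "synthetic_study_config")) {
    abort("`config` must come from `study_template()` or `synthetic_group_config()`s.",
          class = "iegnet_validation_error")
  }
  stochastic <- any(vapply(config$groups, function(g) {
    any(c(g$animal_sd, g$section_sd, g$reference_sd) > 0)
  }, logical(1)))
  if (stochastic && is.null(seed)) {
    abort("A seed is required: the configuration draws random values.",
          class = "iegnet_validation_error")
  }
  if (!is.null(seed)) set.seed(seed)

  registry <- config$registry
  rois <- registry_rois(registry)
  ref <- reference_roi(registry)

  measurements <- purrr::map(config$groups, function(g) {
    n <- g$n_animals
    k <- length(rois)
    L <- .sqrt_psd(g$correlation)
    Z <- matrix(rnorm(n * k), n, k)
    X <- Z %*% L
    vals <- sweep(sweep(X, 2, g$animal_sd, `*`), 2, g$roi_means, `+`)
    ref_vals <- rnorm(n, g$reference_mean, g$reference_sd)
    animals <- paste0(.slug(g$label), "_", seq_len(n))
    per_section <- purrr::map(seq_len(g$n_sections), function(s) {
      noise <- matrix(rnorm(n * (k + 1), 0, g$section_sd), n, k + 1)
      tibble(
        animal = rep(animals, k + 1),
        group = g$label,
        roi = rep(c(rois, ref), each = n),
        section = s,
        value = c(cbind(vals, ref_vals) + noise)
      )
    })
    bind_rows(per_section)
  }) |> bind_rows()

  if (strict_positive) {
    measurements$value <- pmax(measurements$value, 0)
  }

  averaged <- average_sections(measurements, expected_sections = NA)
  study <- normalize_by_reference(averaged, registry, mode = "ratio")
  attr(study, "provenance") <- c(attr(study, "provenance"),
                                 list(generator = config$preset %||% "custom",
                                      seed = seed))
  list(measurements = measurements, study = study)
}

#' Write / read a synthetic study configuration as YAML
#'
#' @param config A `synthetic_study_config`.
#' @param path File path.
#' @return `write_study_config()` returns `path` invisibly;
#'   `read_study_config()` returns the reconstructed configuration.
#' @export
write_study_config <- function(config, path) {
  ser <- list(
    seed = config$seed,
    preset = config$preset,
    reference_roi = reference_roi(config$registry),
    rois = as.list(setNames(config$registry$region, config$registry$roi)),
    groups = purrr::map(config$groups, function(g) {
      list(label = g$label, n_animals = g$n_animals,
           roi_means = as.list(g$roi_means),
           correlation = apply(g$correlation, 1, as.list, simplify = FALSE),
           animal_sd = g$animal_sd, section_sd = g$section_sd,
           n_sections = g$n_sections, reference_mean = g$reference_mean,
           reference_sd = g$reference_sd)
    })
  )
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  ser <- yaml::read_yaml(path)
  registry <- roi_registry(
    tibble(roi = names(ser$rois), region = unlist(ser$rois)),
    reference_roi = ser$reference_roi
  )
  rois <- registry_rois(registry)
  groups <- purrr::map(ser$groups, function(g) {
    R <- do.call(rbind, lapply(g$correlation, unlist))
    dimnames(R) <- list(rois, rois)
    R <- (R + t(R)) / 2
    synthetic_group_config(
      g$label, roi_means = setNames(unlist(g$roi_means), rois),
      correlation = R, animal_sd = g$animal_sd, n_animals = g$n_animals,
      section_sd = g$section_sd, n_sections = g$n_sections,
      reference_mean = g$reference_mean, reference_sd = g$reference_sd
    )
  })
  names(groups) <- vapply(groups, function(g) g$label, character(1))
  structure(list(registry = registry, groups = groups, seed = ser$seed,
                 preset = ser$preset),
            class = "synthetic_study_config")
}
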