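# End-to-end pipeline: read or generate -> normalize -> contrasts ->
# correlation matrices -> networks -> metrics -> comparisons, with a run
# manifest recording every setting in force.

.study_pairs <- function(groups) {
  canonical <- list(c("VEH/VEH", "KET/VEH"), c("VEH/VEH", "VEH/ASE"),
                    c("KET/VEH", "KET/ASE"))
  present <- Filter(function(p) all(p %in% groups), canonical)
  if (length(present)) return(present)
  if (length(groups) >= 2) return(list(groups[1:2]))
  list()
}

#' Run the full expression-connectome pipeline
#'
#' Executes every stage on either a long-format input file or a synthetic
#' preset and writes all artifacts (normalized wide tables, contrast
#' reports, correlation matrices, edge lists + GraphML networks, a metrics
#' JSON, comparison reports) plus a JSON run manifest into `out_dir`.
#'
#' @param config Named list (or path to a YAML file holding one) with
#'   elements:
#'   * `input` — path to a long-format CSV/TSV, **or** `preset` — a
#'     [study_template()] preset name;
#'   * `out_dir` — output directory;
#'   * `seed` — integer, mandatory when any stochastic stage runs;
#'   * optional: `normalization` (`"ratio"`), `variant` (`"pooled"`),
#'     `threshold_p` (0.05), `alpha` (0.05), `B` (1000), `n_animals` (5),
#'     `contrasts` / `comparisons` (lists of group-label pairs; default:
#'     the canonical treatment-arm pairs present in the data), `force`
#'     (overwrite non-empty `out_dir`), `plots` (write figure PDFs,
#'     default FALSE).
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(
    list(input = NULL, preset = NULL, out_dir = NULL, seed = NULL,
         normalization = "ratio", variant = "pooled", threshold_p = 0.05,
         alpha = 0.05, B = 1000, n_animals = 5, contrasts = NULL,
         comparisons = NULL, force = FALSE, plots = FALSE),
    config)
  if (is.null(cfg$out_dir)) {
    abort("`out_dir` is required.", class = "iegnet_validation_error")
  }
  if (dir.exists(cfg$out_dir) &&
      length(list.files(cfg$out_dir)) > 0 && !isTRUE(cfg$force)) {
    abort(paste0("Output directory is not empty (use force = TRUE): ",
                 cfg$out_dir), class = "iegnet_validation_error")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  registry <- roi_registry()
  outputs <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "iegnet_pipeline_error", parent = e)
    })
  }

  # -- acquire + normalize
  study <- if (!is.null(cfg$input)) {
    stage("read", {
      meas <- read_expression_long(cfg$input, registry)
      averaged <- average_sections(meas, expected_sections = NA)
      normalize_by_reference(averaged, registry, mode = cfg$normalization)
    })
  } else if (!is.null(cfg$preset)) {
    stage("generate", {
      tpl <- study_template(cfg$preset, registry = registry,
                            n_animals = cfg$n_animals)
      gen <- generate_study(tpl, seed = cfg$seed)
      long_path <- file.path(cfg$out_dir, "synthetic_long.csv")
      write_expression_long(gen$measurements, long_path)
      outputs <<- c(outputs, long_path)
      gen$study
    })
  } else {
    abort("Give either `input` or `preset`.",
          class = "iegnet_validation_error")
  }
  groups <- study_groups(study)
  outputs <- c(outputs, write_study_wide(study, cfg$out_dir))

  # -- contrasts
  contrast_pairs <- cfg$contrasts %||% .study_pairs(groups)
  for (pair in contrast_pairs) {
    ct <- stage(paste0("contrast ", pair[1], " vs ", pair[2]),
                contrast_groups(study, pair[1], pair[2],
                                variant = cfg$variant, alpha = cfg$alpha))
    path <- file.path(cfg$out_dir,
                      paste0("contrast_", .slug(pair[1]), "_vs_",
                             .slug(pair[2]), ".csv"))
    write_contrast_report(ct, path)
    outputs <- c(outputs, path)
  }

  # -- correlation matrices, networks, metrics
  metrics <- list()
  cms <- list()
  for (g in groups) {
    cm <- stage(paste0("correlation ", g), cor_matrix(study, g))
    cms[[g]] <- cm
    outputs <- c(outputs, write_cor_matrix(cm, cfg$out_dir))
    net <- stage(paste0("network ", g),
                 build_network(cm, threshold_p = cfg$threshold_p))
    outputs <- c(outputs, write_network(net, cfg$out_dir))
    metrics[[g]] <- c(as.list(network_metrics(net, cm)),
                      list(hierarchical_order =
                             if (!length(cm$constant_rois))
                               as.character(hierarchical_order(cm))
                             else NULL))
    if (isTRUE(cfg$plots)) {
      plot_path <- file.path(cfg$out_dir,
                             paste0("network_", .slug(g), ".pdf"))
      ggplot2::ggsave(plot_path, autoplot(net), width = 7, height = 7)
      outputs <- c(outputs, plot_path)
    }
  }
  metrics_path <- file.path(cfg$out_dir, "network_metrics.json")
  jsonlite::write_json(metrics, metrics_path, auto_unbox = TRUE,
                       digits = NA)
  outputs <- c(outputs, metrics_path)

  # -- comparisons
  comparison_pairs <- cfg$comparisons %||% .study_pairs(groups)
  comparison_summaries <- list()
  for (pair in comparison_pairs) {
    cp <- stage(paste0("comparison ", pair[1], " vs ", pair[2]),
                compare_groups(study, pair[1], pair[2],
                               threshold_p = cfg$threshold_p,
                               alpha = cfg$alpha, B = cfg$B,
                               seed = cfg$seed))
    outputs <- c(outputs, write_comparison_report(cp, cfg$out_dir))
    comparison_summaries[[paste(pair, collapse = " vs ")]] <-
      as.list(glance(cp))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("iegnet")),
    config = cfg[setdiff(names(cfg), c("contrasts", "comparisons"))],
    contrasts = lapply(contrast_pairs, paste, collapse = " vs "),
    comparisons = lapply(comparison_pairs, paste, collapse = " vs "),
    settings = list(
      density_convention = "E / (N * (N - 1)) (ordered pairs)",
      path_length = "unweighted, mean over connected pairs",
      clustering = "mean local coefficient, degree < 2 counts 0",
      betweenness = "unweighted, unnormalized",
      global_strength = "sum |r| over the full correlation matrix",
      hierarchical_linkage = "average linkage on 1 - r",
      permutation_p = "exhaustive proportion or add-one Monte-Carlo"
    ),
    comparison_summaries = comparison_summaries,
    outputs = unname(outputs)
  )
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
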