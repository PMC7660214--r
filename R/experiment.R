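# Experiment orchestration: config validation, the staged pipeline
# (cohort -> graphs -> spectra -> accuracy curves -> selection ->
# ensemble -> metrics), and output/provenance writing.

#' Default experiment configuration
#'
#' The cohort section defaults to the [simulation_params()] defaults
#' (an ABIDE-sized simulated cohort); analysis sections default to the
#' published training setup (k = 200, 10-fold stratified CV, Adam at
#' lr 0.01, 200 epochs, hidden sizes 512/64).  Accuracy curves for graph
#' categorization use lighter settings (3 folds, 50 epochs) since they
#' only rank graphs.
#'
#' @return Nested named list of defaults.
#' @export
default_experiment_config <- function() {
  list(
    cohort = list(
      dir = NULL,
      n_patients = 403L, n_controls = 468L, r = 111L,
      effect_size = 0.5, signal_fraction = 0.1, n_sites = 17L,
      site_effect = 0.1, sex_imbalance = 727 / 871,
      age_range = c(6, 58), noise_sd = 0.2, seed = 1L
    ),
    graphs = list(
      sigma = NULL, age_bin_edges = NULL, random_density = 0.1,
      include_baselines = FALSE
    ),
    spectral = list(
      k = 200L, low_k_fraction = 0.2, margin = 0.01, k_grid = NULL
    ),
    curves = list(n_folds = 3L, epochs = 50L, seed = 11L),
    blocks = list(
      hidden_sizes = c(512L, 64L), learning_rate = 0.01,
      epochs = 200L, dropout_rate = 0.3
    ),
    ensemble = list(
      mode = "weighted_sum", training = "end_to_end", top_m = 8L,
      epochs = 200L, learning_rate = 0.01, dropout_rate = 0.3,
      gate_init_sd = 0.01
    ),
    evaluation = list(n_folds = 10L, seed = 1L, threshold = 0.5),
    out_dir = NULL,
    verbose = TRUE
  )
}

#' Merge a user config into the defaults, rejecting unknown keys
#' @noRd
merge_config <- function(user, defaults = default_experiment_config(),
                         path = character(0)) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stopf("config section '%s' must be a list",
                            paste(path, collapse = "$"))
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stopf("unknown config key(s): %s",
          paste(paste(c(path, ""), collapse = "$"), unknown,
                sep = "", collapse = ", "))
  }
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(user[[key]], defaults[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load an experiment configuration
#'
#' @param config A YAML file path, a nested list, or `NULL` for the
#'   defaults.  Unknown keys are a validation error naming the key.
#' @return The merged, validated config list.
#' @export
load_experiment_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  merge_config(config)
}

#' @noRd
stage <- function(name, verbose, expr) {
  if (verbose) message(sprintf("[popgsp] stage: %s", name))
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full population-graph ensemble experiment
#'
#' Executes: simulate or load the cohort; vectorize RSFC; build every
#' graph configuration; eigendecompose; compute per-graph accuracy-vs-k
#' curves; select the top low-frequency graphs; train the gated ensemble
#' with stratified cross-validation; compute metrics.  When `out_dir` is
#' set, writes `predictions.csv`, `gates.csv`, `selection.csv`,
#' `curves.csv`, `metrics.json` and a provenance `manifest.json`.
#'
#' @param config Path to a YAML config, a nested list (see
#'   [default_experiment_config()]), or `NULL`.
#' @return List with `cohort`, `selection`, `curves`, `fit`
#'   (`ensemble_fit`), `metrics`, `by_fold`, `config`.
#' @export
run_experiment <- function(config = NULL) {
  cfg <- load_experiment_config(config)
  verbose <- isTRUE(cfg$verbose)

  cohort <- stage("cohort", verbose, {
    if (!is.null(cfg$cohort$dir)) {
      read_cohort(cfg$cohort$dir)
    } else {
      pc <- cfg$cohort
      pc$dir <- NULL
      generate_cohort(do.call(simulation_params, pc))
    }
  })
  n <- length(cohort$subject_ids)

  x <- stage("vectorize", verbose, vectorize_rsfc(cohort))

  configs <- stage("graph configs", verbose, {
    enumerate_graph_configs(
      include_baselines = isTRUE(cfg$graphs$include_baselines),
      sigma = cfg$graphs$sigma, age_bin_edges = cfg$graphs$age_bin_edges,
      random_density = cfg$graphs$random_density, seed = cfg$evaluation$seed
    )
  })

  bases <- stage("graphs and spectra", verbose, {
    lapply(configs, function(gc) {
      g <- build_population_graph(x, cohort, gc)
      eigendecompose(combinatorial_laplacian(g), g$config)
    })
  })

  k_grid <- cfg$spectral$k_grid %||%
    unique(sort(c(ceiling(0.2 * n), ceiling(0.5 * n), n)))
  curve_folds <- stratified_kfold(cohort$labels, cfg$curves$n_folds,
                                  cfg$curves$seed)
  curve_spec <- block_spec(hidden_sizes = cfg$blocks$hidden_sizes,
                           dropout_rate = cfg$blocks$dropout_rate,
                           learning_rate = cfg$blocks$learning_rate,
                           epochs = cfg$curves$epochs,
                           seed = cfg$curves$seed)
  curves <- stage("accuracy curves", verbose, {
    lapply(bases, function(b) {
      block_accuracy_curve(b, x, cohort$labels, k_grid, curve_folds,
                           curve_spec)
    })
  })

  selection <- stage("graph selection", verbose, {
    select_low_frequency_graphs(curves, n = n,
                                low_k_fraction = cfg$spectral$low_k_fraction,
                                margin = cfg$spectral$margin,
                                top_m = cfg$ensemble$top_m)
  })

  fit <- stage("ensemble", verbose, {
    k <- min(cfg$spectral$k, n)
    x_list <- lapply(selection$selected, function(nm) {
      filter_features(bases[[nm]], x, k)
    })
    names(x_list) <- selection$selected
    folds <- stratified_kfold(cohort$labels, cfg$evaluation$n_folds,
                              cfg$evaluation$seed)
    espec <- ensemble_spec(mode = cfg$ensemble$mode,
                           training = cfg$ensemble$training,
                           hidden_sizes = cfg$blocks$hidden_sizes,
                           dropout_rate = cfg$ensemble$dropout_rate,
                           learning_rate = cfg$ensemble$learning_rate,
                           epochs = cfg$ensemble$epochs,
                           gate_init_sd = cfg$ensemble$gate_init_sd,
                           seed = cfg$evaluation$seed)
    train_ensemble(x_list, cohort$labels, folds, espec,
                   subject_ids = cohort$subject_ids)
  })

  metrics <- compute_metrics(fit$predictions$probability,
                             fit$predictions$true_label,
                             cfg$evaluation$threshold)
  by_fold <- metrics_by_fold(fit$predictions, cfg$evaluation$threshold)

  if (!is.null(cfg$out_dir)) {
    stage("write outputs", verbose, {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_ensemble_outputs(fit,
                             file.path(cfg$out_dir, "predictions.csv"),
                             file.path(cfg$out_dir, "gates.csv"))
      utils::write.csv(selection$table,
                       file.path(cfg$out_dir, "selection.csv"),
                       row.names = FALSE)
      curve_df <- do.call(rbind, Map(function(nm, cu) {
        cbind(config = nm, cu)
      }, names(curves), curves))
      utils::write.csv(curve_df, file.path(cfg$out_dir, "curves.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(metrics = metrics[c("accuracy", "auc", "sensitivity",
                                 "specificity", "f_score")],
             by_fold = by_fold),
        file.path(cfg$out_dir, "metrics.json"),
        auto_unbox = TRUE, digits = NA, na = "null"
      )
      jsonlite::write_json(
        list(package = "popgsp",
             version = as.character(utils::packageVersion("popgsp")),
             r_version = R.version.string,
             config = cfg,
             selected_graphs = selection$selected),
        file.path(cfg$out_dir, "manifest.json"),
        auto_unbox = TRUE, null = "null", digits = NA
      )
    })
  }

  list(cohort = cohort, selection = selection, curves = curves, fit = fit,
       metrics = metrics, by_fold = by_fold, config = cfg)
}
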