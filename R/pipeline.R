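#' Pipeline configuration
#'
#' A plain, serializable description of a full run: synthetic data
#' conditions, network and training settings, feature selection, ELM
#' settings, and the ablation switches mirroring the method's structural
#' variants (`disable_mmd` = no divergence loss; `disable_ensemble` =
#' single sub-predictor; `use_elm = FALSE` = end-to-end network
#' classification; `solver = "pinv"` = unregularized ELM;
#' `source_subset` = train on a subset of the sources).
#'
#' A configuration round-trips unchanged through YAML serialization, and
#' every pipeline run writes its resolved configuration next to its
#' outputs.
#'
#' @param preset synthetic shift regime, see [gen_preset_image_domains()].
#' @param n_source_per_class,n_target_per_class,n_test_per_class per-domain
#'   class sizes for sources, target training set and held-out target test
#'   set.
#' @param image_size image side length (pixels).
#' @param noise_sd background noise level.
#' @param channels,specific_channels tiny-CNN channel widths.
#' @param batch_size,iterations,theta,alpha_mode,lr_decay training settings
#'   (see [training_config()]).
#' @param disable_mmd,disable_ensemble,use_elm ablation switches.
#' @param source_subset integer indices of the sources to use.
#' @param mrmr_fraction,mrmr_bins feature-selection settings.
#' @param hidden,beta,activation,solver ELM settings.
#' @param seed master seed; stage seeds are derived by fixed offsets.
#' @return object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(preset = "mixed",
                            n_source_per_class = 64L,
                            n_target_per_class = 8L,
                            n_test_per_class = 150L,
                            image_size = 32L, noise_sd = 0.3,
                            channels = c(8L, 16L),
                            specific_channels = c(8L, 8L, 4L),
                            batch_size = 16L, iterations = 250L,
                            theta = 10, alpha_mode = "exp_clamped",
                            lr_decay = "inv",
                            disable_mmd = FALSE, disable_ensemble = FALSE,
                            use_elm = TRUE, source_subset = 1:3,
                            mrmr_fraction = 0.25, mrmr_bins = 10L,
                            hidden = 200L, beta = 0.05,
                            activation = "sigmoid", solver = "ridge",
                            seed = 1L) {
  cfg <- list(preset = preset,
              n_source_per_class = as.integer(n_source_per_class),
              n_target_per_class = as.integer(n_target_per_class),
              n_test_per_class = as.integer(n_test_per_class),
              image_size = as.integer(image_size), noise_sd = noise_sd,
              channels = as.integer(channels),
              specific_channels = as.integer(specific_channels),
              batch_size = as.integer(batch_size),
              iterations = as.integer(iterations),
              theta = theta, alpha_mode = alpha_mode, lr_decay = lr_decay,
              disable_mmd = isTRUE(disable_mmd),
              disable_ensemble = isTRUE(disable_ensemble),
              use_elm = isTRUE(use_elm),
              source_subset = as.integer(source_subset),
              mrmr_fraction = mrmr_fraction, mrmr_bins = as.integer(mrmr_bins),
              hidden = as.integer(hidden), beta = beta,
              activation = activation, solver = solver,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full pipeline
#'
#' Executes simulate -> train/extract -> select -> fit-ELM -> evaluate under
#' one configuration, writing all artifacts (resolved config, training
#' history, feature tables, selection table, test scores, evaluation
#' report) to `out_dir` when given. Stage seeds are derived from the master
#' seed by fixed offsets so stages are individually reproducible.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if missing).
#' @return (invisibly) a list with the fitted `mselm` model, the held-out
#'   `report` (an `evaluation_report`), the test scores, and the paths of
#'   any written artifacts.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  # stage 1: simulate (target first, then the full source panel)
  doms <- gen_preset_image_domains(
    preset = config$preset, n_per_class = config$n_source_per_class,
    image_size = config$image_size, n_sources = 3L,
    n_target_per_class = config$n_target_per_class,
    noise_sd = config$noise_sd, seed = seed + 1000L)
  test <- gen_preset_image_domains(
    preset = config$preset, n_per_class = config$n_test_per_class,
    image_size = config$image_size, n_sources = 1L,
    n_target_per_class = config$n_test_per_class,
    noise_sd = config$noise_sd, seed = seed + 2000L)[[1]]
  target <- doms[[1]]
  sources <- doms[-1][config$source_subset]

  # stage 2-4: fit (network training, feature export, mRMR, ELM)
  tcfg <- training_config(
    batch_size = config$batch_size, iterations = config$iterations,
    theta = config$theta, alpha_mode = config$alpha_mode,
    alpha_override = if (config$disable_mmd) 0 else NULL,
    ensemble = !config$disable_ensemble, lr_decay = config$lr_decay)
  fit <- mselm(sources, target,
               backbone = backbone_spec(
                 input_shape = c(1L, config$image_size, config$image_size),
                 channels = config$channels),
               specific = specific_spec(config$specific_channels),
               config = tcfg, mrmr_fraction = config$mrmr_fraction,
               mrmr_bins = config$mrmr_bins, hidden = config$hidden,
               beta = config$beta, activation = config$activation,
               solver = config$solver, use_elm = config$use_elm,
               seed = seed)

  # stage 5: evaluate on the held-out target cohort
  report <- evaluate_mselm(fit, test)
  scores <- data.frame(id = seq_along(test$labels),
                       true_label = test$labels,
                       score = predict(fit, test, type = "score"),
                       predicted = predict(fit, test, type = "class"))

  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths$config <- file.path(out_dir, "config.yaml")
    write_pipeline_config(config, paths$config)
    paths$history <- file.path(out_dir, "history.tsv")
    utils::write.table(fit$network$history, paths$history, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (config$use_elm) {
      paths$features <- file.path(out_dir, "features_target_train.tsv")
      write_feature_set(fit$features_train, paths$features)
      paths$selection <- file.path(out_dir, "selection.tsv")
      utils::write.table(
        data.frame(index = fit$selection$selected_indices,
                   score = fit$selection$scores),
        paths$selection, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    paths$scores <- file.path(out_dir, "scores.tsv")
    utils::write.table(scores, paths$scores, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$report <- file.path(out_dir, "report.json")
    jsonlite::write_json(
      list(tp = report$tp, tn = report$tn, fp = report$fp, fn = report$fn,
           sen = report$sen, spe = report$spe, acc = report$acc,
           pre = report$pre, f1 = report$f1, auc = report$auc),
      paths$report, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(model = fit, report = report, scores = scores,
                 paths = paths))
}
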