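#' Pipeline configuration
#'
#' Bundles every stage's settings for an end-to-end run: synthetic cohort
#' generation, feature extraction, UBM training, MAP adaptation, and
#' cross-validated SVM evaluation. Round-trips losslessly through JSON via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param out_dir output directory for result artifacts.
#' @param n_per_class synthetic speakers per class.
#' @param classes cohort classes to simulate (subset of `hc`, `pd`, `et`).
#' @param m_grid numbers of Gaussian components to sweep.
#' @param ubm_classes classes whose frames train the UBM (default `"hc"`:
#'   background models from healthy speech only).
#' @param relevance_factor MAP relevance factor (default 16).
#' @param folds,repetitions outer cross-validation protocol.
#' @param inner_folds nested hyperparameter-search folds.
#' @param c_grid,gamma_grid SVM grids (defaults as in [experiment_spec()]).
#' @param var_kept cumulative variance for the fusion+PCA variant.
#' @param positive_class positive class for two-class sensitivity.
#' @param write_wavs write cohort WAV files under `out_dir/wav/`.
#' @param seed master seed; all stage seeds derive from it.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("gmmvoice_"),
                            n_per_class = 50L,
                            classes = c("hc", "pd", "et"),
                            m_grid = c(2L, 4L, 8L, 16L, 32L, 64L, 128L),
                            ubm_classes = "hc",
                            relevance_factor = 16,
                            folds = 10L, repetitions = 10L,
                            inner_folds = 5L,
                            c_grid = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5,
                                       1, 5, 10, 50, 100, 500, 1000),
                            gamma_grid = 10^(-4:3),
                            var_kept = 0.90,
                            positive_class = "pd",
                            write_wavs = FALSE,
                            seed = 1L) {
  structure(list(out_dir = out_dir, n_per_class = as.integer(n_per_class),
                 classes = classes, m_grid = as.integer(m_grid),
                 ubm_classes = ubm_classes,
                 relevance_factor = relevance_factor,
                 folds = as.integer(folds),
                 repetitions = as.integer(repetitions),
                 inner_folds = as.integer(inner_folds),
                 c_grid = c_grid, gamma_grid = gamma_grid,
                 var_kept = var_kept, positive_class = positive_class,
                 write_wavs = isTRUE(write_wavs), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, obj)
}

#' Simulate the synthetic cohort of a pipeline run
#'
#' @param config a [pipeline_config()].
#' @return list with `waveforms` and `manifest` (see [synth_cohort()]).
#' @export
run_simulate <- function(config) {
  profiles <- lapply(config$classes, synth_profile)
  names(profiles) <- config$classes
  cohort <- synth_cohort(config$n_per_class, profiles,
                         seed = .derive_seed(config$seed, 1L))
  if (config$write_wavs) {
    dir.create(file.path(config$out_dir, "wav"), recursive = TRUE,
               showWarnings = FALSE)
    for (w in cohort$waveforms)
      write_wav(w, file.path(config$out_dir, "wav",
                             paste0(w$source_id, ".wav")))
  }
  cohort
}

#' Extract per-speaker feature matrices for a cohort
#'
#' @param cohort output of [run_simulate()] (or any list of `waveform`s in
#'   `$waveforms`).
#' @return named list (one entry per speaker) of lists of three
#'   `feature_matrix` objects.
#' @export
run_extract <- function(cohort) {
  lapply(cohort$waveforms,
         function(w) extract_features(preprocess_waveform(w)))
}

#' Train per-dimension universal background models
#'
#' Pools the frames of the configured UBM cohort (by default healthy
#' controls only) and fits one diagonal-covariance GMM per speech dimension
#' and component count.
#'
#' @param features output of [run_extract()].
#' @param manifest cohort manifest with `subject_id` and `class` columns.
#' @param m_grid component counts to fit.
#' @param ubm_classes classes included in UBM training.
#' @param seed integer seed.
#' @return nested list `ubms[[dimension]][[as.character(M)]]` of `gmm`s.
#' @export
run_train_ubm <- function(features, manifest, m_grid = 4L,
                          ubm_classes = "hc", seed = 1L) {
  keep <- manifest$subject_id[manifest$class %in% ubm_classes]
  if (!length(keep)) stop("no UBM training subjects in classes: ",
                          paste(ubm_classes, collapse = ", "))
  dims <- c("articulation", "phonation", "prosody")
  ubms <- list()
  for (d in dims) {
    pooled <- do.call(rbind, lapply(features[keep],
                                    function(f) f[[d]]$values))
    ubms[[d]] <- list()
    for (m in m_grid) {
      model <- gmm_fit(pooled, m, seed = .derive_seed(seed, m))
      model$meta$dimension <- d
      model$meta$n_training_frames <- nrow(pooled)
      ubms[[d]][[as.character(m)]] <- model
    }
  }
  ubms
}

#' MAP-adapt every recording and assemble supervector matrices
#'
#' @param features output of [run_extract()].
#' @param ubms output of [run_train_ubm()] for a single `M` (each dimension
#'   entry may be a `gmm` or a one-element list).
#' @param cfg an [adaptation_config()].
#' @return list of numeric matrices `articulation`, `phonation`, `prosody`,
#'   `fusion` (rows = recordings, in `features` order); recordings lacking
#'   frames in any dimension are dropped, with their ids in attribute
#'   `"excluded"`.
#' @export
run_adapt <- function(features, ubms, cfg = adaptation_config()) {
  dims <- c("articulation", "phonation", "prosody")
  get_ubm <- function(d) {
    u <- ubms[[d]]
    if (inherits(u, "gmm")) u else u[[1L]]
  }
  sv <- list(); excluded <- character(0)
  for (id in names(features)) {
    rec <- features[[id]]
    if (any(vapply(dims, function(d) nrow(rec[[d]]$values) == 0L,
                   logical(1)))) {
      excluded <- c(excluded, id)
      next
    }
    sv[[id]] <- lapply(dims, function(d)
      adapt_recording(rec[[d]], get_ubm(d), cfg))
    names(sv[[id]]) <- dims
  }
  if (length(excluded))
    message("excluded ", length(excluded),
            " recording(s) with empty feature matrices: ",
            paste(excluded, collapse = ", "))
  out <- lapply(dims, function(d)
    do.call(rbind, lapply(sv, function(s) as.numeric(s[[d]]))))
  names(out) <- dims
  out$fusion <- do.call(rbind, lapply(sv, fuse_supervectors))
  for (d in names(out)) rownames(out[[d]]) <- names(sv)
  attr(out, "excluded") <- excluded
  out
}

#' Evaluate every feature configuration for one component count
#'
#' Runs [run_experiment()] on each single speech dimension, the early
#' fusion, and fusion+PCA.
#'
#' @param supervectors output of [run_adapt()].
#' @param labels class labels aligned with the supervector rows.
#' @param spec an [experiment_spec()]; its `var_kept` is ignored (PCA is
#'   applied only in the `fusion_pca` configuration).
#' @param var_kept cumulative variance for the PCA configuration.
#' @return named list of `cv_result`s
#'   (`articulation`, `phonation`, `prosody`, `fusion`, `fusion_pca`).
#' @export
run_classify <- function(supervectors, labels, spec = experiment_spec(),
                         var_kept = 0.90) {
  if (!is.null(names(labels)))
    labels <- labels[rownames(supervectors$fusion)]
  configs <- c("articulation", "phonation", "prosody", "fusion")
  out <- lapply(configs, function(d) {
    s <- spec; s$var_kept <- NULL
    run_experiment(supervectors[[d]], labels, s)
  })
  names(out) <- configs
  s <- spec; s$var_kept <- var_kept
  out$fusion_pca <- run_experiment(supervectors$fusion, labels, s)
  out
}

#' Flatten cross-validation results into a results table
#'
#' @param results named list of `cv_result`s (e.g. from [run_classify()]),
#'   optionally nested per `M` as `results[[as.character(M)]][[config]]`.
#' @return data frame with one row per (M, configuration).
#' @export
results_table <- function(results) {
  if (inherits(results[[1L]], "cv_result")) results <- list(`NA` = results)
  rows <- list()
  for (m in names(results)) {
    for (cfg in names(results[[m]])) {
      r <- results[[m]][[cfg]]
      rows[[length(rows) + 1L]] <- data.frame(
        M = m, configuration = cfg,
        accuracy_mean = round(r$accuracy_mean, 4),
        accuracy_sd = round(r$accuracy_sd, 4),
        sensitivity = round(r$sensitivity, 4),
        specificity = round(r$specificity, 4),
        cost = r$selected_cost, gamma = r$selected_gamma,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full pipeline end to end
#'
#' Simulate -> extract -> train UBMs -> adapt -> classify, sweeping the
#' configured `m_grid`. Writes `results.csv`, per-(M, configuration)
#' confusion matrices as JSON, and a provenance JSON under
#' `config$out_dir`. Fully reproducible from `config$seed`: identical
#' configurations yield byte-identical result CSVs.
#'
#' @param config a [pipeline_config()].
#' @return list with `results` (nested `cv_result`s), `table` (data frame),
#'   `ubms`, `supervectors`, `manifest`, invisibly.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- run_simulate(config)
  utils::write.csv(cohort$manifest,
                   file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  features <- run_extract(cohort)
  ubms <- run_train_ubm(features, cohort$manifest, config$m_grid,
                        config$ubm_classes,
                        seed = .derive_seed(config$seed, 2L))
  labels <- stats::setNames(factor(cohort$manifest$class),
                            cohort$manifest$subject_id)
  spec <- experiment_spec(folds = config$folds,
                          repetitions = config$repetitions,
                          c_grid = config$c_grid,
                          gamma_grid = config$gamma_grid,
                          inner_folds = config$inner_folds,
                          positive_class =
                            if (config$positive_class %in% levels(labels))
                              config$positive_class else NULL,
                          seed = .derive_seed(config$seed, 3L))
  cfg <- adaptation_config(relevance_factor = config$relevance_factor)
  results <- list()
  for (m in config$m_grid) {
    ubms_m <- lapply(ubms, function(u) u[[as.character(m)]])
    sv <- run_adapt(features, ubms_m, cfg)
    results[[as.character(m)]] <-
      run_classify(sv, labels, spec, var_kept = config$var_kept)
  }
  tab <- results_table(results)
  utils::write.csv(tab, file.path(config$out_dir, "results.csv"),
                   row.names = FALSE)
  for (m in names(results))
    for (cfgn in names(results[[m]]))
      jsonlite::write_json(
        list(M = m, configuration = cfgn,
             confusion = results[[m]][[cfgn]]$confusion),
        file.path(config$out_dir,
                  sprintf("confusion_M%s_%s.json", m, cfgn)),
        digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(
    list(config = unclass(config),
         package_version = as.character(utils::packageVersion("gmmvoice")),
         n_recordings = length(features)),
    file.path(config$out_dir, "provenance.json"),
    digits = NA, auto_unbox = TRUE)
  # final supervectors from the last M of the sweep, for downstream plots
  invisible(list(results = results, table = tab, ubms = ubms,
                 manifest = cohort$manifest))
}
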