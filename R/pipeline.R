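#' Pipeline configuration
#'
#' Assembles the configuration of a full traceability run: synthetic table
#' generation, ANOVA screening, profile clustering, swarm tuning, final
#' training and evaluation, and permutation-importance interpretation.
#' Every default that the method itself does not pin down (SVM cost C,
#' swarm budget, linkage, permutation repeats) is recorded here and echoed
#' into the run report, so such gaps stay visible.
#'
#' @param models Character vector of model presets to run (see
#'   [model_search_space()]); at least one.
#' @param generator List of [generate_chem_table()] arguments
#'   (`separation_scale`, `n_noise_features`, `truncate_at_zero`) plus
#'   `count_scale`, a multiplier applied to the per-region sample counts
#'   (1 reproduces the full 1717-sample design; smaller values give
#'   proportionally smaller studies for quick runs).
#' @param pso List with `swarm_size` and `max_iters`.
#' @param split List with `test_fraction`.
#' @param pfi List with `repeats`.
#' @param C SVM soft-margin cost.
#' @param group_by Label column to classify, `"region"` or `"country"`.
#' @param linkage Clustering linkage.
#' @param seed Master integer seed; stage seeds are derived from it by
#'   fixed offsets and recorded in the report manifest.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(models = c("svm-hybrid"),
                            generator = list(),
                            pso = list(),
                            split = list(),
                            pfi = list(),
                            C = 1,
                            group_by = "region",
                            linkage = "average",
                            seed = 1) {
  if (length(models) < 1) stop("need at least one model preset", call. = FALSE)
  valid <- c("svm-linear", "svm-poly", "svm-gaussian", "svm-sigmoid",
             "svm-hybrid", "bpnn", "rf")
  bad <- setdiff(models, valid)
  if (length(bad)) {
    stop("unknown model preset(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  gen <- utils::modifyList(list(separation_scale = 1, n_noise_features = 0,
                                truncate_at_zero = TRUE, count_scale = 1),
                           generator)
  pso <- utils::modifyList(list(swarm_size = 30, max_iters = 50), pso)
  split <- utils::modifyList(list(test_fraction = 0.2), split)
  pfi <- utils::modifyList(list(repeats = 10), pfi)
  structure(list(models = models, generator = gen, pso = pso, split = split,
                 pfi = pfi, C = C, group_by = group_by, linkage = linkage,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A [pipeline_config()].
#' @return `read_pipeline_config()` returns a validated config;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full origin-traceability pipeline
#'
#' Executes, in order: synthetic table generation, per-component ANOVA
#' screening, hierarchical clustering of mean regional profiles, a
#' stratified train/test split, swarm tuning of every configured model
#' preset on the training split (five-fold cross-validated accuracy as
#' fitness), final training at the tuned parameters, test-set evaluation
#' with macro metrics, and permutation-importance interpretation of the
#' best test model. All artifacts (tables, newick dendrogram, rankings,
#' JSON report) are persisted under `output_dir`. Two runs with the same
#' configuration produce identical reports.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Directory for artifacts (created if needed).
#' @return The run report: a list with `config`, `seeds`, `anova`,
#'   `clustering`, `models` (per-preset tuned parameters, CV fitness,
#'   train/test accuracy and macro metrics), `best_model`, `importance`,
#'   and the artifact `paths`.
#' @export
run_pipeline <- function(config, output_dir = tempfile("tobtrace_run_")) {
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  seeds <- list(generate = config$seed, split = config$seed + 1L,
                tune = config$seed + 2L, pfi = config$seed + 3L)

  stage <- "generate"
  report <- tryCatch({
    counts <- load_region_counts()
    if (config$generator$count_scale != 1) {
      counts$n <- pmax(10L, as.integer(ceiling(counts$n *
                                               config$generator$count_scale)))
    }
    tbl <- generate_chem_table(
      region_counts = counts,
      separation_scale = config$generator$separation_scale,
      n_noise_features = config$generator$n_noise_features,
      truncate_at_zero = config$generator$truncate_at_zero,
      seed = seeds$generate)
    paths$table <- file.path(output_dir, "chem_table.csv")
    write_chem_table(tbl, paths$table)

    stage <- "screen"
    paths$anova <- file.path(output_dir, "anova_screen.csv")
    screen <- anova_screen(tbl, group_by = config$group_by,
                           path = paths$anova)
    anova_summary <- list(
      n_components = nrow(screen),
      n_extremely_significant = sum(screen$category == "***"),
      n_not_significant = sum(screen$category == "ns"))

    stage <- "cluster"
    prof <- mean_profiles(tbl, group_by = config$group_by)
    dend <- agglomerate(pearson_distance(prof), linkage = config$linkage)
    paths$dendrogram <- file.path(output_dir, "dendrogram.nwk")
    to_newick(dend, paths$dendrogram)
    paths$merges <- file.path(output_dir, "dendrogram_merges.json")
    merge_list(dend, paths$merges)

    stage <- "split"
    sp <- stratified_split(tbl[[config$group_by]],
                           config$split$test_fraction, seed = seeds$split)
    train_tbl <- tbl[sp$train, , drop = FALSE]
    test_tbl <- tbl[sp$test, , drop = FALSE]

    stage <- "tune/evaluate"
    model_rows <- list()
    fitted <- list()
    for (preset in config$models) {
      tuned <- pso_tune(train_tbl, preset,
                        pso_config(swarm_size = config$pso$swarm_size,
                                   max_iters = config$pso$max_iters,
                                   seed = seeds$tune),
                        k = 5, C = config$C, group_by = config$group_by)
      model <- build_origin_classifier(preset, tuned$best_position,
                                       train_tbl, C = config$C,
                                       group_by = config$group_by,
                                       seed = seeds$tune)
      trace_path <- file.path(output_dir, paste0("pso_trace_", preset, ".csv"))
      utils::write.csv(tuned$trace, trace_path, row.names = FALSE)
      train_acc <- mean(as.character(predict(model, train_tbl)) ==
                          as.character(train_tbl[[config$group_by]]))
      pred <- predict(model, test_tbl)
      cm <- confusion(test_tbl[[config$group_by]], pred, model$levels)
      met <- classification_metrics(cm)
      fitted[[preset]] <- list(model = model, cm = cm)
      model_rows[[preset]] <- list(
        preset = preset,
        optimal_parameters = as.list(tuned$best_position),
        cv_fitness = tuned$best_fitness,
        train_accuracy = train_acc,
        test_accuracy = met$accuracy,
        macro_recall = met$macro_recall,
        macro_precision = met$macro_precision,
        macro_f1 = met$macro_f1)
    }

    stage <- "interpret"
    test_accs <- vapply(model_rows, function(r) r$test_accuracy, 0)
    best <- names(model_rows)[which.max(test_accs)]
    paths$confusion <- file.path(output_dir, "confusion_best.csv")
    write_metrics(fitted[[best]]$cm, paths$confusion)
    imp <- permutation_importance(fitted[[best]]$model, test_tbl,
                                  repeats = config$pfi$repeats,
                                  seed = seeds$pfi)
    paths$importance <- file.path(output_dir, "importance.csv")
    write_importance(imp, paths$importance)

    list(config = unclass(config), seeds = seeds,
         n_samples = nrow(tbl),
         n_components = length(chem_components(tbl)),
         anova = anova_summary,
         clustering = list(linkage = config$linkage,
                           newick = readLines(paths$dendrogram)),
         models = model_rows,
         best_model = best,
         importance = list(
           baseline_loss = attr(imp, "baseline_loss"),
           top20 = as.data.frame(top_k(imp, min(20, nrow(imp))))),
         paths = lapply(paths, normalizePath))
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  report_path <- file.path(output_dir, "report.json")
  rep_out <- report
  rep_out$paths <- NULL              # keep the report machine-independent
  jsonlite::write_json(rep_out, report_path, auto_unbox = TRUE, digits = NA)
  report$paths$report <- normalizePath(report_path)
  report
}
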