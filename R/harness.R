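# Experiment harness: repeated seeded runs, strategy comparison, budget
# sweeps, and single-run artifacts.

test_accuracy <- function(result, test) {
  pred <- classify(result$best$tree, test,
                   result$config$classification_threshold)
  cm <- confusion(test$labels, pred)
  compute_metrics(cm)
}

#' Repeated seeded runs on fresh hold-out splits
#'
#' For each seed: split the dataset (stratified hold-out), standardize by
#' training statistics, run the GP driver, and measure test-set accuracy of
#' the best classifier. `use_fs = FALSE` runs the plain-GP baseline under
#' identical conditions.
#'
#' @param dataset a [feature_table()].
#' @param config an [fsgp_config()]; its `seed` is replaced per run.
#' @param seeds integer seeds, one per run.
#' @param n_runs must equal `length(seeds)` (defaults to it).
#' @param use_fs run with embedded feature selection?
#' @param train_fraction hold-out training fraction (default 0.8).
#' @param standardize_features z-score by training statistics first?
#' @return Object of class `fsgp_trials`: `runs` (data frame with per-run
#'   train/test accuracy, selected-feature count, evaluations), `selected`
#'   (list of per-run selected feature sets), and `summary`
#'   (max/mean/min test accuracy, mean feature count).
#' @examples
#' ft <- generate_synthetic(synthetic_spec(n_samples = 40, seed = 5))
#' tr <- run_trials(ft, fsgp_config(evaluation_budget = 1500), seeds = 1:2)
#' tr$summary
#' @export
run_trials <- function(dataset, config, seeds, n_runs = length(seeds),
                       use_fs = TRUE, train_fraction = 0.8,
                       standardize_features = TRUE) {
  if (n_runs != length(seeds))
    fsgp_error("n_runs must equal length(seeds)", "fsgp_argument_error")
  rows <- vector("list", n_runs)
  selected <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    s <- seeds[i]
    sp <- holdout_split(dataset, train_fraction, stratified = TRUE, seed = s)
    train <- sp$train; test <- sp$test
    if (standardize_features) {
      test <- standardize(test, train)
      train <- standardize(train, train)
    }
    cfg <- config
    cfg$seed <- as.integer(s)
    res <- run_fsgp(train, cfg, feature_selection = use_fs)
    met <- test_accuracy(res, test)
    rows[[i]] <- data.frame(seed = s,
                            train_accuracy = res$best$fitness,
                            test_accuracy = met$accuracy,
                            n_selected = length(res$selected_features),
                            evaluations = res$total_evaluations,
                            terminated_early = res$terminated_early)
    selected[[i]] <- res$selected_features
  }
  runs <- do.call(rbind, rows)
  structure(list(runs = runs,
                 selected = selected,
                 use_fs = use_fs,
                 summary = list(max = max(runs$test_accuracy),
                                mean = mean(runs$test_accuracy),
                                min = min(runs$test_accuracy),
                                mean_train = mean(runs$train_accuracy),
                                mean_features = mean(runs$n_selected))),
            class = "fsgp_trials")
}

#' @export
print.fsgp_trials <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%s trials: %d runs\n",
              if (x$use_fs) "FSGP" else "plain GP", nrow(x$runs)))
  cat(sprintf("  test accuracy max/mean/min: %.1f%% / %.1f%% / %.1f%%; mean features %.1f\n",
              100 * s$max, 100 * s$mean, 100 * s$min, s$mean_features))
  invisible(x)
}

#' Compare FSGP against the plain-GP baseline
#'
#' Paired seeded runs of both strategies at equal budget on the same
#' dataset, summarised by max/mean/min test accuracy and mean
#' selected-feature count, with a two-tailed Mann-Whitney test between the
#' two per-run test-accuracy samples.
#'
#' @inheritParams run_trials
#' @return Object of class `fsgp_comparison` with `fsgp`, `plain_gp`
#'   (both [run_trials()] results) and `mann_whitney`.
#' @export
run_comparison <- function(dataset, config, seeds, train_fraction = 0.8,
                           standardize_features = TRUE) {
  fs <- run_trials(dataset, config, seeds, use_fs = TRUE,
                   train_fraction = train_fraction,
                   standardize_features = standardize_features)
  plain <- run_trials(dataset, config, seeds, use_fs = FALSE,
                      train_fraction = train_fraction,
                      standardize_features = standardize_features)
  structure(list(fsgp = fs, plain_gp = plain,
                 mann_whitney = mann_whitney(fs$runs$test_accuracy,
                                             plain$runs$test_accuracy)),
            class = "fsgp_comparison")
}

#' @export
print.fsgp_comparison <- function(x, ...) {
  print(x$fsgp); print(x$plain_gp); print(x$mann_whitney)
  invisible(x)
}

#' Accuracy and feature count across evaluation budgets
#'
#' Runs [run_trials()] at each budget and tabulates mean/max/min test
#' accuracy and mean selected-feature count per budget.
#'
#' @inheritParams run_trials
#' @param budgets integer vector of evaluation budgets.
#' @return Object of class `fsgp_sweep` with a `table` data frame and the
#'   per-budget trials.
#' @export
run_sweep <- function(dataset, config, budgets, seeds, use_fs = TRUE,
                      train_fraction = 0.8, standardize_features = TRUE) {
  trials <- lapply(budgets, function(b) {
    cfg <- config
    cfg$evaluation_budget <- as.integer(b)
    validate_config(cfg)
    run_trials(dataset, cfg, seeds, use_fs = use_fs,
               train_fraction = train_fraction,
               standardize_features = standardize_features)
  })
  tab <- do.call(rbind, lapply(seq_along(budgets), function(i) {
    s <- trials[[i]]$summary
    data.frame(budget = budgets[i],
               mean_test_accuracy = s$mean,
               max_test_accuracy = s$max,
               min_test_accuracy = s$min,
               mean_features = s$mean_features)
  }))
  structure(list(table = tab, trials = trials), class = "fsgp_sweep")
}

#' @export
print.fsgp_sweep <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

run_manifest <- function(config, seed, input, extra = list()) {
  c(list(package = "fsgp",
         version = as.character(utils::packageVersion("fsgp")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = seed,
         input = input,
         config = unclass(config)),
    extra)
}

#' Run one experiment and write its artifacts
#'
#' End-to-end single run: split, standardize, evolve, evaluate on the test
#' set. When `out_dir` is given, writes `report.json`, `best_tree.txt`
#' (canonical s-expression), `history.csv` (per-generation log) and
#' `manifest.json` (enough to reproduce the run bit-for-bit).
#'
#' @param data a [feature_table()], a [synthetic_spec()], or a CSV path.
#' @param config an [fsgp_config()].
#' @param seed split/run seed (overrides `config$seed`).
#' @param out_dir output directory, or `NULL` for no artifacts.
#' @param baseline run the plain-GP baseline instead of FSGP?
#' @inheritParams run_trials
#' @param label_column label column when `data` is a path.
#' @return The report (list) invisibly.
#' @export
run_experiment <- function(data, config = fsgp_config(), seed = config$seed,
                           out_dir = NULL, train_fraction = 0.8,
                           standardize_features = TRUE, baseline = FALSE,
                           label_column = "label") {
  input_desc <- "feature_table"
  if (is.character(data)) {
    input_desc <- data
    data <- read_feature_table(data, label_column)
  } else if (inherits(data, "synthetic_spec")) {
    input_desc <- sprintf("synthetic(seed=%d)", data$seed)
    data <- generate_synthetic(data)
  }
  stopifnot(inherits(data, "feature_table"))
  sp <- holdout_split(data, train_fraction, stratified = TRUE, seed = seed)
  train <- sp$train; test <- sp$test
  if (standardize_features) {
    test <- standardize(test, train)
    train <- standardize(train, train)
  }
  cfg <- config
  cfg$seed <- as.integer(seed)
  res <- run_fsgp(train, cfg, feature_selection = !baseline)
  met <- test_accuracy(res, test)
  report <- list(
    strategy = if (baseline) "plain-gp" else "fsgp",
    best_tree = res$best$key,
    selected_features = res$selected_features,
    n_selected = length(res$selected_features),
    train_accuracy = res$best$fitness,
    test_metrics = unclass(met),
    total_evaluations = res$total_evaluations,
    generations = max(res$history$generation),
    replacement_generation = res$replacement_generation,
    terminated_early = res$terminated_early,
    ledger_weights = as.list(res$ledger$weights),
    partition = if (!is.null(res$partition)) unclass(res$partition))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(res$best$key, file.path(out_dir, "best_tree.txt"))
    utils::write.csv(res$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      run_manifest(cfg, seed, input_desc,
                   list(train_fraction = train_fraction,
                        standardize = standardize_features,
                        baseline = baseline)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  invisible(report)
}
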