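# The embedded feature-selection machinery and the full driver.

#' Feature-weight ledger
#'
#' Accumulates, per feature, the number of terminal occurrences across all
#' above-average classifiers processed during the weighting phase. All
#' weights start at 0.
#'
#' @param features feature-name vector of the bound dataset.
#' @return An object of class `feature_weight_ledger` with integer `weights`
#'   (named, one entry per feature) and `generations_accumulated`.
#' @export
new_ledger <- function(features) {
  structure(list(weights = setNames(integer(length(features)), features),
                 generations_accumulated = 0L),
            class = "feature_weight_ledger")
}

#' @export
print.feature_weight_ledger <- function(x, ...) {
  cat(sprintf("feature-weight ledger: %d features, total weight %d over %d generations\n",
              length(x$weights), sum(x$weights), x$generations_accumulated))
  top <- sort(x$weights, decreasing = TRUE)
  top <- top[top > 0]
  if (length(top)) {
    top <- utils::head(top, 8)
    cat("  top:", paste(sprintf("%s=%d", names(top), top), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Above-average classifiers of a generation (Cgaa)
#'
#' Returns the individuals whose fitness is strictly greater than the
#' population mean fitness; empty when all fitnesses are equal.
#'
#' @param population an evaluated `gp_population`.
#' @return List of individuals.
#' @export
select_cgaa <- function(population) {
  fits <- require_evaluated(pop_fitnesses(population))
  population$individuals[fits > mean(fits)]
}

#' Accumulate feature weights from Cgaa classifiers
#'
#' Each feature-terminal occurrence in each tree adds 1 to that feature's
#' weight (a feature appearing twice in one tree adds 2); constants
#' contribute nothing. With `per_tree = TRUE` a feature adds at most 1 per
#' tree regardless of multiplicity.
#'
#' @param ledger a [new_ledger()].
#' @param cgaa list of individuals (from [select_cgaa()]).
#' @param per_tree count presence instead of occurrences?
#' @return The updated ledger (`generations_accumulated` + 1).
#' @export
accumulate_weights <- function(ledger, cgaa, per_tree = FALSE) {
  feats <- names(ledger$weights)
  for (ind in cgaa) {
    if (!identical(ind$tree$features, feats))
      fsgp_error("tree is bound to a different feature set than the ledger",
                 "fsgp_schema_error")
    cnt <- feature_counts_cpp(ind$tree$root, length(feats))
    if (per_tree) cnt <- as.integer(cnt > 0L)
    ledger$weights <- ledger$weights + cnt
  }
  ledger$generations_accumulated <- ledger$generations_accumulated + 1L
  ledger
}

#' Partition features into kept (Fso) and purged (Fno) subsets
#'
#' The mean weight is `sum(weights) / n_features` (by default over the full
#' feature set, zero-weight features included); Fso is every feature with
#' weight strictly greater than the mean, Fno the complement. If no feature
#' clears the mean (all weights equal) the fallback keeps the maximal-weight
#' features. A ledger with zero total weight raises a degenerate-ledger
#' error so the driver can skip the purge.
#'
#' @param ledger a [new_ledger()] after accumulation.
#' @param average_over `"all"` or `"nonzero"` (see [fsgp_config()]).
#' @return An object of class `feature_partition` with `fso` and `fno`.
#' @export
partition_features <- function(ledger, average_over = c("all", "nonzero")) {
  average_over <- match.arg(average_over)
  if (ledger$generations_accumulated < 1L)
    fsgp_error("ledger has accumulated no generations", "fsgp_state_error")
  w <- ledger$weights
  total <- sum(w)
  if (total == 0)
    fsgp_error("ledger total weight is zero (no above-average classifier ever seen); skip the replacement step",
               "fsgp_degenerate_ledger")
  denom <- if (average_over == "all") length(w) else sum(w > 0)
  mean_w <- total / denom
  fso <- names(w)[w > mean_w]
  if (length(fso) == 0) fso <- names(w)[w == max(w)]
  structure(list(fso = fso, fno = setdiff(names(w), fso)),
            class = "feature_partition")
}

#' @export
print.feature_partition <- function(x, ...) {
  cat(sprintf("feature partition: %d kept (Fso), %d purged (Fno)\n",
              length(x$fso), length(x$fno)))
  invisible(x)
}

#' Purge Fno features from a tree (replacement mutation)
#'
#' For each Fno feature terminal in the tree (in preorder), draws random Fso
#' replacements -- evaluating the modified tree each time, up to
#' `hc_max_retries` draws -- and adopts the first strictly improving
#' replacement, else the best-fitness replacement found. The Fno terminal is
#' replaced regardless, so the returned tree contains no Fno reference even
#' when every candidate loses fitness; the returned individual carries the
#' freshly evaluated fitness of the adopted tree.
#'
#' @param individual an evaluated individual.
#' @param partition a [partition_features()] result with non-empty `fso`.
#' @inheritParams hc_crossover
#' @return The purged individual (unchanged if the tree had no Fno terminal).
#' @export
replace_fno <- function(individual, partition, config, train,
                        counter = NULL) {
  if (length(partition$fso) == 0)
    fsgp_error("fso is empty; cannot purge", "fsgp_precondition_error")
  if (is.na(individual$fitness))
    fsgp_error("individual must be evaluated before purging",
               "fsgp_state_error")
  feats <- individual$tree$features
  root <- individual$tree$root
  fit <- individual$fitness
  fno_paths <- collect_feature_paths(root, partition$fno)
  if (length(fno_paths) == 0) return(individual)
  fso <- partition$fso
  draws <- max(1L, config$hc_max_retries)
  if (length(fso) == 1L) draws <- 1L
  for (path in fno_paths) {
    best_f <- -Inf
    best_root <- NULL
    adopted <- FALSE
    for (d in seq_len(draws)) {
      repl <- fso[sample.int(length(fso), 1L)]
      cand <- set_subtree(root, path, node_feat(repl, match(repl, feats)))
      f <- fitness(gp_tree(cand, feats), train, config, counter)
      if (f > fit) {
        root <- cand; fit <- f; adopted <- TRUE
        break
      }
      if (f > best_f) { best_f <- f; best_root <- cand }
    }
    if (!adopted) { root <- best_root; fit <- best_f }
  }
  new_individual(gp_tree(root, feats), fit)
}

best_of <- function(pop) {
  fits <- pop_fitnesses(pop)
  pop$individuals[[which.max(fits)]]
}

#' Run the full feature-selecting GP life cycle
#'
#' Executes the complete algorithm on a training table:
#' 1. ramped half-and-half initialization with structural diversity, all
#'    individuals evaluated;
#' 2. generational evolution via elitism plus hill-climbing crossover and
#'    mutation, every fitness evaluation charged against
#'    `evaluation_budget`;
#' 3. during the first half of the run (until half the budget is spent),
#'    each generation's above-average classifiers (Cgaa) add their feature
#'    occurrences to the weight ledger;
#' 4. at the end of the first generation where half the budget is spent,
#'    features are partitioned into Fso/Fno and every individual is purged
#'    with [replace_fno()]; from then on mutation draws features only from
#'    Fso, so no purged feature can re-enter the population;
#' 5. the run stops as soon as any individual reaches training fitness 1.0
#'    or the budget is exhausted (never more than one generation over).
#'
#' The reported best classifier is the best individual seen from the purged
#' population onward (so its features are a subset of Fso); without feature
#' selection, or when the purge was skipped, it is the best ever seen.
#'
#' @param train training [feature_table()].
#' @param config an [fsgp_config()]; `config$seed` makes the run
#'   reproducible.
#' @param feature_selection `FALSE` runs the plain-GP baseline: identical
#'   evolution, no weighting, no purge.
#' @param collect_cgaa keep the serialized Cgaa trees of every weighting
#'   generation in the result (for auditing weight conservation).
#' @return An object of class `fsgp_result`: `best` (individual),
#'   `selected_features`, `history` (per-generation data frame with
#'   best/mean fitness, evaluations, diversity, and post-purge Fno reference
#'   counts), `partition`, `ledger`, `total_evaluations`,
#'   `replacement_generation`, `terminated_early`, `population` (final), and
#'   the `config`.
#' @examples
#' ft <- generate_synthetic(synthetic_spec(n_samples = 40, seed = 3))
#' res <- run_fsgp(standardize(ft),
#'                 fsgp_config(evaluation_budget = 1500, seed = 3))
#' res
#' @export
run_fsgp <- function(train, config, feature_selection = TRUE,
                     collect_cgaa = FALSE) {
  stopifnot(inherits(train, "feature_table"),
            inherits(config, "fsgp_config"))
  validate_config(config)
  with_preserved_seed(config$seed, {
    features <- colnames(train$values)
    counter <- new_eval_counter()
    budget <- config$evaluation_budget
    half <- floor(budget / 2)
    pop <- init_population(config, features)
    pop$individuals <- lapply(pop$individuals, function(ind) {
      ind$fitness <- fitness(ind$tree, train, config, counter)
      ind
    })
    ledger <- new_ledger(features)
    cgaa_log <- list()
    partition <- NULL
    pool <- features
    weighting <- feature_selection
    replaced <- FALSE
    fs_active <- feature_selection
    replacement_generation <- NA_integer_
    history <- list()
    record <- function(pop) {
      fits <- pop_fitnesses(pop)
      fno_refs <- if (replaced) {
        sum(vapply(pop$individuals, function(ind) {
          sum(feature_counts_cpp(ind$tree$root,
                                 length(features))[match(partition$fno,
                                                         features)])
        }, numeric(1)))
      } else NA_real_
      history[[length(history) + 1L]] <<- data.frame(
        generation = pop$generation,
        best_fitness = max(fits),
        mean_fitness = mean(fits),
        evaluations = counter$n,
        diversity = length(unique(vapply(pop$individuals,
                                         function(i) i$key, character(1)))),
        fno_references = fno_refs)
    }
    weigh <- function(pop) {
      cg <- select_cgaa(pop)
      ledger <<- accumulate_weights(ledger, cg, config$weight_per_tree)
      if (collect_cgaa)
        cgaa_log[[length(cgaa_log) + 1L]] <<-
          vapply(cg, function(i) i$key, character(1))
    }
    if (weighting) weigh(pop)
    record(pop)
    best_ever <- best_of(pop)
    while (counter$n < budget && best_ever$fitness < 1) {
      pop <- next_generation(pop, config, train, counter, pool)
      gen_best <- best_of(pop)
      if (gen_best$fitness > best_ever$fitness) best_ever <- gen_best
      if (best_ever$fitness >= 1) { record(pop); break }
      if (weighting) weigh(pop)
      if (fs_active && !replaced && counter$n >= half) {
        p <- tryCatch(partition_features(ledger, config$weight_average),
                      fsgp_degenerate_ledger = function(e) NULL)
        if (is.null(p)) {
          warning("degenerate feature-weight ledger: skipping the replacement step, continuing as plain GP",
                  call. = FALSE)
          fs_active <- FALSE
        } else {
          partition <- p
          pop$individuals <- lapply(pop$individuals, replace_fno,
                                    partition = p, config = config,
                                    train = train, counter = counter)
          pool <- p$fso
          replaced <- TRUE
          replacement_generation <- pop$generation
          # report the best classifier of the purged lineage onward
          best_ever <- best_of(pop)
        }
        weighting <- FALSE
      }
      record(pop)
    }
    structure(list(
      best = best_ever,
      selected_features = tree_features(best_ever$tree),
      history = do.call(rbind, history),
      partition = partition,
      ledger = ledger,
      total_evaluations = counter$n,
      replacement_generation = replacement_generation,
      terminated_early = best_ever$fitness >= 1,
      population = pop,
      cgaa_log = if (collect_cgaa) cgaa_log else NULL,
      feature_selection = feature_selection,
      config = config), class = "fsgp_result")
  })
}

#' @export
print.fsgp_result <- function(x, ...) {
  cat(sprintf("%s run: %d generations, %d evaluations%s\n",
              if (x$feature_selection) "FSGP" else "plain GP",
              max(x$history$generation), x$total_evaluations,
              if (x$terminated_early) " (terminated at fitness 1.0)" else ""))
  cat(sprintf("  best training accuracy %.4f with %d features\n",
              x$best$fitness, length(x$selected_features)))
  if (!is.null(x$partition))
    cat(sprintf("  purge at generation %d: kept %d features, purged %d\n",
                x$replacement_generation, length(x$partition$fso),
                length(x$partition$fno)))
  invisible(x)
}
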