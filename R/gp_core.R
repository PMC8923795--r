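# Evaluation, population initialization, and the three genetic operators.

coerce_sample_matrix <- function(tree, data) {
  feats <- tree$features
  if (inherits(data, "feature_table")) data <- data$values
  if (is.data.frame(data)) data <- as.matrix(data)
  if (is.null(dim(data))) {
    if (is.null(names(data)))
      fsgp_error("a single sample must be a named numeric vector",
                 "fsgp_argument_error")
    data <- matrix(data, nrow = 1, dimnames = list(NULL, names(data)))
  }
  if (identical(colnames(data), feats)) return(data)
  miss <- setdiff(feats, colnames(data))
  if (length(miss))
    fsgp_error(sprintf("sample is missing features: %s",
                       paste(utils::head(miss, 5), collapse = ", ")),
               "fsgp_schema_error")
  data[, feats, drop = FALSE]
}

#' Evaluate a tree on samples
#'
#' Recursive arithmetic evaluation with protected operators: division by a
#' near-zero denominator (|d| < 1e-9) yields 1, as does a non-finite
#' quotient, and any residual non-finite value at the root is clamped to 0,
#' so outputs are always finite.
#'
#' @param tree a [gp_tree()].
#' @param data a [feature_table()], numeric matrix/data frame with the
#'   tree's features as columns, or a single named numeric vector.
#' @return Numeric vector, one value per sample.
#' @examples
#' ft <- generate_synthetic(synthetic_spec(n_samples = 8, seed = 2))
#' tr <- parse_tree("(+ AF3_theta (div F7_alpha 0.25))",
#'                  colnames(ft$values))
#' evaluate_tree(tr, ft)
#' @export
evaluate_tree <- function(tree, data) {
  stopifnot(inherits(tree, "gp_tree"))
  eval_tree_cpp(tree$root, coerce_sample_matrix(tree, data))
}

#' Classify samples with a tree
#'
#' Sign thresholding: a sample is labelled positive iff the tree output is
#' `>= threshold` (default 0).
#'
#' @inheritParams evaluate_tree
#' @param threshold decision threshold.
#' @return Factor with levels `c("negative", "positive")`.
#' @export
classify <- function(tree, data, threshold = 0) {
  v <- evaluate_tree(tree, data)
  factor(ifelse(v >= threshold, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Training-set fitness of a tree
#'
#' Fitness is classification accuracy on the training table: the fraction
#' of samples whose sign-thresholded tree output matches the label. Each
#' call charges one unit to `counter`, the budget bookkeeping used by
#' [run_fsgp()].
#'
#' @param tree a [gp_tree()].
#' @param train a non-empty [feature_table()].
#' @param config an [fsgp_config()] (supplies the threshold).
#' @param counter optional [new_eval_counter()] to charge.
#' @return Accuracy in `[0, 1]`.
#' @export
fitness <- function(tree, train, config, counter = NULL) {
  stopifnot(inherits(train, "feature_table"))
  if (nrow(train$values) == 0)
    fsgp_error("training table is empty", "fsgp_data_error")
  v <- eval_tree_cpp(tree$root, train$values)
  bump_counter(counter)
  mean((v >= config$classification_threshold) ==
         (train$labels == "positive"))
}

new_individual <- function(tree, fit = NA_real_) {
  list(tree = tree, fitness = fit, key = deparse_tree(tree))
}

pop_fitnesses <- function(pop) {
  vapply(pop$individuals, function(i) i$fitness, numeric(1))
}

require_evaluated <- function(fits) {
  if (anyNA(fits))
    fsgp_error("population contains unevaluated individuals",
               "fsgp_state_error")
  invisible(fits)
}

#' Initialize a population (ramped half-and-half)
#'
#' Builds `population_size` trees cycling the depth ramp
#' `init_min_depth..init_max_depth` and alternating the grow and full
#' methods, enforcing structural diversity: no two trees share a canonical
#' serialization. Fitness is left unevaluated.
#'
#' @param config an [fsgp_config()].
#' @param features feature-name vector of the bound dataset.
#' @param pool terminal feature pool (defaults to all features).
#' @return An object of class `gp_population`.
#' @export
init_population <- function(config, features, pool = features) {
  depths <- seq(config$init_min_depth, config$init_max_depth)
  seen <- new.env(parent = emptyenv())
  inds <- vector("list", config$population_size)
  for (i in seq_len(config$population_size)) {
    method <- if (i %% 2L == 1L) "grow" else "full"
    d <- depths[((i - 1L) %/% 2L) %% length(depths) + 1L]
    ok <- FALSE
    for (try in seq_len(config$diversity_retries)) {
      tree <- make_random_tree(method, min(d, config$init_min_depth), d,
                               config, features, pool)
      key <- deparse_tree(tree)
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        inds[[i]] <- list(tree = tree, fitness = NA_real_, key = key)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      fsgp_error(sprintf(
        "could not generate a structurally distinct tree within %d retries (individual %d of %d)",
        config$diversity_retries, i, config$population_size),
        "fsgp_diversity_error")
  }
  structure(list(individuals = inds, generation = 0L),
            class = "gp_population")
}

#' @export
print.gp_population <- function(x, ...) {
  fits <- pop_fitnesses(x)
  cat(sprintf("GP population: %d individuals, generation %d\n",
              length(x$individuals), x$generation))
  if (!anyNA(fits))
    cat(sprintf("  fitness best %.4f / mean %.4f\n", max(fits), mean(fits)))
  invisible(x)
}

# Core tournament on precomputed fitnesses; ties -> smaller tree, then uniform.
tournament_index <- function(inds, fits, k) {
  cand <- sample.int(length(inds), k, replace = TRUE)
  best <- cand[fits[cand] == max(fits[cand])]
  if (length(best) > 1L) {
    sizes <- vapply(best, function(i) tree_size(inds[[i]]$tree), integer(1))
    best <- best[sizes == min(sizes)]
    if (length(best) > 1L) best <- best[sample.int(length(best), 1L)]
  }
  best[1L]
}

#' Tournament selection
#'
#' Samples `k` individuals uniformly with replacement and returns the one
#' with the highest fitness; ties are broken in favour of the smaller tree,
#' then uniformly at random. Sampling is with replacement even at
#' `k = population size`, so the global best wins with probability
#' `1 - ((n-1)/n)^k`, approaching but never reaching certainty.
#'
#' @param population an evaluated `gp_population`.
#' @param k tournament size.
#' @return The selected individual (a list with `tree`, `fitness`, `key`).
#' @export
tournament_select <- function(population, k) {
  inds <- population$individuals
  if (k < 1L || k > length(inds))
    fsgp_error("k must lie in 1..population size", "fsgp_argument_error")
  fits <- require_evaluated(pop_fitnesses(population))
  inds[[tournament_index(inds, fits, k)]]
}

#' Hill-climbing crossover
#'
#' Subtree-exchange crossover with a parent-versus-child guard: up to
#' `hc_max_retries` attempts, each swapping uniformly chosen subtrees of the
#' two parents. A child takes its parent's slot only if it is strictly
#' fitter and respects `max_tree_depth`; otherwise the parent is returned
#' unchanged. Every evaluated child costs one budget unit.
#'
#' @param parent_a,parent_b evaluated individuals.
#' @param config an [fsgp_config()].
#' @param train training [feature_table()].
#' @param counter optional evaluation counter.
#' @return List of two individuals (the slot winners).
#' @export
hc_crossover <- function(parent_a, parent_b, config, train, counter = NULL) {
  out <- list(parent_a, parent_b)
  if (config$hc_max_retries < 1L) return(out)
  root_a <- parent_a$tree$root; root_b <- parent_b$tree$root
  paths_a <- collect_paths(root_a); paths_b <- collect_paths(root_b)
  feats <- parent_a$tree$features
  done <- c(FALSE, FALSE)
  for (attempt in seq_len(config$hc_max_retries)) {
    pa <- paths_a[[sample.int(length(paths_a), 1L)]]
    pb <- paths_b[[sample.int(length(paths_b), 1L)]]
    sub_a <- get_subtree(root_a, pa)
    sub_b <- get_subtree(root_b, pb)
    if (!done[1]) {
      child <- gp_tree(set_subtree(root_a, pa, sub_b), feats)
      if (tree_depth(child) <= config$max_tree_depth) {
        f <- fitness(child, train, config, counter)
        if (f > parent_a$fitness) { out[[1]] <- new_individual(child, f); done[1] <- TRUE }
      }
    }
    if (!done[2]) {
      child <- gp_tree(set_subtree(root_b, pb, sub_a), feats)
      if (tree_depth(child) <= config$max_tree_depth) {
        f <- fitness(child, train, config, counter)
        if (f > parent_b$fitness) { out[[2]] <- new_individual(child, f); done[2] <- TRUE }
      }
    }
    if (all(done)) break
  }
  out
}

#' Hill-climbing subtree mutation
#'
#' Replaces a uniformly chosen subtree with a fresh grow-method subtree
#' (depth budget respecting `max_tree_depth`), up to `hc_max_retries`
#' attempts; returns the first strictly fitter child, else the parent.
#' Fresh subtrees draw feature terminals from `pool`, which the driver
#' narrows to Fso after the purge so mutation cannot reintroduce purged
#' features.
#'
#' @param parent an evaluated individual.
#' @inheritParams hc_crossover
#' @param pool feature names mutation may introduce.
#' @return The winning individual.
#' @export
hc_mutation <- function(parent, config, train, counter = NULL,
                        pool = parent$tree$features) {
  if (config$hc_max_retries < 1L) return(parent)
  root <- parent$tree$root
  feats <- parent$tree$features
  paths <- collect_paths(root)
  for (attempt in seq_len(config$hc_max_retries)) {
    p <- paths[[sample.int(length(paths), 1L)]]
    allowed <- config$max_tree_depth - length(p)
    sub <- make_random_tree("grow", 1L,
                            max(1L, min(allowed, config$init_max_depth)),
                            config, feats, pool)
    child <- gp_tree(set_subtree(root, p, sub$root), feats)
    f <- fitness(child, train, config, counter)
    if (f > parent$fitness) return(new_individual(child, f))
  }
  parent
}

#' Produce the next generation
#'
#' Elitism copies the single best individual (ties: smaller tree, then first)
#' into the new population; remaining slots are filled by drawing an operator
#' per slot with probabilities `(p_crossover, p_reproduction, p_mutation)`,
#' parents chosen by tournament. Crossover fills two slots (one if only one
#' remains), reproduction copies its selected parent, mutation applies
#' [hc_mutation()]. The hill-climbing guards plus elitism make the
#' best-of-population fitness non-decreasing across plain evolution.
#'
#' @param population evaluated `gp_population`.
#' @inheritParams hc_mutation
#' @return A `gp_population` of identical size, generation index + 1.
#' @export
next_generation <- function(population, config, train, counter = NULL,
                            pool = NULL) {
  probs <- c(config$p_crossover, config$p_reproduction, config$p_mutation)
  if (abs(sum(probs) - 1) > 1e-8)
    fsgp_error("operator probabilities must sum to 1", "fsgp_config_error")
  inds <- population$individuals
  n <- length(inds)
  fits <- require_evaluated(pop_fitnesses(population))
  if (is.null(pool)) pool <- inds[[1]]$tree$features
  # elite: best fitness, ties broken toward the smaller tree
  top <- which(fits == max(fits))
  if (length(top) > 1L) {
    sizes <- vapply(top, function(i) tree_size(inds[[i]]$tree), integer(1))
    top <- top[sizes == min(sizes)]
  }
  new_inds <- vector("list", n)
  new_inds[[1L]] <- inds[[top[1L]]]
  filled <- 1L
  thresholds <- cumsum(probs)
  while (filled < n) {
    r <- runif(1)
    if (r < thresholds[1]) {
      pa <- inds[[tournament_index(inds, fits, config$tournament_size)]]
      pb <- inds[[tournament_index(inds, fits, config$tournament_size)]]
      pair <- hc_crossover(pa, pb, config, train, counter)
      new_inds[[filled + 1L]] <- pair[[1]]
      filled <- filled + 1L
      if (filled < n) {
        new_inds[[filled + 1L]] <- pair[[2]]
        filled <- filled + 1L
      }
    } else if (r < thresholds[2]) {
      new_inds[[filled + 1L]] <- inds[[tournament_index(inds, fits, config$tournament_size)]]
      filled <- filled + 1L
    } else {
      parent <- inds[[tournament_index(inds, fits, config$tournament_size)]]
      new_inds[[filled + 1L]] <- hc_mutation(parent, config, train, counter,
                                             pool)
      filled <- filled + 1L
    }
  }
  structure(list(individuals = new_inds,
                 generation = population$generation + 1L),
            class = "gp_population")
}
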