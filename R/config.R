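GP_OPS <- c("+", "-", "*", "/")

#' Configuration for a GP run
#'
#' Bundles every tunable of the evolutionary search. The defaults are the
#' study conditions of the motivating EEG experiments: population 100,
#' operator probabilities 60/20/20 (crossover/reproduction/mutation), ramped
#' half-and-half initialization over depths 5--10, and an evaluation budget
#' of 80000 fitness evaluations.
#'
#' @param population_size number of individuals per generation.
#' @param p_crossover,p_reproduction,p_mutation per-slot operator
#'   probabilities; must sum to 1.
#' @param init_min_depth,init_max_depth depth ramp for ramped half-and-half
#'   initialization (a lone terminal has depth 1).
#' @param max_tree_depth hard depth cap for every evolved tree (Koza's 17).
#' @param tournament_size tournament size for parent selection.
#' @param evaluation_budget total number of fitness evaluations the run may
#'   spend; hill-climbing retries and purge re-evaluations all count.
#' @param function_set subset of `c("+", "-", "*", "/")`; `/` is protected
#'   (returns 1 on a near-zero denominator).
#' @param constant_range interval ephemeral random constants are drawn from
#'   (uniformly, rounded to 6 significant digits so serialization is exact).
#' @param constant_prob probability that a fresh terminal is a constant
#'   rather than a feature reference; 0 gives a features-only terminal set.
#' @param grow_fun_prob probability the grow initializer places a function
#'   node at an unconstrained depth.
#' @param hc_max_retries attempt cap for the hill-climbing crossover and
#'   mutation operators and for each purge-time replacement draw.
#' @param classification_threshold tree outputs `>= threshold` are classified
#'   positive.
#' @param diversity_retries attempts to draw a structurally novel tree during
#'   initialization before giving up with a diversity error.
#' @param weight_per_tree if `TRUE`, feature weighting counts each feature at
#'   most once per above-average classifier; the default counts every
#'   terminal occurrence.
#' @param weight_average `"all"` averages weights over the full feature set
#'   (zero-weight features included); `"nonzero"` averages over features seen
#'   at least once.
#' @param seed integer seed making the whole run reproducible.
#' @return An object of class `fsgp_config` (a validated named list).
#' @examples
#' cfg <- fsgp_config(evaluation_budget = 2000, init_max_depth = 6)
#' cfg$population_size
#' @export
fsgp_config <- function(population_size = 100L,
                        p_crossover = 0.6,
                        p_reproduction = 0.2,
                        p_mutation = 0.2,
                        init_min_depth = 5L,
                        init_max_depth = 10L,
                        max_tree_depth = 17L,
                        tournament_size = 7L,
                        evaluation_budget = 80000L,
                        function_set = GP_OPS,
                        constant_range = c(-1, 1),
                        constant_prob = 0.1,
                        grow_fun_prob = 0.5,
                        hc_max_retries = 10L,
                        classification_threshold = 0,
                        diversity_retries = 200L,
                        weight_per_tree = FALSE,
                        weight_average = c("all", "nonzero"),
                        seed = 1L) {
  cfg <- list(
    population_size = as.integer(population_size),
    p_crossover = p_crossover,
    p_reproduction = p_reproduction,
    p_mutation = p_mutation,
    init_min_depth = as.integer(init_min_depth),
    init_max_depth = as.integer(init_max_depth),
    max_tree_depth = as.integer(max_tree_depth),
    tournament_size = as.integer(tournament_size),
    evaluation_budget = as.integer(evaluation_budget),
    function_set = function_set,
    constant_range = as.numeric(constant_range),
    constant_prob = constant_prob,
    grow_fun_prob = grow_fun_prob,
    hc_max_retries = as.integer(hc_max_retries),
    classification_threshold = classification_threshold,
    diversity_retries = as.integer(diversity_retries),
    weight_per_tree = isTRUE(weight_per_tree),
    weight_average = match.arg(weight_average),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "fsgp_config")
}

validate_config <- function(cfg) {
  probs <- c(cfg$p_crossover, cfg$p_reproduction, cfg$p_mutation)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    fsgp_error("operator probabilities must be non-negative and sum to 1",
               "fsgp_config_error")
  if (cfg$population_size < 2L)
    fsgp_error("population_size must be at least 2", "fsgp_config_error")
  if (!(cfg$init_min_depth >= 1L &&
        cfg$init_min_depth <= cfg$init_max_depth &&
        cfg$init_max_depth <= cfg$max_tree_depth))
    fsgp_error("need 1 <= init_min_depth <= init_max_depth <= max_tree_depth",
               "fsgp_config_error")
  if (length(cfg$function_set) > 0 && !all(cfg$function_set %in% GP_OPS))
    fsgp_error(sprintf("function_set must be a subset of {%s}",
                       paste(GP_OPS, collapse = ", ")),
               "fsgp_config_error")
  if (length(cfg$constant_range) != 2 || diff(cfg$constant_range) < 0)
    fsgp_error("constant_range must be an interval c(lo, hi)",
               "fsgp_config_error")
  if (cfg$constant_prob < 0 || cfg$constant_prob > 1)
    fsgp_error("constant_prob must lie in [0, 1]", "fsgp_config_error")
  if (cfg$evaluation_budget < cfg$population_size)
    fsgp_error("evaluation_budget must cover at least the initial population",
               "fsgp_config_error")
  if (cfg$tournament_size < 1L)
    fsgp_error("tournament_size must be >= 1", "fsgp_config_error")
  if (cfg$hc_max_retries < 0L)
    fsgp_error("hc_max_retries must be >= 0", "fsgp_config_error")
  invisible(cfg)
}

#' @export
print.fsgp_config <- function(x, ...) {
  cat("GP run configuration\n")
  cat(sprintf("  population %d, budget %d evaluations, seed %d\n",
              x$population_size, x$evaluation_budget, x$seed))
  cat(sprintf("  operators: crossover %.0f%% / reproduction %.0f%% / mutation %.0f%% (hill-climbing, %d retries)\n",
              100 * x$p_crossover, 100 * x$p_reproduction, 100 * x$p_mutation,
              x$hc_max_retries))
  cat(sprintf("  trees: ramp %d-%d, cap %d; functions {%s}; constants U[%g, %g] (p = %g)\n",
              x$init_min_depth, x$init_max_depth, x$max_tree_depth,
              paste(x$function_set, collapse = " "),
              x$constant_range[1], x$constant_range[2], x$constant_prob))
  invisible(x)
}
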