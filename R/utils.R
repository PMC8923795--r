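# Internal helpers: classed errors and RNG hygiene.

fsgp_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "fsgp_error"), call = call))
}

# Run `code` under set.seed(seed) without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Create a fitness-evaluation counter
#'
#' Every call to [fitness()] that is handed this counter increments it by one;
#' it is the unit in which [run_fsgp()]'s evaluation budget is spent
#' (hill-climbing retries and purge-time re-evaluations included).
#'
#' @return An environment with an integer field `n`, initialised to 0.
#' @seealso [eval_count()]
#' @export
new_eval_counter <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e
}

#' @rdname new_eval_counter
#' @param counter a counter from [new_eval_counter()].
#' @export
eval_count <- function(counter) counter$n

bump_counter <- function(counter) {
  if (!is.null(counter)) counter$n <- counter$n + 1L
  invisible(NULL)
}
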