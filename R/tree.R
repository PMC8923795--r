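# Expression-tree genotype: construction, serialization, traversal.
# Node layout is shared with src/tree_ops.cpp -- do not reorder fields.

node_fun <- function(op, kids) {
  list(t = 0L, oc = match(op, GP_OPS), op = op, kids = kids)
}
node_feat <- function(name, ix) list(t = 1L, ix = as.integer(ix), feat = name)
node_const <- function(value) list(t = 2L, val = value)

#' GP classifier trees
#'
#' A `gp_tree` is an expression tree over a fixed feature set: internal
#' nodes are arithmetic operators from the configured function set, leaves
#' are feature references or real constants. `features` records the full
#' feature-name vector the tree's column indices are bound to.
#'
#' @param root internal node structure (use [make_random_tree()] or
#'   [parse_tree()] rather than building nodes by hand).
#' @param features character vector of all feature names the tree may
#'   reference.
#' @return An object of class `gp_tree`.
#' @seealso [deparse_tree()], [evaluate_tree()], [tree_depth()]
#' @export
gp_tree <- function(root, features) {
  structure(list(root = root, features = features), class = "gp_tree")
}

#' @export
print.gp_tree <- function(x, ...) {
  s <- deparse_tree(x)
  if (nchar(s) > 200) s <- paste0(substr(s, 1, 197), "...")
  cat(sprintf("GP tree (depth %d, %d nodes, %d distinct features)\n  %s\n",
              tree_depth(x), tree_size(x), length(tree_features(x)), s))
  invisible(x)
}

#' Tree measurements
#'
#' `tree_depth()` counts levels (a lone terminal has depth 1), `tree_size()`
#' counts nodes, `tree_features()` lists the distinct features referenced
#' (in canonical feature order), and `feature_counts()` returns per-feature
#' terminal occurrence counts over the tree's full feature set.
#'
#' @param tree a [gp_tree()].
#' @export
tree_depth <- function(tree) tree_depth_cpp(tree$root)

#' @rdname tree_depth
#' @export
tree_size <- function(tree) tree_size_cpp(tree$root)

#' @rdname tree_depth
#' @export
feature_counts <- function(tree) {
  setNames(feature_counts_cpp(tree$root, length(tree$features)),
           tree$features)
}

#' @rdname tree_depth
#' @export
tree_features <- function(tree) {
  cnt <- feature_counts(tree)
  names(cnt)[cnt > 0]
}

format_const <- function(v) {
  s <- formatC(v, digits = 6, format = "g")
  gsub(" ", "", s)
}

#' Canonical s-expression serialization
#'
#' Trees print as prefix s-expressions, e.g.
#' `(+ AF3_theta (div F7_alpha 0.25))`; protected division prints as `div`,
#' constants with 6 significant digits. [parse_tree()] accepts the same
#' grammar, and because ephemeral constants are generated pre-rounded to 6
#' significant digits the round trip is exact. Serialization is injective
#' up to structural equality, so it doubles as the diversity key during
#' initialization.
#'
#' @param tree a [gp_tree()].
#' @return A single string.
#' @export
deparse_tree <- function(tree) deparse_node(tree$root)

deparse_node <- function(node) {
  if (node$t == 1L) return(node$feat)
  if (node$t == 2L) return(format_const(node$val))
  op <- if (node$op == "/") "div" else node$op
  paste0("(", op, " ", deparse_node(node$kids[[1]]), " ",
         deparse_node(node$kids[[2]]), ")")
}

#' @rdname deparse_tree
#' @param text s-expression text.
#' @param features feature-name vector to bind references against.
#' @export
parse_tree <- function(text, features) {
  toks <- strsplit(gsub("([()])", " \\1 ", text), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0)
    fsgp_error("empty tree text", "fsgp_parse_error")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_expr <- function() {
    tok <- take()
    if (is.na(tok)) fsgp_error("unexpected end of input", "fsgp_parse_error")
    if (tok == "(") {
      op <- take()
      if (identical(op, "div")) op <- "/"
      if (!op %in% GP_OPS)
        fsgp_error(sprintf("unknown function symbol '%s'", op),
                   "fsgp_parse_error")
      a <- parse_expr()
      b <- parse_expr()
      if (!identical(take(), ")"))
        fsgp_error(sprintf("expected ')' after 2 arguments of '%s'", op),
                   "fsgp_parse_error")
      return(node_fun(op, list(a, b)))
    }
    if (tok == ")") fsgp_error("unexpected ')'", "fsgp_parse_error")
    ix <- match(tok, features)
    if (!is.na(ix)) return(node_feat(tok, ix))
    v <- suppressWarnings(as.numeric(tok))
    if (is.na(v))
      fsgp_error(sprintf("token '%s' is neither a feature nor a number", tok),
                 "fsgp_parse_error")
    node_const(v)
  }
  root <- parse_expr()
  if (pos <= length(toks))
    fsgp_error("trailing tokens after complete expression",
               "fsgp_parse_error")
  gp_tree(root, features)
}

# -- random construction -----------------------------------------------------

random_terminal <- function(config, features, pool) {
  if (runif(1) < config$constant_prob) {
    node_const(signif(runif(1, config$constant_range[1],
                            config$constant_range[2]), 6))
  } else {
    name <- pool[sample.int(length(pool), 1L)]
    node_feat(name, match(name, features))
  }
}

#' Generate a random tree (grow or full method)
#'
#' `full` places function nodes everywhere above the target depth so every
#' leaf sits at exactly `max_depth`; `grow` forces function nodes until
#' `min_depth` and terminals at `max_depth`, choosing freely in between, so
#' depth lands in `[min_depth, max_depth]`. Terminals are feature
#' references from `pool` or constants from the configured range.
#'
#' @param method `"grow"` or `"full"`.
#' @param min_depth,max_depth depth bounds (1 means a lone terminal).
#' @param config an [fsgp_config()].
#' @param features full feature-name vector (binds column indices).
#' @param pool feature names terminals may be drawn from; defaults to all
#'   of `features` (the driver narrows this to Fso after the purge).
#' @return A [gp_tree()].
#' @export
make_random_tree <- function(method = c("grow", "full"), min_depth, max_depth,
                             config, features, pool = features) {
  method <- match.arg(method)
  min_depth <- as.integer(min_depth); max_depth <- as.integer(max_depth)
  if (!(min_depth >= 1L && min_depth <= max_depth))
    fsgp_error("need 1 <= min_depth <= max_depth", "fsgp_argument_error")
  if (length(config$function_set) == 0 && max_depth > 1L)
    fsgp_error("empty function set cannot build trees deeper than 1",
               "fsgp_config_error")
  if (length(pool) == 0 && config$constant_prob <= 0)
    fsgp_error("no terminals available (empty pool, no constants)",
               "fsgp_config_error")
  build <- function(depth) {
    make_fun <- if (method == "full") depth < max_depth
    else depth < min_depth ||
      (depth < max_depth && runif(1) < config$grow_fun_prob)
    if (!make_fun) return(random_terminal(config, features, pool))
    op <- config$function_set[sample.int(length(config$function_set), 1L)]
    node_fun(op, list(build(depth + 1L), build(depth + 1L)))
  }
  gp_tree(build(1L), features)
}

# -- traversal ---------------------------------------------------------------

# All node positions as child-index paths (root = integer(0)), preorder.
collect_paths <- function(node, prefix = integer(0)) {
  out <- list(prefix)
  if (node$t == 0L) {
    for (j in seq_along(node$kids)) {
      out <- c(out, collect_paths(node$kids[[j]], c(prefix, j)))
    }
  }
  out
}

# Paths of feature terminals whose name is in `set`.
collect_feature_paths <- function(node, set, prefix = integer(0)) {
  if (node$t == 1L) {
    if (node$feat %in% set) return(list(prefix)) else return(list())
  }
  if (node$t == 2L) return(list())
  out <- list()
  for (j in seq_along(node$kids)) {
    out <- c(out, collect_feature_paths(node$kids[[j]], set, c(prefix, j)))
  }
  out
}

get_subtree <- function(node, path) {
  for (j in path) node <- node$kids[[j]]
  node
}

set_subtree <- function(node, path, new) {
  if (length(path) == 0) return(new)
  node$kids[[path[1]]] <- set_subtree(node$kids[[path[1]]], path[-1], new)
  node
}
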