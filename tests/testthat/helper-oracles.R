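# Independent oracles and fixture builders shared across test files.

# Naive scalar recursive interpreter implementing the documented tree
# semantics: protected division (near-zero denominator or non-finite
# quotient -> 1), non-finite root value -> 0. Kept independent of the
# package's compiled evaluator.
naive_eval_node <- function(node, x) {
  if (node$t == 1L) return(unname(x[[node$feat]]))
  if (node$t == 2L) return(node$val)
  a <- naive_eval_node(node$kids[[1]], x)
  b <- naive_eval_node(node$kids[[2]], x)
  switch(node$op,
         "+" = a + b,
         "-" = a - b,
         "*" = a * b,
         "/" = if (abs(b) < 1e-9) 1 else {
           q <- a / b
           if (!is.finite(q)) 1 else q
         })
}

naive_eval_tree <- function(tree, x) {
  v <- naive_eval_node(tree$root, x)
  if (!is.finite(v)) 0 else v
}

# Brute-force exact two-tailed Mann-Whitney p by enumerating every rank
# split (assumes untied samples).
mw_enum <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  stopifnot(!anyDuplicated(c(a, b)))
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  splits <- utils::combn(n, na)
  us <- colSums(matrix(seq_len(n)[splits], nrow = na)) - na * (na + 1) / 2
  list(u = u_obs,
       p = min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs))))
}

# Tiny labelled table with explicit values (features in columns).
toy_table <- function(values, labels) {
  feature_table(as.matrix(values), labels)
}

# A population whose individuals have prescribed fitnesses (trees are
# distinct lone feature terminals; only the fitness matters to the caller).
fake_population <- function(fits, n_features = max(5, length(fits))) {
  feats <- paste0("f", seq_len(n_features))
  inds <- lapply(seq_along(fits), function(i) {
    tree <- gp_tree(list(t = 1L, ix = i, feat = feats[i]), feats)
    list(tree = tree, fitness = fits[i], key = deparse_tree(tree))
  })
  structure(list(individuals = inds, generation = 0L),
            class = "gp_population")
}

# Depths of all terminals (root = depth 1), for checking the full method.
leaf_depths <- function(node, depth = 1L) {
  if (node$t != 0L) return(depth)
  unlist(lapply(node$kids, leaf_depths, depth = depth + 1L))
}

# Independent feature-occurrence counter used to audit the weight ledger.
walk_count <- function(node, env) {
  if (node$t == 1L) {
    env$counts[node$feat] <- env$counts[node$feat] + 1L
    return(invisible(NULL))
  }
  if (node$t == 0L) for (k in node$kids) walk_count(k, env)
  invisible(NULL)
}

count_occurrences <- function(tree_text, features) {
  tree <- parse_tree(tree_text, features)
  env <- new.env()
  env$counts <- setNames(integer(length(features)), features)
  walk_count(tree$root, env)
  env$counts
}

# Perfectly separable single-informative-feature toy problem.
separable_table <- function(n = 30, seed = 1) {
  generate_synthetic(synthetic_spec(n_samples = n, n_channels = 1,
                                    n_bands = 1, n_informative = 1,
                                    effect_size = 20, seed = seed))
}
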