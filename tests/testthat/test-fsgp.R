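cfg <- fsgp_config(population_size = 20, init_min_depth = 2,
                   init_max_depth = 4, evaluation_budget = 2000)

test_that("above-average classifier selection uses a strict mean cutoff", {
  pop <- fake_population(c(0.5, 0.6, 0.7, 0.8))
  sel <- select_cgaa(pop)
  expect_equal(sort(vapply(sel, function(i) i$fitness, numeric(1))),
               c(0.7, 0.8))
  expect_length(select_cgaa(fake_population(rep(0.6, 4))), 0)
  sel2 <- select_cgaa(fake_population(c(0, 1)))
  expect_equal(vapply(sel2, function(i) i$fitness, numeric(1)), 1)
  expect_error(select_cgaa(fake_population(c(0.4, NA))),
               class = "fsgp_state_error")
})

test_that("weight accumulation counts terminal occurrences additively", {
  feats <- paste0("f", 1:5)
  mk <- function(txt) {
    tr <- parse_tree(txt, feats)
    list(tree = tr, fitness = 0.9, key = txt)
  }
  led <- new_ledger(feats)
  led1 <- accumulate_weights(led, list(mk("(+ f1 (* f1 f2))")))
  expect_equal(unname(led1$weights), c(2L, 1L, 0L, 0L, 0L))
  expect_equal(led1$generations_accumulated, 1L)

  # empty Cgaa list changes only the generation count
  led2 <- accumulate_weights(led1, list())
  expect_equal(led2$weights, led1$weights)
  expect_equal(led2$generations_accumulated, 2L)

  # additivity over trees
  led3 <- accumulate_weights(led, list(mk("f1"), mk("(- f1 f3)")))
  expect_equal(unname(led3$weights), c(2L, 0L, 1L, 0L, 0L))

  # per-tree presence counting caps each tree's contribution at 1
  led4 <- accumulate_weights(led, list(mk("(+ f1 (* f1 f2))")),
                             per_tree = TRUE)
  expect_equal(unname(led4$weights), c(1L, 1L, 0L, 0L, 0L))

  alien <- list(tree = gp_tree(list(t = 1L, ix = 1L, feat = "g1"), "g1"),
                fitness = 1, key = "g1")
  expect_error(accumulate_weights(led, list(alien)),
               class = "fsgp_schema_error")
})

test_that("feature partitioning splits on the strict mean-weight rule", {
  led <- new_ledger(c("f1", "f2", "f3"))
  led$generations_accumulated <- 1L

  led$weights[] <- c(5L, 1L, 0L)   # mean 2
  p <- partition_features(led)
  expect_equal(p$fso, "f1")
  expect_setequal(p$fno, c("f2", "f3"))

  led$weights[] <- c(3L, 3L, 3L)   # all equal: fall back to max weight
  p <- partition_features(led)
  expect_setequal(p$fso, c("f1", "f2", "f3"))
  expect_length(p$fno, 0)

  led$weights[] <- c(4L, 4L, 1L)   # mean 3
  p <- partition_features(led)
  expect_setequal(p$fso, c("f1", "f2"))

  # averaging over nonzero features raises the bar
  led$weights[] <- c(6L, 2L, 0L)   # mean over nonzero = 4
  expect_equal(partition_features(led, "nonzero")$fso, "f1")

  led$weights[] <- 0L
  expect_error(partition_features(led), class = "fsgp_degenerate_ledger")
  fresh <- new_ledger(c("f1"))
  expect_error(partition_features(fresh), class = "fsgp_state_error")
})

test_that("the replacement mutation purges every Fno terminal", {
  # fixed 6-row table: f_so1 separates perfectly, f_so2 gets 4/6,
  # f_no1 is anti-correlated
  vals <- cbind(f_no1 = c(-1, -2, -3, 1, 2, 3),
                f_so1 = c(1, 2, 3, -1, -2, -3),
                f_so2 = c(1, -1, 1, -1, 1, -1))
  tab <- toy_table(vals, c("positive", "positive", "positive",
                           "negative", "negative", "negative"))
  feats <- colnames(vals)
  part <- structure(list(fso = c("f_so1", "f_so2"), fno = "f_no1"),
                    class = "feature_partition")
  mk <- function(txt) {
    tr <- parse_tree(txt, feats)
    list(tree = tr, fitness = fitness(tr, tab, cfg), key = txt)
  }

  # no Fno terminal: identity
  ind <- mk("(+ f_so1 f_so2)")
  expect_identical(replace_fno(ind, part, cfg, tab), ind)

  # lone Fno terminal with a singleton Fso: forced single outcome
  part1 <- structure(list(fso = "f_so1", fno = "f_no1"),
                     class = "feature_partition")
  counter <- new_eval_counter()
  out <- replace_fno(mk("f_no1"), part1, cfg, tab, counter)
  expect_identical(out$key, "f_so1")
  expect_equal(out$fitness, 1)
  expect_equal(eval_count(counter), 1L)

  # two candidate replacements: enumerate both by direct evaluation and
  # check the operation lands on the strictly improving one when it exists,
  # else the better of the two
  parent <- mk("(+ f_no1 f_so1)")
  cand <- vapply(c("(+ f_so1 f_so1)", "(+ f_so2 f_so1)"),
                 function(s) fitness(parse_tree(s, feats), tab, cfg),
                 numeric(1))
  set.seed(11)
  out <- replace_fno(parent, part, cfg, tab)
  improving <- cand[cand > parent$fitness]
  if (length(improving)) {
    expect_true(out$fitness %in% improving)
  } else {
    expect_equal(out$fitness, max(cand))
  }
  # the purge holds regardless of fitness
  expect_equal(unname(feature_counts(out$tree)["f_no1"]), 0L)

  empty <- structure(list(fso = character(0), fno = feats),
                     class = "feature_partition")
  expect_error(replace_fno(parent, empty, cfg, tab),
               class = "fsgp_precondition_error")
})

test_that("the driver selects the informative feature on a separable toy", {
  ft <- standardize(separable_table(n = 30, seed = 1))
  hits <- 0L
  for (s in 1:3) {
    res <- run_fsgp(ft, fsgp_config(evaluation_budget = 20000, seed = s))
    if (res$terminated_early &&
        identical(res$selected_features, "AF3_theta")) hits <- hits + 1L
    expect_lt(res$total_evaluations, 20000)
    expect_equal(res$best$fitness, 1)
  }
  expect_gte(hits, 2L)
})

test_that("a full run keeps its books consistent", {
  ft <- standardize(generate_synthetic(synthetic_spec(n_samples = 60,
                                                      seed = 31)))
  res <- run_fsgp(ft, fsgp_config(evaluation_budget = 4000, seed = 3),
                  collect_cgaa = TRUE)

  # selected features are exactly the distinct features of the best tree
  expect_identical(res$selected_features, tree_features(res$best$tree))

  # after the replacement generation the best tree references only Fso
  if (!is.na(res$replacement_generation)) {
    expect_true(all(res$selected_features %in% res$partition$fso))
    post <- res$history[res$history$generation > res$replacement_generation, ]
    expect_true(all(post$fno_references == 0))
  }

  # ledger total equals an independent recount of the logged Cgaa trees
  feats <- colnames(ft$values)
  recount <- setNames(integer(length(feats)), feats)
  for (gen_keys in res$cgaa_log) {
    for (key in gen_keys) recount <- recount + count_occurrences(key, feats)
  }
  expect_equal(res$ledger$weights, recount)
  expect_equal(res$ledger$generations_accumulated, length(res$cgaa_log))

  # evaluation accounting: history's final count matches the total, and
  # the run stopped within one generation of the budget
  expect_equal(res$total_evaluations, max(res$history$evaluations))
  h <- res$history
  expect_lt(h$evaluations[nrow(h) - 1], 4000)
})

test_that("identical config and seed reproduce the run exactly", {
  ft <- standardize(generate_synthetic(synthetic_spec(n_samples = 40,
                                                      seed = 32)))
  cfg2 <- fsgp_config(evaluation_budget = 3000, seed = 17)
  a <- run_fsgp(ft, cfg2)
  b <- run_fsgp(ft, cfg2)
  expect_identical(a$best$key, b$best$key)
  expect_identical(a$history, b$history)
  expect_identical(a$selected_features, b$selected_features)
  expect_identical(a$total_evaluations, b$total_evaluations)
  expect_identical(a$ledger$weights, b$ledger$weights)
})

test_that("FSGP runs are monotone except possibly at the purge itself", {
  ft <- standardize(generate_synthetic(synthetic_spec(n_samples = 100,
                                                      effect_size = 1,
                                                      seed = 33)))
  for (s in 1:5) {
    res <- run_fsgp(ft, fsgp_config(evaluation_budget = 4000, seed = s))
    h <- res$history
    dips <- which(diff(h$best_fitness) < 0)
    expect_true(all(h$generation[dips + 1] == res$replacement_generation))
  }
})
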