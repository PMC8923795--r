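cfg <- fsgp_config(population_size = 20, init_min_depth = 2,
                   init_max_depth = 4, evaluation_budget = 1000)

test_that("fitness is training accuracy and charges the counter", {
  # 60% positive table; a constant-output-1 tree labels everything positive
  tab <- toy_table(matrix(rnorm(10), 10, 1, dimnames = list(NULL, "f1")),
                   c(rep("positive", 6), rep("negative", 4)))
  const1 <- parse_tree("1", "f1")
  counter <- new_eval_counter()
  expect_equal(fitness(const1, tab, cfg, counter), 0.6)
  expect_equal(eval_count(counter), 1L)

  # hand-enumerated 5-row toy: (- f1 f2) >= 0 iff f1 >= f2
  vals <- cbind(f1 = c(2, 1, 0, -1, 3), f2 = c(1, 2, 0, -3, 5))
  labs <- c("positive", "positive", "negative", "negative", "positive")
  # row-by-row: f1>=f2 -> predicted positive: rows 1,3,4; predictions
  # P,N,P,P,N vs labels P,P,N,N,P -> correct rows: 1 only? enumerate:
  # r1 2>=1 P==P ok; r2 1>=2 F -> N vs P wrong; r3 0>=0 P vs N wrong;
  # r4 -1>=-3 P vs N wrong; r5 3>=5 N vs P wrong -> 1/5
  tab2 <- toy_table(vals, labs)
  expect_equal(fitness(parse_tree("(- f1 f2)", c("f1", "f2")), tab2, cfg),
               1 / 5)

  # perfect classifier reaches the upper bound
  tab3 <- toy_table(cbind(f1 = c(1, 2, -1, -2)),
                    c("positive", "positive", "negative", "negative"))
  expect_equal(fitness(parse_tree("f1", "f1"), tab3, cfg), 1)

  empty <- toy_table(cbind(f1 = c(1, -1)), c("positive", "negative"))
  empty$values <- empty$values[0, , drop = FALSE]
  empty$labels <- empty$labels[0]
  expect_error(fitness(const1, empty, cfg), class = "fsgp_data_error")
})

test_that("initialization enforces structural diversity", {
  set.seed(10)
  pop <- init_population(cfg, paste0("f", 1:10))
  keys <- vapply(pop$individuals, function(i) i$key, character(1))
  expect_equal(length(unique(keys)), 20L)
  expect_true(all(is.na(vapply(pop$individuals, function(i) i$fitness,
                               numeric(1)))))

  # pigeonhole: depth-1 trees over one feature without constants admit a
  # single distinct tree
  cfg1 <- fsgp_config(population_size = 5, init_min_depth = 1,
                      init_max_depth = 1, constant_prob = 0,
                      evaluation_budget = 100, diversity_retries = 30)
  expect_error(init_population(cfg1, "f1"), class = "fsgp_diversity_error")
})

test_that("tournament selection picks the fittest of k with-replacement draws", {
  pop <- fake_population(c(0.2, 0.9, 0.5, 0.7))
  # the winner is always the max of its (with-replacement) sample, so the
  # result can only be an actual fitness, never less than a k=1 draw
  set.seed(1)
  picks <- replicate(500, tournament_select(pop, 4L)$fitness)
  expect_true(all(picks %in% c(0.2, 0.9, 0.5, 0.7)))
  # at k = n the best wins with probability 1 - (3/4)^4 ~ 0.684
  expect_gt(mean(picks == 0.9), 0.684 - 0.07)
  expect_lt(mean(picks == 0.9), 0.684 + 0.07)
  # k = 1 is a uniform draw: all individuals appear
  set.seed(2)
  seen <- replicate(200, tournament_select(pop, 1L)$fitness)
  expect_setequal(unique(seen), c(0.2, 0.9, 0.5, 0.7))

  # two-individual race: P(best wins | k=2, with replacement) = 3/4
  pop2 <- fake_population(c(0.9, 0.1))
  set.seed(3)
  wins <- sum(replicate(10000, tournament_select(pop2, 2L)$fitness) == 0.9)
  expect_gt(wins, 7500 - 150)
  expect_lt(wins, 7500 + 150)

  expect_error(tournament_select(pop, 0L), class = "fsgp_argument_error")
  unev <- fake_population(c(0.5, NA))
  expect_error(tournament_select(unev, 2L), class = "fsgp_state_error")
})

test_that("hill-climbing crossover admits only strictly fitter children", {
  # f1 separates perfectly, f2 is its negation
  tab <- toy_table(cbind(f1 = c(1, 2, -1, -2), f2 = c(-1, -2, 1, 2)),
                   c("positive", "positive", "negative", "negative"))
  feats <- c("f1", "f2")
  mk <- function(txt) {
    tr <- parse_tree(txt, feats)
    list(tree = tr, fitness = fitness(tr, tab, cfg), key = deparse_tree(tr))
  }
  perfect <- mk("f1"); bad <- mk("f2")
  expect_equal(perfect$fitness, 1)
  expect_equal(bad$fitness, 0)

  # both parents perfect: no child can strictly improve
  set.seed(4)
  out <- hc_crossover(perfect, perfect, cfg, tab)
  expect_identical(out[[1]]$key, "f1")
  expect_identical(out[[2]]$key, "f1")

  # zero retries returns the parents untouched and costs nothing
  cfg0 <- cfg; cfg0$hc_max_retries <- 0L
  counter <- new_eval_counter()
  out <- hc_crossover(bad, perfect, cfg0, tab, counter)
  expect_identical(out[[1]]$key, "f2")
  expect_equal(eval_count(counter), 0L)

  # single-node parents admit exactly one swap: bad's slot must become f1
  set.seed(5)
  out <- hc_crossover(bad, perfect, cfg, tab)
  expect_identical(out[[1]]$key, "f1")
  expect_equal(out[[1]]$fitness, 1)
  # perfect's slot cannot improve, so it stays
  expect_identical(out[[2]]$key, "f1")
})

test_that("hill-climbing mutation improves with the closed-form success rate", {
  tab <- toy_table(cbind(f1 = c(1, 2, -1, -2), f2 = c(-1, -2, 1, 2)),
                   c("positive", "positive", "negative", "negative"))
  feats <- c("f1", "f2")
  cfgm <- fsgp_config(population_size = 10, init_min_depth = 1,
                      init_max_depth = 1, constant_prob = 0,
                      evaluation_budget = 100, hc_max_retries = 1L)
  tr <- parse_tree("f2", feats)
  parent <- list(tree = tr, fitness = fitness(tr, tab, cfgm),
                 key = deparse_tree(tr))

  # parent at fitness 1.0 cannot improve
  perf <- parse_tree("f1", feats)
  pperf <- list(tree = perf, fitness = fitness(perf, tab, cfgm),
                key = "f1")
  set.seed(6)
  expect_identical(hc_mutation(pperf, cfgm, tab)$key, "f1")

  cfg0 <- cfgm; cfg0$hc_max_retries <- 0L
  expect_identical(hc_mutation(parent, cfg0, tab)$key, "f2")

  # one retry, depth-1 replacement over {f1, f2}: success iff f1 is drawn,
  # closed-form probability 1/2 per attempt
  set.seed(7)
  hits <- sum(replicate(1000, hc_mutation(parent, cfgm, tab)$key == "f1"))
  expect_gt(hits, 500 - 50)
  expect_lt(hits, 500 + 50)
})

test_that("next generation preserves size, elitism, and limit cases", {
  tab <- generate_synthetic(synthetic_spec(n_samples = 30, seed = 20))
  tabz <- standardize(tab)
  cfgn <- fsgp_config(population_size = 16, init_min_depth = 2,
                      init_max_depth = 4, evaluation_budget = 5000, seed = 2)
  set.seed(8)
  pop <- init_population(cfgn, colnames(tabz$values))
  pop$individuals <- lapply(pop$individuals, function(i) {
    i$fitness <- fitness(i$tree, tabz, cfgn); i
  })
  best0 <- max(vapply(pop$individuals, function(i) i$fitness, numeric(1)))
  for (g in 1:3) {
    pop <- next_generation(pop, cfgn, tabz)
    fits <- vapply(pop$individuals, function(i) i$fitness, numeric(1))
    expect_length(pop$individuals, 16L)
    expect_gte(max(fits), best0)
    best0 <- max(fits)
    expect_equal(pop$generation, g)
  }

  # pure reproduction with a full-size tournament: elitism keeps the best
  # and with-replacement tournaments copy it into most remaining slots
  cfgr <- cfgn
  cfgr$p_crossover <- 0; cfgr$p_mutation <- 0; cfgr$p_reproduction <- 1
  cfgr$tournament_size <- 16L
  set.seed(9)
  pop2 <- next_generation(pop, cfgr, tabz)
  fits2 <- vapply(pop2$individuals, function(i) i$fitness, numeric(1))
  expect_equal(max(fits2), best0)
  expect_gt(mean(fits2 == max(fits2)), 0.5)

  cfgbad <- cfgn
  cfgbad$p_crossover <- 0.9
  expect_error(next_generation(pop, cfgbad, tabz),
               class = "fsgp_config_error")
})

test_that("depth cap is respected across evolution", {
  tab <- standardize(generate_synthetic(synthetic_spec(n_samples = 30,
                                                       seed = 21)))
  cfgd <- fsgp_config(population_size = 20, init_min_depth = 3,
                      init_max_depth = 5, max_tree_depth = 6,
                      evaluation_budget = 2000, seed = 5)
  res <- run_fsgp(tab, cfgd)
  depths <- vapply(res$population$individuals,
                   function(i) tree_depth(i$tree), integer(1))
  expect_true(all(depths <= 6))
})
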