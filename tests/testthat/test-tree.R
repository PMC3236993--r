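test_that("strategy trees carry the published branch probabilities", {
  params <- baseline_params()
  key <- baseline_key()

  rec <- build_strategy_tree(params, key, "reconstruction")
  expect_true(validate_tree(rec)$ok)
  # collect every chance-node split present in the tree
  collect <- function(node) {
    if (node$kind == "terminal") return(NULL)
    c(list(vapply(node$children, `[[`, numeric(1), "prob")),
      unlist(lapply(node$children, function(ch) collect(ch$node)),
             recursive = FALSE))
  }
  splits <- collect(rec)
  has_split <- function(p) any(vapply(splits, function(s)
    length(s) == length(p) && all(abs(sort(s) - sort(p)) < 1e-12), logical(1)))
  expect_true(has_split(c(0.34, 0.66)))   # sequelae split
  expect_true(has_split(c(0.86, 0.14)))   # osteoarthritis/meniscus split
  expect_true(has_split(c(0.035, 0.965))) # failure split

  cons <- build_strategy_tree(params, key, "conservative")
  expect_true(validate_tree(cons)$ok)
  csplits <- collect(cons)
  expect_true(any(vapply(csplits, function(s)
    length(s) == 2 && min(abs(s - 0.16)) < 1e-12, logical(1))))
  # crossover branch carries one extra surgical cost (9926 USD)
  pp <- tree_paths(cons)
  cross <- pp[grepl("\\bcrossover", pp$path) & !grepl("no-crossover", pp$path), ]
  plain <- pp[grepl("no-crossover", pp$path), ]
  # the crossover subtree mirrors the no-crossover subtree shifted by 9926
  expect_equal(sort(unique(cross$cost)), sort(unique(plain$cost)) + 9926)
  expect_equal(sum(cross$prob), 0.16, tolerance = 1e-12)
})

test_that("collapsed tree degenerates to base cost and point utility", {
  pm_v <- activity_distribution(c(0, 0, 0, 0, 1))
  params <- model_params(
    p_fail = 0, p_crossover = 0, p_seq_operative = 0, p_seq_conservative = 0,
    split_oa_operative = 0.86, split_oa_conservative = 0.74,
    cost_surgical = 9926, cost_conservative = 2535,
    cost_oa = 17361, cost_meniscus = 6382,
    dist_operative = pm_v, dist_conservative = pm_v)
  key <- toy_key()
  r <- rollback(build_strategy_tree(params, key, "reconstruction"))
  expect_equal(r$expected_cost, 9926)
  expect_equal(r$expected_effect, key$mean[["V"]])
})

test_that("validate_tree reports violating nodes without raising", {
  bad <- chance_node(c(0.5, 0.4),
                     list(terminal_node(1, 0.5, "a"), terminal_node(2, 0.6, "b")),
                     label = "broken")
  rep <- validate_tree(bad)
  expect_false(rep$ok)
  expect_true("broken" %in% rep$violations$node)
  expect_error(rollback(bad), "invalid tree")

  nonfinite <- chance_node(1, list(terminal_node(Inf, 0.5, "leaf")), "root")
  expect_false(validate_tree(nonfinite)$ok)
})

test_that("rollback equals the exhaustive path-enumeration oracle", {
  expect_equal(rollback(terminal_node(123.4, 0.56))$expected_cost, 123.4)
  expect_equal(rollback(terminal_node(123.4, 0.56))$expected_effect, 0.56)

  set.seed(101)
  for (i in 1:100) {
    tr <- random_tree(max_depth = 5, max_children = 4)
    expect_true(validate_tree(tr)$ok)
    rb <- rollback(tr)
    or <- paths_expectation(tr)
    expect_equal(rb$expected_cost, or$expected_cost, tolerance = 1e-9)
    expect_equal(rb$expected_effect, or$expected_effect, tolerance = 1e-9)
  }
})

test_that("literal rollback (zero residuals) reproduces the hand computation", {
  params <- baseline_params(residual_cost_operative = 0,
                            residual_cost_conservative = 0)
  res <- evaluate_strategies(params, baseline_key())
  # 9926*1.035 + 0.34*(0.86*17361 + 0.14*6382)
  expect_equal(res$cost[res$strategy == "reconstruction"], 15653.5496,
               tolerance = 1e-9)
  # 2535 + 0.16*9926 + 0.77*(0.74*17361 + 0.26*6382)
  expect_equal(res$cost[res$strategy == "conservative"], 15293.1342,
               tolerance = 1e-9)
})

test_that("expected cost is monotone in cost parameters; adverse p=0 collapses", {
  key <- baseline_key()
  base <- baseline_params()
  res0 <- evaluate_strategies(base, key)
  for (field in c("cost_surgical", "cost_oa", "cost_meniscus")) {
    ov <- list(); ov[[field]] <- base[[field]] * 1.25
    res1 <- evaluate_strategies(do.call(baseline_params, ov), key)
    expect_true(all(res1$cost >= res0$cost - 1e-9))
  }

  # all adverse probabilities zero: base cost + residual, pooled utility
  quiet <- baseline_params(p_fail = 0, p_crossover = 0,
                           p_seq_operative = 0, p_seq_conservative = 0)
  res <- evaluate_strategies(quiet, key)
  expect_equal(res$cost[res$strategy == "reconstruction"],
               quiet$cost_surgical + quiet$residual_cost_operative)
  expect_equal(res$effect[res$strategy == "reconstruction"],
               expected_utility(quiet$dist_operative, key))
  expect_equal(res$effect[res$strategy == "conservative"],
               expected_utility(quiet$dist_conservative, key))
})

test_that("effect is non-increasing in sequelae probability when class II is poor", {
  key <- baseline_key()
  base <- baseline_params()
  e0 <- evaluate_strategies(base, key)
  e1 <- evaluate_strategies(baseline_params(p_seq_operative = 0.5), key)
  expect_lt(e1$effect[e1$strategy == "reconstruction"],
            e0$effect[e0$strategy == "reconstruction"])
})

test_that("trees survive a JSON round trip and render as text", {
  params <- baseline_params()
  tr <- build_strategy_tree(params, baseline_key(), "conservative")
  tr2 <- tree_from_json(tree_to_json(tr))
  expect_equal(rollback(tr2), rollback(tr), tolerance = 1e-12)
  txt <- format_tree(tr)
  expect_true(any(grepl("crossover", txt)))
})

test_that("model_params rejects invalid probabilities and costs", {
  d <- activity_distribution(rep(0.2, 5))
  expect_error(model_params(p_fail = 1.2, p_crossover = 0.1,
                            p_seq_operative = 0.3, p_seq_conservative = 0.7,
                            split_oa_operative = 0.8, split_oa_conservative = 0.7,
                            cost_surgical = 1, cost_conservative = 1,
                            cost_oa = 1, cost_meniscus = 1,
                            dist_operative = d, dist_conservative = d),
               "probabilities")
  expect_error(model_params(p_fail = 0.1, p_crossover = 0.1,
                            p_seq_operative = 0.3, p_seq_conservative = 0.7,
                            split_oa_operative = 0.8, split_oa_conservative = 0.7,
                            cost_surgical = -5, cost_conservative = 1,
                            cost_oa = 1, cost_meniscus = 1,
                            dist_operative = d, dist_conservative = d),
               "non-negative")
})
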