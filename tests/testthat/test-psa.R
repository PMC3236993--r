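test_that("utility sampling is deterministic, bounded and degenerate at sd 0", {
  key0 <- toy_key(sd = 0)
  spec0 <- psa_spec(key0, n_iterations = 10, seed = 4)
  k <- sample_utility_key(spec0, 3)
  expect_equal(k$mean[activity_classes()], key0$mean[activity_classes()])

  spec <- psa_spec(toy_key(sd = 0.2), n_iterations = 10, seed = 4)
  a <- sample_utility_key(spec, 5)
  b <- sample_utility_key(spec, 5)
  expect_identical(a$mean, b$mean)
  expect_false(identical(a$mean, sample_utility_key(spec, 6)$mean))
  for (i in 1:50) {
    d <- sample_utility_key(spec, i)$mean
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("sampled class means concentrate around the true mean", {
  key <- utility_key(c(0.2, 0.4, 0.6, 0.7, 0.8),
                     sd = c(0, 0, 0, 0, 0.05))
  spec <- psa_spec(key, n_iterations = 10000, seed = 12)
  draws <- vapply(1:10000, function(i) sample_utility_key(spec, i)$mean[["V"]],
                  numeric(1))
  expect_lt(abs(mean(draws) - 0.8), 3 * 0.05 / sqrt(10000))
})

test_that("zero-variance PSA degenerates to the deterministic result", {
  params <- baseline_params()
  key <- baseline_key()
  key$sd[] <- 0
  psa <- run_psa(params, psa_spec(key, n_iterations = 50, seed = 1))
  det <- evaluate_strategies(params, key)
  for (s in det$strategy) {
    e <- psa$draws$effect[psa$draws$strategy == s]
    expect_equal(unique(round(e, 12)), round(det$effect[det$strategy == s], 12))
    expect_equal(psa$summary$sd_effect[psa$summary$strategy == s], 0)
  }
})

test_that("the fast PSA path equals explicit rebuild-and-rollback per draw", {
  params <- baseline_params()
  spec <- psa_spec(baseline_key(), n_iterations = 12, seed = 77)
  psa <- run_psa(params, spec)
  for (i in c(1, 5, 12)) {
    k <- sample_utility_key(spec, i)
    for (s in c("conservative", "reconstruction")) {
      rb <- rollback(build_strategy_tree(params, k, s))
      row <- psa$draws[psa$draws$iteration == i & psa$draws$strategy == s, ]
      expect_equal(row$effect, rb$expected_effect, tolerance = 1e-12)
      expect_equal(row$cost, rb$expected_cost, tolerance = 1e-9)
    }
  }
})

test_that("PSA at scale is reproducible and consistent with the deterministic model", {
  params <- baseline_params()
  spec <- psa_spec(baseline_key(), n_iterations = 10000, seed = 42)
  psa <- run_psa(params, spec)
  expect_equal(nrow(psa$draws), 2 * 10000)

  # bit-identical summaries under the same seed
  psa2 <- run_psa(params, spec)
  expect_identical(psa$summary, psa2$summary)

  det <- evaluate_strategies(params, baseline_key())
  for (s in det$strategy) {
    m <- psa$summary[psa$summary$strategy == s, ]
    se <- m$sd_effect / sqrt(10000)
    expect_lt(abs(m$mean_effect - det$effect[det$strategy == s]), 3 * se)
  }
})

test_that("CEAC probabilities are bounded, complementary, and frontier behaves", {
  params <- baseline_params()
  psa <- run_psa(params, psa_spec(baseline_key(), n_iterations = 2000, seed = 8))
  grid <- seq(0, 100000, by = 5000)
  curve <- ceac(psa, grid)

  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  sums <- tapply(curve$probability, curve$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  frontier_count <- tapply(curve$frontier, curve$wtp, sum)
  expect_true(all(frontier_count == 1))

  # costs are not sampled: at WTP 0 the cheaper strategy wins every draw
  at0 <- curve[curve$wtp == 0, ]
  expect_equal(at0$probability[at0$strategy == "conservative"], 1)
  expect_true(at0$frontier[at0$strategy == "conservative"])

  # at WTP 10,000 reconstruction is the frontier strategy
  at10k <- curve[curve$wtp == 10000, ]
  expect_true(at10k$frontier[at10k$strategy == "reconstruction"])

  expect_error(ceac(psa, numeric(0)), "non-empty")
})

test_that("as sds shrink the CEAC approaches a step at the deterministic ICER", {
  params <- baseline_params()
  key <- baseline_key()
  icer <- incremental_table(evaluate_strategies(params, key))$icer[2]
  key$sd[] <- 1e-4
  psa <- run_psa(params, psa_spec(key, n_iterations = 500, seed = 3))
  curve <- ceac(psa, c(floor(icer) - 500, ceiling(icer) + 500))
  below <- curve[curve$wtp < icer & curve$strategy == "reconstruction", ]
  above <- curve[curve$wtp > icer & curve$strategy == "reconstruction", ]
  expect_equal(below$probability, 0)
  expect_equal(above$probability, 1)
})

test_that("scatter export has one row per iteration and strategy", {
  params <- baseline_params()
  psa <- run_psa(params, psa_spec(toy_key(sd = 0.1), n_iterations = 10, seed = 2))
  sc <- scatter_export(psa)
  expect_equal(nrow(sc), 20)
  expect_equal(sort(unique(sc$strategy)), c("conservative", "reconstruction"))

  set.seed(6)
  for (n in c(1, 7, 33)) {
    p <- run_psa(params, psa_spec(toy_key(sd = 0.05), n_iterations = n, seed = n))
    expect_equal(nrow(scatter_export(p)), 2 * n)
  }

  psa0 <- run_psa(params, psa_spec(toy_key(sd = 0), n_iterations = 5, seed = 1))
  sc0 <- scatter_export(psa0)
  expect_equal(nrow(unique(sc0[, c("strategy", "cost", "effect")])), 2)
})

test_that("default iteration count is 10,000", {
  expect_equal(psa_spec(toy_key())$n_iterations, 10000L)
  expect_equal(config_psa_spec(baseline_config())$n_iterations, 10000L)
})
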