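#' Specification of a probabilistic sensitivity analysis
#'
#' Utility means are resampled per iteration from independent normal
#' distributions (one per activity class, means and SDs from the utility
#' key), truncated to [0,1] by resampling. Costs and probabilities are not
#' sampled; the published analysis varies utility values only.
#'
#' @param key A [utility_key()] carrying per-class means and SDs.
#' @param n_iterations Number of Monte Carlo draws (default 10000).
#' @param seed Integer seed; with the iteration index it fully determines
#'   each draw.
#' @param truncation Bounds for utility draws.
#' @param max_resample Cap on the per-class rejection loop.
#' @return List of class `psa_spec`.
#' @export
psa_spec <- function(key, n_iterations = 10000L, seed = 1L,
                     truncation = c(0, 1), max_resample = 1000L) {
  stopifnot(inherits(key, "utility_key"))
  if (!is.finite(n_iterations) || n_iterations < 1)
    stop("n_iterations must be >= 1")
  if (length(truncation) != 2L || truncation[1] >= truncation[2])
    stop("truncation must be an increasing pair")
  structure(list(key = key, n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), truncation = truncation,
                 max_resample = as.integer(max_resample)),
            class = "psa_spec")
}

# deterministic per-iteration substream seed, kept inside 32-bit range
mix_seed <- function(seed, iteration) {
  (as.double(seed) * 48271 + as.double(iteration) * 9973) %% 2147483629
}

#' Draw one sampled utility key
#'
#' Each class utility is drawn from normal(mean, sd) and truncated to the
#' spec's bounds by resampling (rejection capped at `max_resample` tries).
#' Reproducible: the draw depends only on `(spec$seed, iteration)`. Sampled
#' keys are intentionally not forced monotone; classes are sampled
#' independently.
#'
#' @param spec A [psa_spec()].
#' @param iteration Iteration index (1-based).
#' @return A [utility_key()] (built with `check_monotone = FALSE`) with the
#'   sampled means and zero SDs.
#' @export
sample_utility_key <- function(spec, iteration) {
  stopifnot(inherits(spec, "psa_spec"))
  cls <- activity_classes()
  mu <- spec$key$mean[cls]
  sigma <- spec$key$sd[cls]
  set.seed(mix_seed(spec$seed, iteration))
  lo <- spec$truncation[1]; hi <- spec$truncation[2]
  draw <- stats::rnorm(5, mu, sigma)
  for (i in seq_along(draw)) {
    tries <- 0L
    while (draw[i] < lo || draw[i] > hi) {
      tries <- tries + 1L
      if (tries > spec$max_resample)
        stop("truncation resampling cap exceeded for class ", cls[i])
      draw[i] <- stats::rnorm(1, mu[i], sigma[i])
    }
  }
  utility_key(stats::setNames(draw, cls), check_monotone = FALSE)
}

#' Run the Monte Carlo probabilistic sensitivity analysis
#'
#' For each iteration the terminal effects of both strategy trees are
#' rebuilt from the sampled utility key and rolled back. Because the
#' rollback effect is linear in the class utilities, the per-iteration
#' rollback is carried out through the tree-derived per-class effect
#' weights ([effect_weights()]); tests verify this equals an explicit
#' rebuild-and-rollback per draw. Costs do not vary (utilities only are
#' sampled).
#'
#' @param params A [model_params()].
#' @param spec A [psa_spec()].
#' @return List of class `psa_result`: `draws` (data frame `iteration`,
#'   `strategy`, `cost`, `effect`), `summary` (per strategy: mean cost,
#'   mean/sd effect, mean/sd cost-effectiveness ratio), `deterministic`
#'   (the no-noise [evaluate_strategies()] result), `seed`, `n_iterations`.
#' @export
run_psa <- function(params, spec) {
  stopifnot(inherits(params, "model_params"), inherits(spec, "psa_spec"))
  strategies <- c("conservative", "reconstruction")
  w <- sapply(strategies, function(s) effect_weights(params, s))
  det <- evaluate_strategies(params, spec$key)
  costs <- stats::setNames(det$cost, det$strategy)[strategies]

  draws_u <- t(vapply(seq_len(spec$n_iterations),
                      function(i) sample_utility_key(spec, i)$mean[activity_classes()],
                      numeric(5)))
  effects <- draws_u %*% w    # n_iterations x 2, columns follow `strategies`

  draws <- data.frame(
    iteration = rep(seq_len(spec$n_iterations), times = length(strategies)),
    strategy = rep(strategies, each = spec$n_iterations),
    cost = rep(costs, each = spec$n_iterations),
    effect = as.vector(effects),
    stringsAsFactors = FALSE)

  summary <- do.call(rbind, lapply(strategies, function(s) {
    e <- effects[, s]
    ce <- costs[[s]] / e
    data.frame(strategy = s, mean_cost = costs[[s]],
               mean_effect = mean(e), sd_effect = stats::sd(e),
               mean_ce_ratio = mean(ce), sd_ce_ratio = stats::sd(ce),
               stringsAsFactors = FALSE)
  }))

  structure(list(draws = draws, summary = summary, deterministic = det,
                 seed = spec$seed, n_iterations = spec$n_iterations),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (seed %d)\n", x$n_iterations, x$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Cost-effectiveness acceptability curve and frontier
#'
#' For each willingness-to-pay value, the probability that each strategy has
#' the maximal net monetary benefit across the PSA draws (ties broken toward
#' the less costly strategy), and the frontier strategy: the one with
#' maximal expected NMB, reported with its own acceptability probability.
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Non-empty vector of non-negative WTP values; default
#'   0 to 100,000 USD/QALY in steps of 1,000.
#' @return Data frame with columns `wtp`, `strategy`, `probability`,
#'   `frontier` (logical: frontier strategy at that WTP).
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 1000)) {
  stopifnot(inherits(psa, "psa_result"))
  if (length(wtp_grid) == 0L || any(!is.finite(wtp_grid)) || any(wtp_grid < 0))
    stop("wtp_grid must be non-empty and non-negative")
  strategies <- unique(psa$draws$strategy)
  eff <- sapply(strategies, function(s)
    psa$draws$effect[psa$draws$strategy == s])
  cost <- vapply(strategies, function(s)
    psa$draws$cost[psa$draws$strategy == s][1], numeric(1))
  # tie-break toward the cheaper strategy: order columns by ascending cost
  # and let max.col pick the first maximum
  ord <- order(cost, strategies)
  eff <- eff[, ord, drop = FALSE]; cost <- cost[ord]; strategies <- strategies[ord]

  rows <- lapply(wtp_grid, function(l) {
    nmb <- sweep(l * eff, 2, cost)             # draws x strategies
    win <- max.col(nmb, ties.method = "first")
    prob <- vapply(seq_along(strategies), function(j) mean(win == j), numeric(1))
    mean_nmb <- colMeans(nmb)
    best <- which(mean_nmb == max(mean_nmb))[1]
    data.frame(wtp = l, strategy = strategies, probability = prob,
               frontier = seq_along(strategies) == best,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export the cost-effectiveness plane scatter
#'
#' One row per (iteration, strategy) with its cost and effect, suitable for
#' plotting every Monte Carlo run on the cost-effectiveness plane.
#'
#' @param psa A [run_psa()] result.
#' @return Data frame with columns `iteration`, `strategy`, `cost`, `effect`.
#' @export
scatter_export <- function(psa) {
  stopifnot(inherits(psa, "psa_result"))
  psa$draws[, c("iteration", "strategy", "cost", "effect")]
}
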