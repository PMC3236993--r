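#' Incremental cost-effectiveness table
#'
#' Standard incremental analysis over two or more strategies: sort by
#' ascending cost, drop strictly dominated strategies (another strategy
#' costs less and is at least as effective), prune extended dominance
#' (a strategy whose ICER against the previous frontier member exceeds the
#' next member's ICER is removed, restoring a monotone ICER chain), then
#' report successive incremental cost, incremental effect and their ratio.
#' All internals are unrounded; rounding is a formatting concern.
#'
#' @param results Data frame with columns `strategy`, `cost`, `effect`
#'   (see [evaluate_strategies()]); at least two strategies, effects > 0.
#' @return Data frame with columns `strategy`, `cost`, `incr_cost`,
#'   `effect`, `incr_effect`, `ce_ratio`, `icer`, `status` (one of
#'   `reference`, `frontier`, `dominated`, `ext_dominated`). `icer` is `NA`
#'   for the reference row, for excluded rows, and when the incremental
#'   effect is zero (undefined, flagged in `status` as `frontier`).
#' @export
incremental_table <- function(results) {
  needed <- c("strategy", "cost", "effect")
  if (!all(needed %in% names(results)))
    stop("results must have columns strategy, cost, effect")
  if (nrow(results) < 2L) stop("need at least two strategies")
  if (any(!is.finite(results$cost)) || any(!is.finite(results$effect)) ||
      any(results$effect <= 0))
    stop("costs must be finite and effects positive")

  # deterministic order: ascending cost, then descending effect, then name
  ord <- order(results$cost, -results$effect, results$strategy)
  res <- results[ord, needed, drop = FALSE]

  status <- rep("frontier", nrow(res))
  for (i in seq_len(nrow(res)))
    for (j in seq_len(nrow(res)))
      if (j != i && res$cost[j] < res$cost[i] && res$effect[j] >= res$effect[i])
        status[i] <- "dominated"

  # extended dominance: enforce increasing ICERs along the frontier chain
  repeat {
    chain <- which(status == "frontier")
    if (length(chain) < 3L) break
    icers <- diff(res$cost[chain]) / diff(res$effect[chain])
    bad <- which(diff(icers) < 0)
    if (!length(bad)) break
    status[chain[bad[1] + 1L]] <- "ext_dominated"
  }

  chain <- which(status == "frontier")
  out <- data.frame(strategy = res$strategy, cost = res$cost,
                    incr_cost = NA_real_, effect = res$effect,
                    incr_effect = NA_real_,
                    ce_ratio = res$cost / res$effect,
                    icer = NA_real_, status = status,
                    stringsAsFactors = FALSE)
  if (length(chain)) {
    out$status[chain[1]] <- "reference"
    if (length(chain) > 1L) {
      for (k in 2:length(chain)) {
        i <- chain[k]; p <- chain[k - 1L]
        out$incr_cost[i] <- out$cost[i] - out$cost[p]
        out$incr_effect[i] <- out$effect[i] - out$effect[p]
        out$icer[i] <- if (out$incr_effect[i] == 0) NA_real_
                       else out$incr_cost[i] / out$incr_effect[i]
      }
    }
  }
  out
}

#' Net monetary benefit
#'
#' NMB = WTP * effect - cost; at a given willingness to pay the strategy
#' with the larger NMB is preferred.
#'
#' @param results Data frame with columns `strategy`, `cost`, `effect`.
#' @param wtp Willingness to pay, USD per QALY (non-negative scalar).
#' @return Data frame with columns `strategy`, `wtp`, `nmb`.
#' @export
net_monetary_benefit <- function(results, wtp) {
  if (!is.finite(wtp) || wtp < 0) stop("wtp must be non-negative")
  data.frame(strategy = results$strategy, wtp = wtp,
             nmb = wtp * results$effect - results$cost,
             stringsAsFactors = FALSE)
}

#' Worst-case scenario: no sequelae
#'
#' Re-runs both strategies with the sequelae probabilities forced to zero
#' (crossover, failure, costs and residual calibration unchanged) and
#' returns the incremental table. Ignoring late osteoarthritis and meniscal
#' lesions removes most of the effect difference between the arms and
#' inflates the ICER by an order of magnitude.
#'
#' @param params A [model_params()].
#' @param key A [utility_key()].
#' @return An [incremental_table()] data frame.
#' @export
worst_case_no_sequelae <- function(params, key) {
  wc <- params
  wc$p_seq_operative <- 0
  wc$p_seq_conservative <- 0
  incremental_table(evaluate_strategies(wc, key))
}

#' Format an incremental table as text
#'
#' @param tab Output of [incremental_table()].
#' @return Character vector of fixed-width lines (costs rounded to whole
#'   USD, effects to 2 decimals, matching the published presentation).
#' @export
format_cea_table <- function(tab) {
  fm <- function(x, d = 0) ifelse(is.na(x), "", formatC(x, format = "f", digits = d))
  body <- sprintf("%-16s %8s %10s %7s %8s %10s %10s %-13s",
                  tab$strategy, fm(tab$cost), fm(tab$incr_cost),
                  fm(tab$effect, 2), fm(tab$incr_effect, 2),
                  fm(tab$ce_ratio), fm(tab$icer), tab$status)
  header <- sprintf("%-16s %8s %10s %7s %8s %10s %10s %-13s",
                    "strategy", "cost", "incr_cost", "effect", "incr_eff",
                    "CE ratio", "ICER", "status")
  c(header, body)
}
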