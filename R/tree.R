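#' Model parameters for the two-strategy decision tree
#'
#' All branch probabilities, arm and complication costs, per-arm residual
#' calibration constants, arm activity distributions and the time horizon.
#' Baseline values (supplied by the shipped config): 3.5% reconstruction
#' failure, 16% conservative-to-surgery crossover, sequelae probabilities
#' 34% (operative) and 77% (conservative) split 86/14 and 74/26 between
#' osteoarthritis and meniscal lesions, sequelae patients in class II,
#' 90-month horizon.
#'
#' @param p_fail Probability that reconstruction fails and is redone once.
#' @param p_crossover Probability that a conservatively treated patient
#'   crosses over to surgical reconstruction (cost only).
#' @param p_seq_operative,p_seq_conservative Sequelae probabilities per arm.
#' @param split_oa_operative,split_oa_conservative Osteoarthritis share of
#'   sequelae per arm (remainder is meniscal lesion).
#' @param cost_surgical,cost_conservative Arm base costs, USD.
#' @param cost_oa,cost_meniscus Total complication costs (inpatient +
#'   perioperative), USD.
#' @param residual_cost_operative,residual_cost_conservative Additive
#'   per-arm calibration constants, USD; absorb unpublished micro-structure
#'   of the original model. Set to 0 for a literal rollback.
#' @param dist_operative,dist_conservative Arm activity distributions
#'   ([activity_distribution()]).
#' @param sequelae_class Activity class assigned to sequelae patients.
#' @param horizon_months Model horizon (months); descriptive, no discounting.
#' @return List of class `model_params`.
#' @export
model_params <- function(p_fail, p_crossover,
                         p_seq_operative, p_seq_conservative,
                         split_oa_operative, split_oa_conservative,
                         cost_surgical, cost_conservative,
                         cost_oa, cost_meniscus,
                         residual_cost_operative = 0,
                         residual_cost_conservative = 0,
                         dist_operative, dist_conservative,
                         sequelae_class = "II", horizon_months = 90) {
  probs <- c(p_fail = p_fail, p_crossover = p_crossover,
             p_seq_operative = p_seq_operative,
             p_seq_conservative = p_seq_conservative,
             split_oa_operative = split_oa_operative,
             split_oa_conservative = split_oa_conservative)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0,1]")
  costs <- c(cost_surgical = cost_surgical,
             cost_conservative = cost_conservative,
             cost_oa = cost_oa, cost_meniscus = cost_meniscus,
             residual_cost_operative = residual_cost_operative,
             residual_cost_conservative = residual_cost_conservative)
  if (any(!is.finite(costs)) || any(costs < 0))
    stop("all costs must be finite and non-negative")
  stopifnot(inherits(dist_operative, "activity_distribution"),
            inherits(dist_conservative, "activity_distribution"))
  sequelae_class <- match.arg(sequelae_class, activity_classes())
  if (!is.finite(horizon_months) || horizon_months <= 0)
    stop("horizon must be positive")
  structure(list(
    p_fail = p_fail, p_crossover = p_crossover,
    p_seq_operative = p_seq_operative, p_seq_conservative = p_seq_conservative,
    split_oa_operative = split_oa_operative,
    split_oa_conservative = split_oa_conservative,
    cost_surgical = cost_surgical, cost_conservative = cost_conservative,
    cost_oa = cost_oa, cost_meniscus = cost_meniscus,
    residual_cost_operative = residual_cost_operative,
    residual_cost_conservative = residual_cost_conservative,
    dist_operative = dist_operative, dist_conservative = dist_conservative,
    sequelae_class = sequelae_class, horizon_months = horizon_months
  ), class = "model_params")
}

#' Terminal (leaf) node of a decision tree
#'
#' @param cost Accumulated path cost, USD.
#' @param effect Terminal utility.
#' @param label Node label.
#' @return List of class `tree_node`.
#' @export
terminal_node <- function(cost, effect, label = "") {
  structure(list(kind = "terminal", cost = cost, effect = effect,
                 label = label), class = "tree_node")
}

#' Chance node of a decision tree
#'
#' @param probs Numeric vector of branch probabilities.
#' @param nodes List of child `tree_node`s, same length as `probs`.
#' @param label Node label.
#' @return List of class `tree_node`.
#' @export
chance_node <- function(probs, nodes, label = "") {
  stopifnot(length(probs) == length(nodes))
  structure(list(kind = "chance",
                 children = Map(function(p, n) list(prob = p, node = n),
                                probs, nodes),
                 label = label), class = "tree_node")
}

# leaves for one activity class fan-out: one terminal per class, weighted
# by dist, each carrying the same accumulated cost
class_fanout <- function(dist, key, cost, label) {
  cls <- activity_classes()
  chance_node(unclass(dist)[cls],
              lapply(cls, function(cl)
                terminal_node(cost, key$mean[[cl]], paste0(label, "/", cl))),
              label)
}

#' Build one strategy's decision tree
#'
#' Reconstruction arm: base cost (surgical + residual); sequelae (probability
#' `p_seq_operative`, split between osteoarthritis and meniscus, patient ends
#' in the sequelae class) and reconstruction failure (probability `p_fail`,
#' one extra surgical cost, activity shifted one class down) are modelled as
#' independent events. Conservative arm: base cost (conservative + residual);
#' crossover (probability `p_crossover`) adds one surgical cost but keeps the
#' conservative activity distribution; sequelae as above with the
#' conservative split.
#'
#' @param params A [model_params()].
#' @param key A [utility_key()].
#' @param strategy `"reconstruction"` or `"conservative"`.
#' @return Root `tree_node`; always passes [validate_tree()].
#' @export
build_strategy_tree <- function(params, key, strategy = c("reconstruction", "conservative")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(params, "model_params"), inherits(key, "utility_key"))
  u_seq <- key$mean[[params$sequelae_class]]

  if (strategy == "reconstruction") {
    base <- params$cost_surgical + params$residual_cost_operative
    seq_branch <- function(extra, tag) {
      # sequelae: effect pinned at the sequelae class whatever happened before
      chance_node(
        c(params$split_oa_operative, 1 - params$split_oa_operative),
        list(terminal_node(base + extra + params$cost_oa, u_seq,
                           paste0(tag, "/osteoarthritis")),
             terminal_node(base + extra + params$cost_meniscus, u_seq,
                           paste0(tag, "/meniscus"))),
        paste0(tag, "/sequelae"))
    }
    fail_node <- chance_node(
      c(params$p_seq_operative, 1 - params$p_seq_operative),
      list(seq_branch(params$cost_surgical, "fail"),
           class_fanout(shifted_distribution(params$dist_operative), key,
                        base + params$cost_surgical, "fail/no-sequelae")),
      "fail")
    ok_node <- chance_node(
      c(params$p_seq_operative, 1 - params$p_seq_operative),
      list(seq_branch(0, "no-fail"),
           class_fanout(params$dist_operative, key, base, "no-fail/no-sequelae")),
      "no-fail")
    chance_node(c(params$p_fail, 1 - params$p_fail),
                list(fail_node, ok_node), "reconstruction")
  } else {
    base <- params$cost_conservative + params$residual_cost_conservative
    cons_branch <- function(extra, tag) {
      seq_node <- chance_node(
        c(params$split_oa_conservative, 1 - params$split_oa_conservative),
        list(terminal_node(base + extra + params$cost_oa, u_seq,
                           paste0(tag, "/osteoarthritis")),
             terminal_node(base + extra + params$cost_meniscus, u_seq,
                           paste0(tag, "/meniscus"))),
        paste0(tag, "/sequelae"))
      chance_node(
        c(params$p_seq_conservative, 1 - params$p_seq_conservative),
        list(seq_node,
             class_fanout(params$dist_conservative, key, base + extra,
                          paste0(tag, "/no-sequelae"))),
        tag)
    }
    chance_node(c(params$p_crossover, 1 - params$p_crossover),
                list(cons_branch(params$cost_surgical, "crossover"),
                     cons_branch(0, "no-crossover")),
                "conservative")
  }
}

#' Validate a decision tree
#'
#' Checks, at every chance node, that branch probabilities lie in [0,1] and
#' sum to 1 within `1e-9`, and that terminal payoffs are finite. Returns a
#' structured report instead of raising on model content.
#'
#' @param tree A `tree_node`.
#' @param tol Probability-sum tolerance.
#' @return List with `ok` (logical) and `violations` (data frame with
#'   columns `node`, `problem`), one row per violating node.
#' @export
validate_tree <- function(tree, tol = 1e-9) {
  violations <- list()
  note <- function(label, problem)
    violations[[length(violations) + 1L]] <<- data.frame(
      node = label, problem = problem, stringsAsFactors = FALSE)
  walk <- function(node) {
    if (!inherits(node, "tree_node")) { note("<unknown>", "not a tree_node"); return() }
    if (node$kind == "terminal") {
      if (!is.finite(node$cost) || !is.finite(node$effect))
        note(node$label, "non-finite terminal payoff")
    } else {
      p <- vapply(node$children, `[[`, numeric(1), "prob")
      if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        note(node$label, "branch probability outside [0,1]")
      else if (abs(sum(p) - 1) > tol)
        note(node$label, sprintf("branch probabilities sum to %.12f", sum(p)))
      for (ch in node$children) walk(ch$node)
    }
  }
  walk(tree)
  viol <- if (length(violations)) do.call(rbind, violations)
          else data.frame(node = character(), problem = character(),
                          stringsAsFactors = FALSE)
  list(ok = nrow(viol) == 0L, violations = viol)
}

#' Expected-value rollback of a decision tree
#'
#' Bottom-up expectation of (accumulated cost, terminal effect) over all
#' root-to-leaf paths. Children are evaluated in declaration order for
#' bit-reproducibility.
#'
#' @param tree A `tree_node` that passes [validate_tree()].
#' @return List with `expected_cost` (USD) and `expected_effect` (utility).
#' @export
rollback <- function(tree) {
  chk <- validate_tree(tree)
  if (!chk$ok)
    stop("invalid tree: ", paste(unique(chk$violations$problem), collapse = "; "))
  roll <- function(node) {
    if (node$kind == "terminal") return(c(node$cost, node$effect))
    acc <- c(0, 0)
    for (ch in node$children) acc <- acc + ch$prob * roll(ch$node)
    acc
  }
  v <- roll(tree)
  list(expected_cost = v[1], expected_effect = v[2])
}

#' Enumerate all root-to-leaf paths of a tree
#'
#' Exhaustive path enumeration, kept deliberately independent of
#' [rollback()] so the two can cross-check each other: the probability-
#' weighted sum of path payoffs must equal the rollback expectation.
#'
#' @param tree A `tree_node`.
#' @return Data frame with one row per path: `prob`, `cost`, `effect`,
#'   `path` (slash-joined labels).
#' @export
tree_paths <- function(tree) {
  out <- list()
  descend <- function(node, prob, trail) {
    if (node$kind == "terminal") {
      out[[length(out) + 1L]] <<- data.frame(
        prob = prob, cost = node$cost, effect = node$effect,
        path = paste(c(trail, node$label), collapse = "|"),
        stringsAsFactors = FALSE)
    } else {
      for (ch in node$children)
        descend(ch$node, prob * ch$prob, c(trail, node$label))
    }
  }
  descend(tree, 1, character())
  do.call(rbind, out)
}

#' Per-class effect weights of a strategy tree
#'
#' The rollback expected effect is linear in the utility key's class means:
#' effect = sum_c w_c * u_c. The weights are obtained by rolling back the
#' strategy tree under each indicator key (u = basis vector), so they come
#' from the same tree the model uses. They power the calibration and the
#' fast PSA path.
#'
#' @param params A [model_params()].
#' @param strategy `"reconstruction"` or `"conservative"`.
#' @return Named numeric vector of weights over classes I-V (sums to 1).
#' @export
effect_weights <- function(params, strategy) {
  cls <- activity_classes()
  vapply(cls, function(cl) {
    basis <- utility_key(stats::setNames(as.numeric(cls == cl), cls),
                         check_monotone = FALSE)
    rollback(build_strategy_tree(params, basis, strategy))$expected_effect
  }, numeric(1))
}

#' Evaluate both strategies deterministically
#'
#' @param params A [model_params()].
#' @param key A [utility_key()].
#' @return Data frame with columns `strategy`, `cost`, `effect`
#'   (one row per strategy).
#' @export
evaluate_strategies <- function(params, key) {
  rows <- lapply(c("conservative", "reconstruction"), function(s) {
    r <- rollback(build_strategy_tree(params, key, s))
    data.frame(strategy = s, cost = r$expected_cost,
               effect = r$expected_effect, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Render a tree as indented text
#'
#' @param tree A `tree_node`.
#' @param digits Digits for probabilities and payoffs.
#' @return Character vector of lines, invisibly printed with `cat`-friendly
#'   newlines by `print`.
#' @export
format_tree <- function(tree, digits = 4) {
  lines <- character()
  walk <- function(node, prob, depth) {
    pad <- strrep("  ", depth)
    head <- if (is.na(prob)) "" else sprintf("[p=%.*f] ", digits, prob)
    if (node$kind == "terminal") {
      lines <<- c(lines, sprintf("%s%s%s  (cost=%.2f, effect=%.*f)",
                                 pad, head, node$label, node$cost, digits,
                                 node$effect))
    } else {
      lines <<- c(lines, sprintf("%s%s%s", pad, head, node$label))
      for (ch in node$children) walk(ch$node, ch$prob, depth + 1L)
    }
  }
  walk(tree, NA_real_, 0L)
  lines
}

#' Serialize a tree to JSON
#'
#' @param tree A `tree_node`.
#' @return JSON string.
#' @export
tree_to_json <- function(tree) {
  strip <- function(node) {
    if (node$kind == "terminal")
      list(kind = "terminal", cost = node$cost, effect = node$effect,
           label = node$label)
    else
      list(kind = "chance", label = node$label,
           children = lapply(node$children, function(ch)
             list(prob = ch$prob, node = strip(ch$node))))
  }
  jsonlite::toJSON(strip(tree), auto_unbox = TRUE, digits = NA)
}

#' Deserialize a tree from JSON
#'
#' @param json JSON string produced by [tree_to_json()].
#' @return A `tree_node`.
#' @export
tree_from_json <- function(json) {
  build <- function(x) {
    if (identical(x$kind, "terminal"))
      terminal_node(x$cost, x$effect, x$label)
    else
      chance_node(vapply(x$children, `[[`, numeric(1), "prob"),
                  lapply(x$children, function(ch) build(ch$node)),
                  x$label)
  }
  build(jsonlite::fromJSON(json, simplifyVector = FALSE))
}
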