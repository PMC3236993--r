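# shared fixtures, built in code

table1_records <- function() {
  read_activity_records(system.file("extdata", "table1_activity.csv",
                                    package = "aclcea"))
}

table2_items <- function() {
  read_resource_items(system.file("extdata", "table2_costs.csv",
                                  package = "aclcea"))
}

baseline_params <- function(...) {
  config_model_params(baseline_config(), overrides = list(...))
}

baseline_key <- function() config_utility_key(baseline_config())

# simple monotone key for unit tests
toy_key <- function(sd = 0)
  utility_key(c(I = 0.3, II = 0.5, III = 0.7, IV = 0.85, V = 0.95), sd = sd)

random_distribution <- function() {
  p <- stats::runif(5)
  activity_distribution(p / sum(p))
}

# random valid tree: chance nodes with <= max_children, depth <= max_depth
random_tree <- function(max_depth = 5, max_children = 4, depth = 0) {
  if (depth >= max_depth || stats::runif(1) < 0.35) {
    return(terminal_node(stats::runif(1, 0, 20000), stats::runif(1),
                         sprintf("leaf_d%d", depth)))
  }
  k <- sample(2:max_children, 1)
  p <- stats::runif(k)
  p <- p / sum(p)
  chance_node(p, lapply(seq_len(k), function(i)
    random_tree(max_depth, max_children, depth + 1)),
    sprintf("chance_d%d", depth))
}

# independent expectation oracle over enumerated paths (not rollback)
paths_expectation <- function(tree) {
  pp <- tree_paths(tree)
  list(expected_cost = sum(pp$prob * pp$cost),
       expected_effect = sum(pp$prob * pp$effect))
}
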