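#' Construct a utility transformation key
#'
#' Maps Gottlob activity classes to health-state utilities on [0,1], as
#' elicited from an expert survey. Mean utilities must be non-decreasing
#' from class I to class V (higher activity is a better state; classes 0 and
#' V anchor the floor and ceiling of the scale). An optional class "0" entry
#' below class I is accepted.
#'
#' @param mean Named numeric vector of per-class mean utilities. Names must
#'   be `I..V`, optionally preceded by `"0"`.
#' @param sd Per-class standard deviations (scalar recycled, or named like
#'   `mean`). Used by the probabilistic sensitivity analysis.
#' @param check_monotone Enforce non-decreasing means (default `TRUE`).
#'   Sampled keys inside the PSA are drawn independently per class and may
#'   legitimately violate monotonicity; they are built with `FALSE`.
#' @return List of class `utility_key` with elements `mean` and `sd`.
#' @export
utility_key <- function(mean, sd = 0, check_monotone = TRUE) {
  cls <- activity_classes()
  if (is.null(names(mean))) names(mean) <- cls
  allowed <- c("0", cls)
  if (!all(names(mean) %in% allowed) || !all(cls %in% names(mean)))
    stop("utility key must name classes I..V (class 0 optional)")
  mean <- mean[allowed[allowed %in% names(mean)]]
  if (any(!is.finite(mean)) || any(mean < 0) || any(mean > 1))
    stop("mean utilities must lie in [0,1]")
  if (check_monotone && is.unsorted(mean))
    stop("mean utilities must be non-decreasing from lowest to highest class")
  if (length(sd) == 1L) sd <- rep(sd, length(mean))
  if (is.null(names(sd))) {
    if (length(sd) != length(mean))
      stop("sd must be scalar or match mean in length")
    names(sd) <- names(mean)
  }
  sd <- sd[names(mean)]
  if (any(!is.finite(sd)) || any(sd < 0))
    stop("sd utilities must be non-negative")
  structure(list(mean = mean, sd = sd), class = "utility_key")
}

#' @export
print.utility_key <- function(x, digits = 4, ...) {
  cat("Utility transformation key:\n")
  print(round(rbind(mean = x$mean, sd = x$sd), digits))
  invisible(x)
}

#' Shift an activity class one level down
#'
#' After a failed reconstruction the patient is assumed one activity class
#' lower than before; patients already in class I remain in class I.
#'
#' @param cls Character vector of class labels in `I..V`.
#' @return Shifted class labels.
#' @export
shift_class_down <- function(cls) {
  lv <- activity_classes()
  idx <- match(cls, lv)
  if (anyNA(idx)) stop("class outside I..V: ", paste(cls[is.na(idx)], collapse = ", "))
  lv[pmax(idx - 1L, 1L)]
}

#' Apply the one-class-down shift to a whole distribution
#'
#' Probability mass moves one class down; class I mass stays put, so classes
#' I and II both map onto I.
#'
#' @param dist An [activity_distribution()].
#' @return Shifted [activity_distribution()].
#' @export
shifted_distribution <- function(dist) {
  stopifnot(inherits(dist, "activity_distribution"))
  lv <- activity_classes()
  out <- stats::setNames(numeric(5), lv)
  tgt <- shift_class_down(lv)
  for (i in seq_along(lv)) out[tgt[i]] <- out[tgt[i]] + dist[[lv[i]]]
  activity_distribution(out)
}

#' Expected utility of an activity distribution under a key
#'
#' @param dist An [activity_distribution()].
#' @param key A [utility_key()].
#' @return `sum(dist[c] * key$mean[c])` over classes I-V.
#' @export
expected_utility <- function(dist, key) {
  stopifnot(inherits(dist, "activity_distribution"), inherits(key, "utility_key"))
  cls <- activity_classes()
  if (!all(cls %in% names(key$mean)))
    stop("utility key is missing classes present in the distribution")
  sum(unclass(dist)[cls] * key$mean[cls])
}

#' Arm-level effect targets for calibration
#'
#' The published per-arm expected effects (utility scale) that the
#' calibrated key must reproduce. Back-computed from printed arm cost and
#' cost-effectiveness ratios, the operative effect must be at least the
#' conservative one.
#'
#' @param operative,conservative Target expected utilities in [0,1].
#' @return List of class `effect_targets`.
#' @export
effect_targets <- function(operative, conservative) {
  if (any(!is.finite(c(operative, conservative))) ||
      operative < 0 || operative > 1 || conservative < 0 || conservative > 1)
    stop("targets must lie in [0,1]")
  if (operative < conservative)
    stop("operative target must be >= conservative target")
  structure(list(operative = operative, conservative = conservative),
            class = "effect_targets")
}

#' Calibrate a monotone utility key to published arm effects
#'
#' The per-class utilities behind the published analysis are not printed, so
#' the package calibrates its own: find mean utilities, non-decreasing and
#' bounded in [0,1] by construction, whose induced arm-level expected
#' effects under the baseline tree match the targets. With 2 targets and 5
#' unknowns the problem is underdetermined; a small penalty pulls the class
#' increments toward equal spacing to pick a unique representative. (Exactly
#' equal spacing cannot satisfy both targets inside [0,1], which is why the
#' penalty is soft.) Deterministic: fixed start, derivative-based optimizer,
#' no randomness.
#'
#' @param targets An [effect_targets()].
#' @param params A [model_params()] supplying tree structure, probabilities
#'   and the two arm activity distributions.
#' @param sd Per-class SDs to attach to the returned key (calibration fits
#'   means only).
#' @param lambda Equal-spacing penalty weight.
#' @param maxit Optimizer iteration cap.
#' @return A [utility_key()] with attribute `fit` (achieved arm effects and
#'   squared target deviation).
#' @export
fit_utilities <- function(targets, params, sd = 0, lambda = 1e-6, maxit = 5000) {
  stopifnot(inherits(targets, "effect_targets"))
  w_op <- effect_weights(params, "reconstruction")
  w_co <- effect_weights(params, "conservative")
  tgt <- c(targets$operative, targets$conservative)

  # softmax-increment parameterization: 6 positive increments summing to 1,
  # utilities are the first 5 partial sums -> monotone, inside (0,1)
  key_of <- function(theta) {
    w <- exp(theta - max(theta))
    cumsum(w)[1:5] / sum(w)
  }
  objective <- function(theta) {
    u <- key_of(theta)
    eff <- c(sum(w_op * u), sum(w_co * u))
    incr <- diff(c(0, u, 1))
    sum((eff - tgt)^2) + lambda * sum((incr - 1 / 6)^2)
  }
  fit <- stats::optim(rep(0, 6), objective, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-16))
  # polish from the first optimum; BFGS can report maxit on flat penalty terms
  fit <- stats::optim(fit$par, objective, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-16))
  u <- key_of(fit$par)
  eff <- c(operative = sum(w_op * u), conservative = sum(w_co * u))
  dev <- sum((eff - tgt)^2)
  if (dev > 1e-6)
    stop(sprintf("calibration infeasible: squared target deviation %.3e", dev))
  key <- utility_key(stats::setNames(u, activity_classes()), sd = sd)
  attr(key, "fit") <- list(effects = eff, squared_deviation = dev,
                           targets = tgt, lambda = lambda)
  key
}
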