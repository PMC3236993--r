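#' Configuration for synthetic study tables
#'
#' Describes a multi-study evidence table with the same structure as the
#' pooled activity-class tables the evidence module consumes: per study and
#' arm, a sample size drawn uniformly from a range and per-class counts
#' drawn multinomially from arm-specific class probabilities.
#'
#' @param n_studies Number of studies.
#' @param n_range Length-2 integer range for per-arm sample sizes.
#' @param class_probabilities Named list with elements `operative` and
#'   `conservative`, each an [activity_distribution()].
#' @param age_range,followup_range Uniform ranges for mean age (years) and
#'   follow-up (months).
#' @param fractional_prob Probability that a study row gets a fractional
#'   count pair (half a patient moved between adjacent classes), mirroring
#'   published tables that split patients across classes; set 0 to disable.
#' @param seed Integer seed.
#' @return List of class `synth_study_config`.
#' @export
synth_study_config <- function(n_studies = 4L, n_range = c(20L, 70L),
                               class_probabilities,
                               age_range = c(23, 35),
                               followup_range = c(50, 140),
                               fractional_prob = 0.2, seed = 1L) {
  stopifnot(n_studies >= 1, n_range[1] >= 1, n_range[1] <= n_range[2],
            age_range[1] <= age_range[2],
            followup_range[1] <= followup_range[2],
            fractional_prob >= 0, fractional_prob <= 1)
  if (!all(c("operative", "conservative") %in% names(class_probabilities)))
    stop("class_probabilities must name operative and conservative arms")
  for (d in class_probabilities) stopifnot(inherits(d, "activity_distribution"))
  structure(list(n_studies = as.integer(n_studies), n_range = n_range,
                 class_probabilities = class_probabilities,
                 age_range = age_range, followup_range = followup_range,
                 fractional_prob = fractional_prob, seed = as.integer(seed)),
            class = "synth_study_config")
}

#' Generate a synthetic multi-study activity table
#'
#' @param cfg A [synth_study_config()].
#' @return Validated study-arm record data frame (same shape the evidence
#'   CSV reader returns).
#' @export
generate_studies <- function(cfg) {
  stopifnot(inherits(cfg, "synth_study_config"))
  set.seed(cfg$seed)
  cls <- activity_classes()
  rows <- list()
  for (s in seq_len(cfg$n_studies)) {
    for (arm in c("operative", "conservative")) {
      n <- cfg$n_range[1] + sample.int(cfg$n_range[2] - cfg$n_range[1] + 1L, 1L) - 1L
      counts <- as.numeric(stats::rmultinom(1, n, unclass(cfg$class_probabilities[[arm]])))
      if (stats::runif(1) < cfg$fractional_prob) {
        # split half a patient between a random adjacent class pair,
        # exercising the real-valued count path
        i <- sample(1:4, 1L)
        if (counts[i] >= 1) {
          counts[i] <- counts[i] - 0.5
          counts[i + 1L] <- counts[i + 1L] + 0.5
        }
      }
      row <- data.frame(study = sprintf("synth_%02d", s), arm = arm, n = n,
                        stringsAsFactors = FALSE)
      for (k in seq_along(cls)) row[[paste0("class_", cls[k])]] <- counts[k]
      row$age_years <- stats::runif(1, cfg$age_range[1], cfg$age_range[2])
      row$followup_months <- stats::runif(1, cfg$followup_range[1],
                                          cfg$followup_range[2])
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  validate_study_records(out)
  out
}

#' Generate a synthetic expert utility survey
#'
#' Emulates an expert elicitation: `n_experts` truncated-normal utility
#' draws per activity class, summarized into a derived utility key (sample
#' mean and SD per class).
#'
#' @param mu Named per-class true mean utilities (I-V).
#' @param sigma Per-class true SDs (scalar recycled).
#' @param n_experts Number of experts (default 25).
#' @param seed Integer seed.
#' @return List with `draws` (data frame `expert`, `class`, `utility`) and
#'   `key` (the derived [utility_key()], built without the monotonicity
#'   check since sample means need not be monotone).
#' @export
generate_utility_survey <- function(mu, sigma, n_experts = 25L, seed = 1L) {
  cls <- activity_classes()
  if (is.null(names(mu))) names(mu) <- cls
  stopifnot(all(cls %in% names(mu)), n_experts >= 1)
  if (length(sigma) == 1L) sigma <- stats::setNames(rep(sigma, 5), cls)
  set.seed(as.integer(seed))
  draws <- do.call(rbind, lapply(cls, function(cl) {
    x <- stats::rnorm(n_experts, mu[[cl]], sigma[[cl]])
    for (i in seq_along(x)) {        # truncate to [0,1] by resampling
      tries <- 0L
      while (x[i] < 0 || x[i] > 1) {
        tries <- tries + 1L
        if (tries > 1000L) stop("truncation resampling cap exceeded")
        x[i] <- stats::rnorm(1, mu[[cl]], sigma[[cl]])
      }
    }
    data.frame(expert = seq_len(n_experts), class = cl, utility = x,
               stringsAsFactors = FALSE)
  }))
  m <- vapply(cls, function(cl) mean(draws$utility[draws$class == cl]), numeric(1))
  s <- vapply(cls, function(cl) stats::sd(draws$utility[draws$class == cl]), numeric(1))
  if (n_experts == 1L) s[] <- 0
  list(draws = draws,
       key = utility_key(m, sd = s, check_monotone = FALSE))
}

#' Generate synthetic resource line items with exact totals
#'
#' Random non-negative line items that sum exactly to each requested profile
#' total (uniform stick-breaking, last item takes the remainder).
#'
#' @param profile_totals Named numeric vector, label -> total USD.
#' @param n_items Items per profile.
#' @param seed Integer seed.
#' @return Data frame of resource items with a `profile` column, passing
#'   [validate_resource_items()] and reproducing the totals exactly under
#'   [profile_total()].
#' @export
generate_cost_items <- function(profile_totals, n_items = 6L, seed = 1L) {
  stopifnot(all(profile_totals >= 0), n_items >= 1)
  set.seed(as.integer(seed))
  out <- lapply(names(profile_totals), function(lab) {
    total <- profile_totals[[lab]]
    if (n_items == 1L) {
      parts <- total
    } else {
      cuts <- sort(stats::runif(n_items - 1L, 0, total))
      parts <- diff(c(0, cuts, total))
    }
    data.frame(profile = lab,
               name = sprintf("%s_item_%02d", lab, seq_len(n_items)),
               quantity = 1,
               unit_cost = parts,
               line_cost = parts,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  validate_resource_items(out)
  out
}
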