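#' Gottlob activity classes
#'
#' The model describes post-treatment outcome on the ordinal Gottlob scale:
#' class I (symptomatic activities of daily living) up to class V
#' (unrestricted high-demand sport). Class 0 is the theoretical floor; it is
#' representable in a utility key but never appears in pooled study tables,
#' which report classes I-V only.
#'
#' @return Character vector of the five class labels, lowest to highest.
#' @export
activity_classes <- function() c("I", "II", "III", "IV", "V")

#' Construct an activity distribution
#'
#' A probability distribution over Gottlob activity classes I-V.
#'
#' @param proportions Numeric vector of length 5 (optionally named I-V, in
#'   that order) of non-negative proportions.
#' @param normalize If `TRUE`, rescale to sum to 1; if `FALSE` (default) the
#'   input must already sum to 1 within `1e-9`.
#' @return Named numeric vector of class `activity_distribution`.
#' @export
activity_distribution <- function(proportions, normalize = FALSE) {
  cls <- activity_classes()
  if (length(proportions) != 5L)
    stop("an activity distribution has exactly 5 classes (I-V)")
  if (!is.null(names(proportions)) && !identical(names(proportions), cls))
    proportions <- proportions[cls]
  p <- as.numeric(proportions)
  if (anyNA(p) || any(p < 0))
    stop("proportions must be non-negative and non-missing")
  s <- sum(p)
  if (normalize) {
    if (s <= 0) stop("cannot normalize a zero distribution")
    p <- p / s
  } else if (abs(s - 1) > 1e-9) {
    stop(sprintf("proportions must sum to 1 (got %.12f)", s))
  }
  structure(stats::setNames(p, cls), class = "activity_distribution")
}

#' @export
print.activity_distribution <- function(x, digits = 3, ...) {
  cat("Activity distribution (Gottlob I-V):\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Validate study-arm activity records
#'
#' A study-arm record table holds one row per study x treatment arm with the
#' number of patients contributing activity data (`n`), per-class counts
#' (`class_I` .. `class_V`), mean age and follow-up. Fractional counts are
#' legal (published tables split patients across adjacent classes).
#'
#' @param records Data frame with columns `study`, `arm`, `n`,
#'   `class_I` .. `class_V`, `age_years`, `followup_months`.
#' @param tol Tolerance for the counts-sum-to-n check.
#' @return `records`, invisibly, after validation.
#' @export
validate_study_records <- function(records, tol = 1e-6) {
  needed <- c("study", "arm", "n", paste0("class_", activity_classes()),
              "age_years", "followup_months")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(records) == 0L) stop("no study records supplied")
  bad_arm <- setdiff(unique(records$arm), c("operative", "conservative"))
  if (length(bad_arm))
    stop("unknown arm label(s): ", paste(bad_arm, collapse = ", "))
  cnt <- as.matrix(records[, paste0("class_", activity_classes())])
  if (any(!is.finite(cnt)) || any(cnt < 0))
    stop("class counts must be finite and non-negative")
  if (any(!is.finite(records$n)) || any(records$n <= 0))
    stop("n must be positive for every record")
  dev <- abs(rowSums(cnt) - records$n)
  if (any(dev > tol))
    stop(sprintf("class counts do not sum to n for record(s): %s",
                 paste(records$study[dev > tol], collapse = ", ")))
  invisible(records)
}

#' Read study-arm records from CSV
#'
#' @param path CSV with columns `study,arm,n,class_I..class_V,age_years,followup_months`.
#' @return Validated data frame of study-arm records.
#' @export
read_activity_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  validate_study_records(df)
  df
}

#' Pool study-level activity counts into an arm distribution
#'
#' Raw counts are summed across studies and divided by the total number of
#' patients; this is the fixed-effect, sample-size-weighted pooling the
#' published tables use. No heterogeneity modelling is attempted.
#'
#' @param records Validated study-arm record table.
#' @param arm `"operative"` or `"conservative"`.
#' @return An [activity_distribution()].
#' @export
pool_activity <- function(records, arm) {
  validate_study_records(records)
  arm <- match.arg(arm, c("operative", "conservative"))
  sub <- records[records$arm == arm, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no evidence: no records for arm '", arm, "'")
  counts <- colSums(sub[, paste0("class_", activity_classes()), drop = FALSE])
  activity_distribution(stats::setNames(counts / sum(sub$n), activity_classes()),
                        normalize = TRUE)
}

#' Share of patients at high activity (classes IV + V)
#'
#' @param dist An [activity_distribution()].
#' @return Proportion in classes IV and V combined.
#' @export
high_activity_share <- function(dist) {
  stopifnot(inherits(dist, "activity_distribution"))
  unname(dist[["IV"]] + dist[["V"]])
}

#' Sample-size-weighted mean
#'
#' @param values Numeric vector.
#' @param weights Positive weights of the same length (study sample sizes).
#' @return `sum(values * weights) / sum(weights)`.
#' @export
weighted_mean <- function(values, weights) {
  if (length(values) != length(weights))
    stop("values and weights must have equal length")
  if (length(values) == 0L) stop("empty input")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite")
  sum(values * weights) / sum(weights)
}

#' Arm-level pooled summary
#'
#' One row per arm: pooled n, sample-size-weighted age and follow-up, the
#' pooled class proportions (unrounded) and the high-activity (IV+V) share.
#' Percentages rounded to one decimal are a formatting concern only; see
#' [format_pool_summary()].
#'
#' @param records Validated study-arm record table.
#' @return Data frame with one row per arm present in `records`.
#' @export
pool_summary <- function(records) {
  validate_study_records(records)
  arms <- intersect(c("operative", "conservative"), unique(records$arm))
  rows <- lapply(arms, function(a) {
    sub <- records[records$arm == a, , drop = FALSE]
    d <- pool_activity(records, a)
    out <- data.frame(
      arm = a,
      n = sum(sub$n),
      age_years = weighted_mean(sub$age_years, sub$n),
      followup_months = weighted_mean(sub$followup_months, sub$n),
      stringsAsFactors = FALSE
    )
    for (cl in activity_classes()) out[[paste0("prop_", cl)]] <- d[[cl]]
    out$high_activity_share <- high_activity_share(d)
    out
  })
  do.call(rbind, rows)
}

#' Format a pooled summary with table-style rounded percentages
#'
#' @param summary Output of [pool_summary()].
#' @return Data frame with percentage columns rounded to 1 decimal.
#' @export
format_pool_summary <- function(summary) {
  out <- summary[, c("arm", "n", "age_years", "followup_months")]
  for (cl in activity_classes())
    out[[paste0("pct_", cl)]] <- round(100 * summary[[paste0("prop_", cl)]], 1)
  out$pct_high_activity <- round(100 * summary$high_activity_share, 1)
  out
}
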