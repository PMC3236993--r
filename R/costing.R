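#' Validate resource line items
#'
#' A resource item is one billed line of a treatment profile: a named
#' resource, a quantity, a unit cost and the line cost in USD. The line cost
#' is authoritative: published cost tables fold dosing frequency into it
#' (e.g. 16 days at 3 doses/day of a 3 USD agent is printed as 157 USD), so
#' `line_cost == quantity * unit_cost` is deliberately NOT enforced.
#'
#' @param items Data frame with columns `name`, `quantity`, `unit_cost`,
#'   `line_cost` (extra columns such as `profile` are allowed).
#' @return `items`, invisibly.
#' @export
validate_resource_items <- function(items) {
  needed <- c("name", "quantity", "unit_cost", "line_cost")
  missing_cols <- setdiff(needed, names(items))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(!is.finite(items$line_cost)) || any(items$line_cost < 0))
    stop("line costs must be finite and non-negative")
  if (any(!is.finite(items$quantity)) || any(items$quantity < 0))
    stop("quantities must be finite and non-negative")
  invisible(items)
}

#' Total direct cost of a resource profile
#'
#' @param items Data frame of resource items (see [validate_resource_items()]),
#'   or a numeric vector of line costs. An empty profile costs 0.
#' @return Total cost in USD.
#' @export
profile_total <- function(items) {
  if (is.numeric(items)) {
    if (any(!is.finite(items)) || any(items < 0))
      stop("line costs must be finite and non-negative")
    return(sum(items))
  }
  if (nrow(items) == 0L) return(0)
  validate_resource_items(items)
  sum(items$line_cost)
}

#' Total cost of a long-term complication
#'
#' Complications (osteoarthritis treated by total knee prosthesis; meniscal
#' lesions) are costed as inpatient cost plus a perioperative block assumed
#' in the same range as ACL surgery.
#'
#' @param inpatient In-hospital cost, USD.
#' @param perioperative Perioperative cost, USD.
#' @return Sum, USD.
#' @export
complication_cost <- function(inpatient, perioperative) {
  if (inpatient < 0 || perioperative < 0)
    stop("complication cost components must be non-negative")
  inpatient + perioperative
}

#' Convert Swiss Francs to US Dollars
#'
#' @param amount_chf Amount in CHF.
#' @param factor CHF per USD conversion factor (default 1.15).
#' @return `amount_chf / factor`, USD.
#' @export
chf_to_usd <- function(amount_chf, factor = 1.15) {
  if (!is.finite(factor) || factor <= 0)
    stop("conversion factor must be positive")
  amount_chf / factor
}

#' Build a labelled cost profile
#'
#' @param label Profile name (e.g. `"surgical"`).
#' @param items Resource item data frame.
#' @return List of class `cost_profile` with `label`, `items`, `total`.
#' @export
cost_profile <- function(label, items) {
  total <- profile_total(items)
  structure(list(label = label, items = items, total = total),
            class = "cost_profile")
}

#' @export
print.cost_profile <- function(x, ...) {
  cat(sprintf("Cost profile '%s': %d items, total %.0f USD\n",
              x$label, nrow(x$items), x$total))
  invisible(x)
}

#' Read resource items from CSV
#'
#' @param path CSV with columns `profile,name,quantity,unit_cost,line_cost`.
#' @return Data frame of validated items, with the `profile` column retained.
#' @export
read_resource_items <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"profile" %in% names(df)) stop("missing column: profile")
  validate_resource_items(df)
  df
}

#' Summarize cost profiles from an item table
#'
#' @param items Data frame with a `profile` column.
#' @return Data frame with one row per profile: `profile`, `n_items`, `total`.
#' @export
cost_summary <- function(items) {
  validate_resource_items(items)
  if (!"profile" %in% names(items)) stop("missing column: profile")
  profs <- unique(items$profile)
  do.call(rbind, lapply(profs, function(p) {
    sub <- items[items$profile == p, , drop = FALSE]
    data.frame(profile = p, n_items = nrow(sub), total = profile_total(sub),
               stringsAsFactors = FALSE)
  }))
}
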