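#' Standard population for direct age standardization
#'
#' @param age_labels age-group labels, matching the target table's rows.
#' @param weights non-negative age weights; normalized internally to sum
#'   to 1.
#' @param name tag recorded with the object.
#' @return object of class `standard_population` with normalized weights.
#' @export
standard_population <- function(age_labels, weights, name = "custom") {
  age_labels <- as.character(age_labels)
  weights <- as.numeric(weights)
  if (length(weights) != length(age_labels))
    apc_stop("weights length ", length(weights), " != ", length(age_labels), " labels")
  if (any(!is.finite(weights)) || any(weights < 0))
    apc_stop("standard-population weights must be finite and non-negative")
  if (sum(weights) <= 0) apc_stop("standard-population weights sum to zero")
  structure(
    list(age_labels = age_labels, weights = weights / sum(weights), name = name),
    class = "standard_population"
  )
}

#' WHO 2000 World Standard weights for ages 40 and over
#'
#' The WHO World Standard Population age weights for the ten five-year groups
#' 40-44 through 85+ (per-cent shares 6.59, 6.04, 5.37, 4.55, 3.72, 2.96,
#' 2.21, 1.52, 0.91, 0.635), renormalized to sum to one over these groups.
#'
#' @param age_labels labels to attach (default the conventional 40+ labels).
#' @return a [standard_population()].
#' @export
who2000_standard <- function(age_labels = NULL) {
  path <- system.file("extdata", "who2000_40plus.csv",
                      package = "apcpolish", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  standard_population(age_labels %||% df$age_label, df$weight,
                      name = "WHO 2000 World Standard (40+)")
}

#' Read a standard population from CSV
#'
#' Expects columns `age_label`, `weight`.
#'
#' @param path CSV file.
#' @param name tag for the object.
#' @return a [standard_population()].
#' @export
read_standard_population <- function(path, name = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age_label", "weight") %in% names(df)))
    apc_stop("standard-population CSV needs columns age_label, weight")
  standard_population(df$age_label, df$weight, name = name)
}

#' Long-form rate series for descriptive plots
#'
#' Phase-1 graphical outputs as tidy tables: one row per table cell, grouped
#' for plotting rates by age across periods (`axis = "period"`), by age
#' across cohorts (`axis = "cohort"`), or by period across ages
#' (`axis = "age"`).
#'
#' @param table an [apc_table].
#' @param axis x-axis of the intended plot: `"age"`, `"period"` or
#'   `"cohort"`.
#' @return data.frame with columns `group`, `x`, `rate` (I*J rows).
#' @export
series_by <- function(table, axis = c("period", "age", "cohort")) {
  stopifnot(inherits(table, "apc_table"))
  axis <- match.arg(axis)
  idx <- cohort_index(table)
  I <- nrow(table$rates); J <- ncol(table$rates)
  grid <- expand.grid(j = seq_len(J), i = seq_len(I))[, c("i", "j")]
  age <- table$age_labels[grid$i]
  period <- table$period_labels[grid$j]
  cohort <- idx$cohort_labels[grid$j - grid$i + I]
  rate <- table$rates[cbind(grid$i, grid$j)]
  switch(axis,
    period = data.frame(group = age, x = period, rate = rate),
    age = data.frame(group = period, x = age, rate = rate),
    cohort = data.frame(group = age, x = cohort, rate = rate)
  )
}

#' Directly age-standardized rates per period
#'
#' Weighted average of the age-specific rates in each period using a fixed
#' standard population's age weights, making period rates comparable despite
#' changing age structure.
#'
#' @param table an [apc_table].
#' @param std a [standard_population()] whose labels match the table's age
#'   groups (default: WHO 2000 World Standard for 40+ tables).
#' @return named numeric vector of standardized rates per 100,000, one per
#'   period.
#' @examples
#' age_adjust(hcc_mortality("females"))
#' @export
age_adjust <- function(table, std = who2000_standard(table$age_labels)) {
  stopifnot(inherits(table, "apc_table"), inherits(std, "standard_population"))
  if (!identical(std$age_labels, table$age_labels))
    apc_stop("standard-population age labels do not match the table: ",
             paste(setdiff(table$age_labels, std$age_labels), collapse = ", "))
  out <- as.numeric(crossprod(std$weights, table$rates))
  names(out) <- table$period_labels
  out
}
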