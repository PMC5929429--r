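#' Rates with the cohort influence removed
#'
#' Multiplying each cell's rate by `exp(-residual)` strips the interaction
#' (cohort) component, leaving the purely log-additive age-period surface
#' `exp(mu + alpha_i + beta_j) * 1e5` (per 100,000) by the reconstruction
#' identity.
#'
#' @param table an [apc_table].
#' @param dec the matching `apc_polish` decomposition.
#' @return I x J matrix of cohort-free rates per 100,000.
#' @export
rates_without_cohort <- function(table, dec) {
  stopifnot(inherits(table, "apc_table"), inherits(dec, "apc_polish"))
  if (!identical(dim(table$rates), dim(dec$residuals)))
    apc_stop("table and decomposition dimensions differ")
  table$rates * exp(-dec$residuals)
}

#' Automatic reference-cohort selection
#'
#' For each cohort, the ratio of its rates without and with the cohort
#' influence, aggregated over the cohort's cells by the geometric mean, is
#' `exp(-mean residual)`.  The reference is the cohort whose ratio is closest
#' to one — equivalently, whose mean residual is closest to zero — i.e. the
#' cohort whose rates change least when the cohort influence is removed.
#' Ties are broken in favour of the cohort with more cells, then the later
#' mid-cohort year.
#'
#' @param table an [apc_table].
#' @param dec the matching `apc_polish` decomposition.
#' @return list of class `reference_selection` with `k_ref`, `label`, and a
#'   `diagnostics` data.frame (cohort, ratio, abs_log_ratio, n_cells,
#'   selected) sorted by closeness of the ratio to 1.
#' @examples
#' tab <- hcc_mortality("males")
#' select_reference(tab, apc_median_polish(tab))$label  # 1946
#' @export
select_reference <- function(table, dec) {
  obs <- residual_observations(dec, table)
  K <- attr(obs, "n_cohorts")
  kf <- factor(obs$k, levels = seq_len(K))
  mean_res <- as.numeric(tapply(obs$residual, kf, mean))
  n_cells <- as.integer(table(kf))
  ratio <- exp(-mean_res)
  abs_log <- abs(mean_res)
  # minimal |log ratio|; ties (to 1e-10) -> more cells, then later cohort
  ord <- order(round(abs_log, 10), -n_cells, -seq_len(K))
  k_ref <- ord[1]
  diagnostics <- data.frame(
    k = seq_len(K), cohort = attr(obs, "cohort_labels"),
    ratio = ratio, abs_log_ratio = abs_log, n_cells = n_cells,
    selected = seq_len(K) == k_ref
  )[ord, ]
  rownames(diagnostics) <- NULL
  structure(
    list(k_ref = k_ref, label = attr(obs, "cohort_labels")[k_ref],
         diagnostics = diagnostics),
    class = "reference_selection"
  )
}

#' @export
print.reference_selection <- function(x, ...) {
  cat("Reference cohort:", x$label, "(k =", x$k_ref, ")\n")
  print(utils::head(x$diagnostics, 5), row.names = FALSE)
  invisible(x)
}
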