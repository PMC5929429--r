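#' Median polish of log rates
#'
#' Phase-2 decomposition of the multiphase procedure: the table of rates is
#' transformed to natural-log rates per person-year, `log(rate / 1e5)`, and
#' row (age) and column (period) medians are subtracted iteratively until the
#' largest absolute row/column median of the residuals falls below `tol`.
#' What remains in the residual matrix is the age-by-period interaction,
#' which downstream steps attribute to birth cohorts.
#'
#' Within every iteration rows are swept first, then columns (Tukey's
#' convention); subtracted medians accumulate into the age effects `alpha`
#' and period effects `beta`.  After convergence the effects are centered to
#' sum to zero, with their means absorbed into the overall constant `mu` —
#' the conventional sum-to-zero reporting constraint for age-period-cohort
#' effects.  Centering moves values between `mu`, `alpha` and `beta` only;
#' residuals are unaffected.
#'
#' The reconstruction identity
#' `mu + alpha_i + beta_j + residuals_ij == log(rate_ij / 1e5)`
#' holds exactly (to floating point) after every sweep, by construction.
#'
#' @param table an [apc_table] with strictly positive rates.
#' @param max_iter maximum number of row+column sweeps (default 100).
#' @param tol convergence tolerance on residual row/column medians, on the
#'   log-rate scale (default 1e-8).
#' @return object of class `apc_polish`: list with `mu` (log rate per
#'   person-year), `alpha` (length I), `beta` (length J), `residuals`
#'   (I x J), `n_iterations`, `converged`, and the originating `table`.
#' @examples
#' dec <- apc_median_polish(hcc_mortality("males"))
#' round(dec$mu, 2)  # -6.74
#' @export
apc_median_polish <- function(table, max_iter = 100, tol = 1e-8) {
  stopifnot(inherits(table, "apc_table"))
  if (max_iter < 1) apc_stop("max_iter must be >= 1")
  if (tol < 0) apc_stop("tol must be non-negative")
  x <- log(table$rates / 1e5)
  I <- nrow(x); J <- ncol(x)
  alpha <- rep(0, I); beta <- rep(0, J)
  res <- x
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    rmed <- apply(res, 1, stats::median)
    alpha <- alpha + rmed
    res <- res - rmed
    cmed <- apply(res, 2, stats::median)
    beta <- beta + cmed
    res <- sweep(res, 2, cmed)
    worst <- max(abs(c(apply(res, 1, stats::median),
                       apply(res, 2, stats::median))))
    if (worst <= tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("median polish did not converge in ", max_iter,
            " iterations (worst residual median ", signif(worst, 3), ")")
  # sum-to-zero centering: the conventional APC constraint sum(alpha)=sum(beta)=0
  ma <- mean(alpha); mb <- mean(beta)
  structure(
    list(mu = ma + mb, alpha = alpha - ma, beta = beta - mb,
         residuals = res, n_iterations = it, converged = converged,
         table = table),
    class = "apc_polish"
  )
}

#' @export
print.apc_polish <- function(x, ...) {
  cat("Median polish decomposition (", x$n_iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  cat("  constant mu =", round(x$mu, 4), "(log rate per person-year)\n")
  cat("  age effects:   ", paste(round(x$alpha, 2), collapse = " "), "\n")
  cat("  period effects:", paste(round(x$beta, 2), collapse = " "), "\n")
  invisible(x)
}

#' Tidy reporting table for a median-polish decomposition
#'
#' One row per component (Constant, then each period, then each age group),
#' with the effect rounded half-up to two decimals, mirroring the layout of
#' published age/period effect tables.
#'
#' @param dec an `apc_polish` object.
#' @param digits decimals for the report (default 2).
#' @return data.frame with columns `component` (constant/period/age),
#'   `label`, `effect`.
#' @export
polish_summary <- function(dec, digits = 2) {
  stopifnot(inherits(dec, "apc_polish"))
  data.frame(
    component = c("constant",
                  rep("period", length(dec$beta)),
                  rep("age", length(dec$alpha))),
    label = c("Constant", dec$table$period_labels, dec$table$age_labels),
    effect = round_half_up(c(dec$mu, dec$beta, dec$alpha), digits),
    stringsAsFactors = FALSE
  )
}
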