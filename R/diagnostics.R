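#' Expected death counts under nested rate models
#'
#' Model-fitness diagnostics compare observed deaths to expected counts
#' `E_ij = population_ij * exp(fitted log rate)` under the progressively
#' richer models: `null` (constant `mu`), `age` (`mu + alpha_i`),
#' `age_period` (`mu + alpha_i + beta_j`), and `apc`
#' (`mu + alpha_i + beta_j + gamma_k`, with `gamma` from a cohort-effects
#' fit).
#'
#' @param table an [apc_table] carrying a `population` matrix.
#' @param dec the matching `apc_polish` decomposition.
#' @param est a `cohort_effects` fit; required for `model = "apc"`.
#' @param model one of `"null"`, `"age"`, `"age_period"`, `"apc"`.
#' @return I x J matrix of expected counts.
#' @export
fitted_deaths <- function(table, dec, est = NULL,
                          model = c("apc", "age_period", "age", "null")) {
  stopifnot(inherits(table, "apc_table"), inherits(dec, "apc_polish"))
  model <- match.arg(model)
  if (is.null(table$population))
    apc_stop("fitted_deaths needs a population matrix")
  I <- nrow(table$rates); J <- ncol(table$rates)
  log_rate <- matrix(dec$mu, I, J)
  if (model %in% c("age", "age_period", "apc"))
    log_rate <- log_rate + dec$alpha
  if (model %in% c("age_period", "apc"))
    log_rate <- sweep(log_rate, 2, dec$beta, `+`)
  if (model == "apc") {
    if (is.null(est)) apc_stop("model 'apc' needs cohort-effect estimates")
    stopifnot(inherits(est, "cohort_effects"))
    kmat <- outer(seq_len(I), seq_len(J), function(i, j) j - i + I)
    log_rate <- log_rate + matrix(est$gamma[kmat], I, J)
  }
  E <- table$population * exp(log_rate)
  dimnames(E) <- dimnames(table$rates)
  E
}

#' Poisson deviance residuals
#'
#' Signed square-root cell contributions to the Poisson deviance,
#' `d = sign(O - E) * sqrt(2 * (O * log(O / E) - (O - E)))`, with the
#' `O * log(O / E)` term taken as 0 when `O = 0`.
#'
#' @param observed matrix (or vector) of observed counts, `>= 0`.
#' @param expected matrix of expected counts, `> 0`, same shape.
#' @return matrix of deviance residuals.
#' @examples
#' deviance_residuals(10, 5)  # ~ 1.9655
#' @export
deviance_residuals <- function(observed, expected) {
  if (!identical(dim(observed), dim(expected)) ||
      length(observed) != length(expected))
    apc_stop("observed and expected shapes differ")
  if (any(!is.finite(expected)) || any(expected <= 0))
    apc_stop("expected counts must be positive")
  if (any(!is.finite(observed)) || any(observed < 0))
    apc_stop("observed counts must be non-negative")
  term <- ifelse(observed == 0, 0, observed * log(observed / expected))
  sign(observed - expected) * sqrt(pmax(2 * (term - (observed - expected)), 0))
}

#' Deviance summary across the nested model sequence
#'
#' Sum of squared Poisson deviance residuals for the null, age, age-period
#' and APC models; on data driven by all three time scales the sequence
#' should be (stochastically) decreasing.  Skipped with a message when the
#' table lacks deaths or population.
#'
#' @param table an [apc_table] with `deaths` and `population`.
#' @param dec the matching `apc_polish` decomposition.
#' @param est a `cohort_effects` fit for the APC entry (optional; the APC row
#'   is dropped when absent).
#' @return data.frame with columns `model`, `ss_deviance`, or `NULL`
#'   (invisibly) when counts are unavailable.
#' @export
deviance_summary <- function(table, dec, est = NULL) {
  stopifnot(inherits(table, "apc_table"))
  if (is.null(table$deaths) || is.null(table$population)) {
    message("deviance diagnostics skipped: table lacks deaths/population")
    return(invisible(NULL))
  }
  models <- c("null", "age", "age_period", if (!is.null(est)) "apc")
  ss <- vapply(models, function(m) {
    E <- fitted_deaths(table, dec, est = est, model = m)
    sum(deviance_residuals(table$deaths, E)^2)
  }, numeric(1))
  data.frame(model = models, ss_deviance = as.numeric(ss))
}
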