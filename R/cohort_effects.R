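#' Residual observations for the cohort regression
#'
#' Phase 3 operates on one record per table cell: the median-polish residual
#' together with its cohort membership (and the cell's death count when the
#' table carries one).
#'
#' @param dec an `apc_polish` decomposition.
#' @param table the [apc_table] the decomposition was computed from; defaults
#'   to the table stored in `dec`.
#' @return data.frame of class `apc_observations` with columns `i`, `j`, `k`,
#'   `age`, `period`, `cohort` (mid-cohort year), `residual`, and `deaths`
#'   when available; `I * J` rows, ordered by period within age.
#' @export
residual_observations <- function(dec, table = dec$table) {
  stopifnot(inherits(dec, "apc_polish"), inherits(table, "apc_table"))
  if (!identical(dim(dec$residuals), dim(table$rates)))
    apc_stop("decomposition is ", nrow(dec$residuals), "x", ncol(dec$residuals),
             " but table is ", nrow(table$rates), "x", ncol(table$rates))
  idx <- cohort_index(table)
  I <- nrow(table$rates); J <- ncol(table$rates)
  grid <- expand.grid(j = seq_len(J), i = seq_len(I))[, c("i", "j")]
  k <- grid$j - grid$i + I
  obs <- data.frame(
    i = grid$i, j = grid$j, k = k,
    age = table$age_labels[grid$i],
    period = table$period_labels[grid$j],
    cohort = idx$cohort_labels[k],
    residual = dec$residuals[cbind(grid$i, grid$j)],
    stringsAsFactors = FALSE
  )
  if (!is.null(table$deaths)) obs$deaths <- table$deaths[cbind(grid$i, grid$j)]
  attr(obs, "n_cohorts") <- idx$n_cohorts
  attr(obs, "cohort_labels") <- idx$cohort_labels
  class(obs) <- c("apc_observations", "data.frame")
  obs
}

#' Observation weights for the cohort regression
#'
#' The weighted variant of the residual-on-cohort regression uses weights
#' proportional to death counts, so cohorts (or cells) carrying more deaths —
#' hence more precise log rates — count for more.  Strategies:
#' \describe{
#'   \item{uniform}{equal weight for every cell (reduces to ordinary least
#'     squares).}
#'   \item{per_cohort_deaths}{`W_k` = share of all deaths falling in cohort
#'     `k`, replicated to each of the cohort's cells.}
#'   \item{per_cell_deaths}{each cell weighted by its own death share; unlike
#'     per-cohort weights, these vary within cohorts and therefore move the
#'     point estimates.}
#' }
#'
#' @param obs an `apc_observations` data frame.
#' @param strategy one of `"uniform"`, `"per_cell_deaths"`,
#'   `"per_cohort_deaths"`.
#' @return numeric weight vector, one per record, summing to 1, with
#'   attributes `strategy` and `W_k` (per-cohort weight shares summing to 1).
#'   A cohort with zero total weight triggers a degenerate-weight warning
#'   here and an error at fitting time.
#' @export
cohort_weights <- function(obs, strategy = c("uniform", "per_cell_deaths",
                                             "per_cohort_deaths")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(obs, "apc_observations"))
  K <- attr(obs, "n_cohorts")
  if (strategy == "uniform") {
    w <- rep(1 / nrow(obs), nrow(obs))
  } else {
    if (is.null(obs$deaths))
      apc_stop("strategy '", strategy, "' needs death counts, ",
               "but the table has none")
    total <- sum(obs$deaths)
    if (total <= 0) apc_stop("all death counts are zero; cannot form weights")
    if (strategy == "per_cell_deaths") {
      w <- obs$deaths / total
    } else {
      per_k <- as.numeric(
        tapply(obs$deaths, factor(obs$k, levels = seq_len(K)), sum)
      ) / total
      w <- per_k[obs$k]
      w <- w / sum(w)
    }
  }
  W_k <- switch(strategy,
    uniform = rep(1 / K, K),
    per_cell_deaths = as.numeric(tapply(w, factor(obs$k, levels = seq_len(K)),
                                        sum)) / sum(w),
    per_cohort_deaths = per_k
  )
  if (any(W_k == 0))
    warning("degenerate weights: cohort(s) ",
            paste(which(W_k == 0), collapse = ", "),
            " carry zero total weight")
  structure(w, strategy = strategy, W_k = W_k)
}

#' Fit the residual-on-cohort regression
#'
#' Least-squares regression of median-polish residuals on the K cohort
#' indicator variables with no intercept, so each coefficient `gamma_k` is
#' the cohort's level directly.  Unweighted, the coefficients are exactly the
#' per-cohort arithmetic means of the residuals.  With observation weights
#' the weighted normal equations give the weighted per-cohort means, and the
#' variance estimate is the standard weighted-least-squares one with the
#' weights normalized to sum to the number of records.
#'
#' @param obs an `apc_observations` data frame.
#' @param weights optional non-negative per-record weight vector (e.g. from
#'   [cohort_weights()]); `NULL` for the unweighted fit.
#' @return object of class `cohort_effects`: data.frame with one row per
#'   cohort (`k`, `cohort`, `gamma`, `se`, `weight`, `n_cells`) plus
#'   attributes `sigma2`, `df` (= n - K), `mode`, and `cohort_labels`.
#' @examples
#' dec <- apc_median_polish(hcc_mortality("males"))
#' fit <- fit_cohort_effects(residual_observations(dec))
#' round(exp(fit$gamma[1] - fit$gamma[fit$cohort == 1946]), 2)  # 0.75
#' @export
fit_cohort_effects <- function(obs, weights = NULL) {
  stopifnot(inherits(obs, "apc_observations"))
  K <- attr(obs, "n_cohorts")
  n <- nrow(obs)
  if (!all(seq_len(K) %in% obs$k))
    apc_stop("cohort(s) ", paste(setdiff(seq_len(K), obs$k), collapse = ", "),
             " have no observations")
  kf <- factor(obs$k, levels = seq_len(K))
  if (is.null(weights)) {
    w <- rep(1, n)
    mode <- "unweighted"
    W_k <- rep(1 / K, K)
  } else {
    if (length(weights) != n) apc_stop("weights length ", length(weights), " != ", n)
    if (any(weights < 0) || all(weights == 0))
      apc_stop("weights must be non-negative and not all zero")
    w <- as.numeric(weights) * n / sum(weights)  # normalize to sum to n
    mode <- paste0("weighted:", attr(weights, "strategy") %||% "custom")
    W_k <- attr(weights, "W_k") %||%
      as.numeric(tapply(w, kf, sum) / sum(w))
  }
  S_k <- as.numeric(tapply(w, kf, sum))
  if (any(S_k == 0))
    apc_stop("cohort(s) ", paste(which(S_k == 0), collapse = ", "),
             " have zero total weight; their effects are unidentifiable")
  gamma <- as.numeric(tapply(w * obs$residual, kf, sum)) / S_k
  rss <- sum(w * (obs$residual - gamma[obs$k])^2)
  df <- n - K
  sigma2 <- if (df > 0) rss / df else 0
  se <- sqrt(sigma2 / S_k)
  out <- data.frame(
    k = seq_len(K),
    cohort = attr(obs, "cohort_labels"),
    gamma = gamma, se = se, weight = W_k,
    n_cells = as.integer(table(kf))
  )
  attr(out, "sigma2") <- sigma2
  attr(out, "df") <- df
  attr(out, "mode") <- mode
  attr(out, "cohort_labels") <- attr(obs, "cohort_labels")
  class(out) <- c("cohort_effects", "data.frame")
  out
}

resolve_cohort <- function(est, ref) {
  labels <- attr(est, "cohort_labels")
  K <- nrow(est)
  if (is.character(ref)) ref <- suppressWarnings(as.numeric(ref))
  if (is.na(ref)) apc_stop("reference cohort must be a cohort label or index")
  hit <- which(labels == ref)
  if (length(hit) == 1) return(hit)
  if (ref >= 1 && ref <= K && ref == round(ref)) return(as.integer(ref))
  apc_stop("reference cohort '", ref, "' not found; labels: ",
           paste(labels, collapse = ", "))
}

#' Cohort rate ratios against a reference cohort
#'
#' Exponentiated contrasts `RR_k = exp(gamma_k - gamma_ref)` with confidence
#' intervals `exp((gamma_k - gamma_ref) +/- q * SE)`, where the standard
#' error of the difference comes from the fit's coefficient covariance
#' (diagonal for the indicator design) and `q` is the normal quantile by
#' default (`z = 1.959964` at 95%), or the t quantile on `n - K` degrees of
#' freedom with `use_t = TRUE`.  Reference selection is pure post-processing:
#' no refitting is needed to change reference.
#'
#' @param est a `cohort_effects` fit.
#' @param ref reference cohort, given as a mid-cohort label (e.g. `1946`) or
#'   a cohort index `1..K`.
#' @param alpha_level two-sided error rate (default 0.05 for 95% intervals).
#' @param use_t use Student-t instead of normal quantiles.
#' @return data.frame of class `rate_ratios` with columns `k`, `cohort`,
#'   `rr`, `ci_low`, `ci_high`, `is_ref`, `mode`; the reference row has
#'   `rr = 1` exactly and `NA` interval bounds (printed as `REF`).
#' @export
rate_ratios <- function(est, ref, alpha_level = 0.05, use_t = FALSE) {
  stopifnot(inherits(est, "cohort_effects"))
  if (alpha_level <= 0 || alpha_level >= 1) apc_stop("alpha_level must be in (0, 1)")
  r <- resolve_cohort(est, ref)
  diff <- est$gamma - est$gamma[r]
  se_diff <- sqrt(est$se^2 + est$se[r]^2)
  se_diff[r] <- 0
  q <- if (use_t) stats::qt(1 - alpha_level / 2, df = attr(est, "df"))
       else stats::qnorm(1 - alpha_level / 2)
  out <- data.frame(
    k = est$k, cohort = est$cohort,
    rr = exp(diff),
    ci_low = exp(diff - q * se_diff),
    ci_high = exp(diff + q * se_diff),
    is_ref = seq_len(nrow(est)) == r,
    mode = attr(est, "mode")
  )
  out$rr[r] <- 1
  out$ci_low[r] <- NA_real_
  out$ci_high[r] <- NA_real_
  attr(out, "ref") <- est$cohort[r]
  attr(out, "alpha_level") <- alpha_level
  class(out) <- c("rate_ratios", "data.frame")
  out
}

#' @export
print.rate_ratios <- function(x, digits = 2, ...) {
  cat("Cohort rate ratios (", x$mode[1], ", reference ", attr(x, "ref"),
      ", ", 100 * (1 - attr(x, "alpha_level")), "% CI)\n", sep = "")
  fmt <- function(v) formatC(round_half_up(v, digits), format = "f", digits = digits)
  ci <- ifelse(x$is_ref, "REF", paste0(fmt(x$ci_low), "-", fmt(x$ci_high)))
  print(data.frame(cohort = x$cohort, effect = fmt(x$rr), ci = ci),
        row.names = FALSE)
  invisible(x)
}
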