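#' Age-period contingency table of event rates
#'
#' The central data container: an I x J matrix of event rates per 100,000
#' person-years, cross-classified by I five-year age groups (rows) and J
#' five-year calendar periods (columns), optionally paired with matrices of
#' event (death) counts and person-time.  Birth cohorts run along the
#' anti-diagonals: the cell in age row `i` and period column `j` belongs to
#' cohort `k = j - i + I`, giving `K = I + J - 1` cohorts in total.
#'
#' @param rates numeric I x J matrix of rates per 100,000; all entries must be
#'   strictly positive (the method works on log rates).
#' @param age_labels character vector of I age-group labels, e.g. `"40-44"`,
#'   with an optionally open-ended last group (`"85+"`).
#' @param period_labels character vector of J period labels, e.g.
#'   `"1976-1980"`.
#' @param deaths optional I x J matrix of non-negative event counts.
#' @param population optional I x J matrix of positive person-time.
#' @param meta named list of free-text tags (sex, cause, source, ...).
#' @param check_consistency when both `deaths` and `population` are supplied,
#'   verify `rates == deaths / population * 1e5` to relative tolerance 1e-6.
#'   Set to `FALSE` for tables whose printed rates were rounded upstream.
#' @return an object of class `apc_table`.
#' @examples
#' r <- matrix(c(10, 20, 30, 60), 2, 2)
#' tab <- apc_table(r, c("40-44", "45-49"), c("1976-1980", "1981-1985"))
#' tab
#' @export
apc_table <- function(rates, age_labels, period_labels,
                      deaths = NULL, population = NULL,
                      meta = list(), check_consistency = TRUE) {
  rates <- as.matrix(rates)
  if (!is.numeric(rates)) apc_stop("rates must be numeric")
  I <- nrow(rates); J <- ncol(rates)
  if (I < 2 || J < 2) apc_stop("need at least 2 age groups and 2 periods, got ", I, "x", J)
  age_labels <- as.character(age_labels)
  period_labels <- as.character(period_labels)
  if (length(age_labels) != I) apc_stop("age_labels length ", length(age_labels), " != ", I, " rows")
  if (length(period_labels) != J) apc_stop("period_labels length ", length(period_labels), " != ", J, " columns")
  bad <- which(!is.finite(rates) | rates <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    apc_stop("non-positive rate at cell (age ", age_labels[bad[1, 1]],
             ", period ", period_labels[bad[1, 2]],
             "): log transform undefined")
  }
  dimnames(rates) <- list(age = age_labels, period = period_labels)

  check_mat <- function(m, what, lower_ok) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (!identical(dim(m), dim(rates)))
      apc_stop(what, " matrix is ", nrow(m), "x", ncol(m), ", expected ", I, "x", J)
    bad <- which(!is.finite(m) | (if (lower_ok) m < 0 else m <= 0), arr.ind = TRUE)
    if (nrow(bad) > 0)
      apc_stop("invalid ", what, " at cell (age ", age_labels[bad[1, 1]],
               ", period ", period_labels[bad[1, 2]], ")")
    dimnames(m) <- dimnames(rates)
    m
  }
  deaths <- check_mat(deaths, "deaths", lower_ok = TRUE)
  population <- check_mat(population, "population", lower_ok = FALSE)

  if (!is.null(deaths) && !is.null(population) && isTRUE(check_consistency)) {
    implied <- deaths / population * 1e5
    rel <- abs(implied - rates) / pmax(rates, .Machine$double.eps)
    if (any(rel > 1e-6)) {
      w <- which(rel == max(rel), arr.ind = TRUE)[1, ]
      apc_stop("rates inconsistent with deaths/population at cell (age ",
               age_labels[w[1]], ", period ", period_labels[w[2]],
               "): rate ", rates[w[1], w[2]], " vs implied ",
               signif(implied[w[1], w[2]], 8),
               "; use check_consistency = FALSE for pre-rounded rates")
    }
  }

  structure(
    list(rates = rates, age_labels = age_labels, period_labels = period_labels,
         deaths = deaths, population = population, meta = meta),
    class = "apc_table"
  )
}

#' @export
print.apc_table <- function(x, ...) {
  cat("Age-period contingency table: ", nrow(x$rates), " age groups x ",
      ncol(x$rates), " periods (", n_cohorts(x), " cohorts)\n", sep = "")
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  }
  cat("  deaths: ", if (is.null(x$deaths)) "absent" else "present",
      ", population: ", if (is.null(x$population)) "absent" else "present",
      "\n", sep = "")
  print(round(x$rates, 2))
  invisible(x)
}

#' @export
dim.apc_table <- function(x) dim(x$rates)

n_cohorts <- function(table) nrow(table$rates) + ncol(table$rates) - 1L

#' Cohort indexing of an age-period table
#'
#' Builds the diagonal cohort index: cell (i, j) belongs to cohort
#' `k = j - i + I`, so cohort 1 is the oldest-age/earliest-period corner and
#' cohort `K = I + J - 1` the youngest-age/latest-period corner.  Mid-cohort
#' year labels are derived as period midpoint minus age-group midpoint (the
#' open-ended last age group takes the nominal midpoint of a closed five-year
#' group), which lands on the conventional mid-cohort grid: e.g. ages starting
#' at 40 and periods starting at 1976 give cohorts 1891, 1896, ..., 1966.
#'
#' Numeric labels require equal age and period interval widths; tables with
#' unparseable labels (toy examples) fall back to the integer index `k`.
#'
#' @param table an [apc_table].
#' @return list with `n_cohorts`, numeric `cohort_labels` (length K), and the
#'   I x J integer matrix `k` of cohort memberships.
#' @export
cohort_index <- function(table) {
  stopifnot(inherits(table, "apc_table"))
  I <- nrow(table$rates); J <- ncol(table$rates)
  K <- I + J - 1L
  kmat <- outer(seq_len(I), seq_len(J), function(i, j) j - i + I)
  dimnames(kmat) <- dimnames(table$rates)

  age_start <- label_start(table$age_labels)
  per_start <- label_start(table$period_labels)
  if (!anyNA(age_start) && !anyNA(per_start)) {
    aw <- unique(diff(age_start)); pw <- unique(diff(per_start))
    if (length(aw) != 1 || length(pw) != 1 || aw != pw)
      apc_stop("unequal age/period interval widths (",
               paste(aw, collapse = ","), " vs ", paste(pw, collapse = ","),
               "): cohort indexing requires a common width")
    width <- aw
    # period midpoint - age midpoint: the +width/2 terms cancel, leaving
    # period start minus age start; cohort 1 pairs the oldest age group with
    # the earliest period.
    labels <- per_start[1] - age_start[I] + width * (seq_len(K) - 1)
  } else {
    labels <- as.numeric(seq_len(K))
  }
  list(n_cohorts = K, cohort_labels = labels, k = kmat)
}

#' Cohort membership of one cell
#'
#' @param table an [apc_table].
#' @param i age-group row index (1-based).
#' @param j period column index (1-based).
#' @return list with integer `k` and the numeric mid-cohort `label`.
#' @examples
#' tab <- hcc_mortality("males")
#' cohort_of_cell(tab, 10, 1)  # oldest age, earliest period -> cohort 1, 1891
#' @export
cohort_of_cell <- function(table, i, j) {
  idx <- cohort_index(table)
  I <- nrow(table$rates); J <- ncol(table$rates)
  if (length(i) != 1 || length(j) != 1 || is.na(i) || is.na(j) ||
      i < 1 || i > I || j < 1 || j > J)
    apc_stop("cell index (", i, ",", j, ") outside ", I, "x", J, " table")
  k <- as.integer(j - i + I)
  list(k = k, label = idx$cohort_labels[k])
}

#' Cells belonging to one cohort
#'
#' @param table an [apc_table].
#' @param k cohort index in `1..(I+J-1)`.
#' @return two-column integer matrix of (i, j) pairs, ordered by increasing
#'   period `j`; the anti-diagonal `j - i + I == k`.
#' @export
cells_of_cohort <- function(table, k) {
  I <- nrow(table$rates); J <- ncol(table$rates)
  K <- I + J - 1L
  if (length(k) != 1 || is.na(k) || k < 1 || k > K)
    apc_stop("cohort index ", k, " outside 1..", K)
  j <- seq_len(J)
  i <- j - k + I
  keep <- i >= 1 & i <= I
  cbind(i = as.integer(i[keep]), j = as.integer(j[keep]))
}

#' Read an age-period table from CSV
#'
#' Two dialects are supported.  `wide`: first column holds age labels, the
#' header row holds period labels, cells hold rates.  `long`: columns `age`,
#' `period`, `rate` and optionally `deaths`, `population`; age and period
#' level order follows first appearance in the file.
#'
#' @param path CSV file path.
#' @param layout `"wide"` or `"long"`.
#' @param meta,check_consistency passed to [apc_table()].
#' @return an [apc_table].
#' @export
read_apc_table <- function(path, layout = c("wide", "long"), meta = list(),
                           check_consistency = TRUE) {
  layout <- match.arg(layout)
  if (!file.exists(path)) apc_stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (layout == "wide") {
    if (ncol(df) < 3) apc_stop("wide layout needs an age column plus >= 2 period columns")
    age_labels <- as.character(df[[1]])
    period_labels <- colnames(df)[-1]
    rates <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(rates)) apc_stop("non-numeric rate cells in ", path)
    apc_table(rates, age_labels, period_labels, meta = meta,
              check_consistency = check_consistency)
  } else {
    need <- c("age", "period", "rate")
    if (!all(need %in% names(df)))
      apc_stop("long layout requires columns age, period, rate; got: ",
               paste(names(df), collapse = ", "))
    age_labels <- unique(as.character(df$age))
    period_labels <- unique(as.character(df$period))
    I <- length(age_labels); J <- length(period_labels)
    if (nrow(df) != I * J)
      apc_stop("long table has ", nrow(df), " rows, expected ", I, "x", J,
               " = ", I * J, " (ragged or duplicated cells)")
    fill <- function(col) {
      if (!col %in% names(df)) return(NULL)
      m <- matrix(NA_real_, I, J)
      m[cbind(match(df$age, age_labels), match(df$period, period_labels))] <-
        as.numeric(df[[col]])
      m
    }
    apc_table(fill("rate"), age_labels, period_labels,
              deaths = fill("deaths"), population = fill("population"),
              meta = meta, check_consistency = check_consistency)
  }
}

#' Write an age-period table to CSV
#'
#' @param table an [apc_table].
#' @param path output CSV path.
#' @param layout `"wide"` (rates only) or `"long"` (rates plus deaths and
#'   population when present).
#' @return `path`, invisibly.
#' @export
write_apc_table <- function(table, path, layout = c("wide", "long")) {
  stopifnot(inherits(table, "apc_table"))
  layout <- match.arg(layout)
  if (layout == "wide") {
    df <- data.frame(age = table$age_labels, table$rates,
                     check.names = FALSE, row.names = NULL)
    colnames(df) <- c("age", table$period_labels)
  } else {
    grid <- expand.grid(i = seq_along(table$age_labels),
                        j = seq_along(table$period_labels))
    df <- data.frame(
      age = table$age_labels[grid$i],
      period = table$period_labels[grid$j],
      rate = table$rates[cbind(grid$i, grid$j)]
    )
    if (!is.null(table$deaths)) df$deaths <- table$deaths[cbind(grid$i, grid$j)]
    if (!is.null(table$population)) df$population <- table$population[cbind(grid$i, grid$j)]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged hepatocellular-carcinoma mortality fixtures
#'
#' The Taiwan 1976-2010 HCC mortality rate tables (per 100,000) for males and
#' females: 10 five-year age groups (40-44 through 85+) by 7 five-year
#' periods, i.e. 16 birth cohorts with mid-cohort years 1891 through 1966.
#' Rates only; the underlying death counts are not public.
#'
#' @param name `"males"` or `"females"` (the prefixed forms `"hcc_males"` /
#'   `"hcc_females"` are also accepted).
#' @return an [apc_table].
#' @examples
#' hcc_mortality("males")$rates["40-44", "1976-1980"]  # 31.41
#' @export
hcc_mortality <- function(name = c("males", "females")) {
  name <- sub("^hcc_", "", as.character(name)[1])
  if (!name %in% c("males", "females"))
    apc_stop("unknown fixture '", name,
             "'; available: hcc_males, hcc_females")
  path <- system.file("extdata", paste0("hcc_", name, ".csv"),
                      package = "apcpolish", mustWork = TRUE)
  read_apc_table(path, layout = "wide",
                 meta = list(sex = name, cause = "hepatocellular carcinoma",
                             region = "Taiwan", years = "1976-2010",
                             units = "deaths per 100,000 person-years"))
}
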