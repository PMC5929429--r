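# Independent oracles, deliberately written as plain loops so they share no
# code path with the package implementation.

# Brute-force median polish: explicit row-then-column sweeps on a plain
# matrix of log rates, returning the residual matrix and raw (uncentered)
# effect accumulators.
oracle_polish <- function(x, n_sweeps = 50) {
  a <- rep(0, nrow(x)); b <- rep(0, ncol(x))
  for (s in seq_len(n_sweeps)) {
    for (i in seq_len(nrow(x))) {
      m <- median(x[i, ])
      x[i, ] <- x[i, ] - m
      a[i] <- a[i] + m
    }
    for (j in seq_len(ncol(x))) {
      m <- median(x[, j])
      x[, j] <- x[, j] - m
      b[j] <- b[j] + m
    }
  }
  list(residuals = x, row = a, col = b)
}

# Group means of residuals by anti-diagonal, by direct accumulation.
oracle_cohort_means <- function(res) {
  I <- nrow(res); J <- ncol(res)
  K <- I + J - 1
  sums <- numeric(K); counts <- integer(K)
  for (i in seq_len(I)) for (j in seq_len(J)) {
    k <- j - i + I
    sums[k] <- sums[k] + res[i, j]
    counts[k] <- counts[k] + 1L
  }
  sums / counts
}

# A small exactly-additive table: rate = exp(m + r_i + c_j) * 1e5.
additive_table <- function(m = -7, row_eff = c(-0.5, 0, 0.2, 0.9),
                           col_eff = c(-0.1, 0, 0.3)) {
  astart <- 40 + 5 * (seq_along(row_eff) - 1)
  pstart <- 1976 + 5 * (seq_along(col_eff) - 1)
  apc_table(exp(m + outer(row_eff, col_eff, `+`)) * 1e5,
            paste0(astart, "-", astart + 4),
            paste0(pstart, "-", pstart + 4))
}

# Deterministic toy table with deaths and population attached.
toy_counted_table <- function() {
  pop <- matrix(c(2e5, 3e5, 2.5e5, 1e5, 1.5e5, 1.2e5), 2, 3, byrow = TRUE)
  deaths <- matrix(c(30, 60, 45, 40, 66, 50), 2, 3, byrow = TRUE)
  apc_table(deaths / pop * 1e5,
            c("40-44", "45-49"), c("1976-1980", "1981-1985", "1986-1990"),
            deaths = deaths, population = pop)
}

round2 <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100  # half-up

expect_rounded <- function(x, target, digits = 2) {
  expect_equal(round(x, digits), target, tolerance = 1e-12)
}
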