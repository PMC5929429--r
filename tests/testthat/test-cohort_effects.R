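male_fit <- local({
  dec <- apc_median_polish(hcc_mortality("males"))
  obs <- residual_observations(dec)
  list(dec = dec, obs = obs, fit = fit_cohort_effects(obs))
})

test_that("observations enumerate all cells with correct cohort structure", {
  obs <- male_fit$obs
  expect_identical(nrow(obs), 70L)
  expect_identical(attr(obs, "n_cohorts"), 16L)
  expect_true(all(obs$k == obs$j - obs$i + 10))
  # grouping by k reproduces cells_of_cohort
  tab <- hcc_mortality("males")
  for (k in c(1, 7, 12, 16)) {
    got <- obs[obs$k == k, c("i", "j")]
    got <- as.matrix(got[order(got$j), ])
    expect_equal(unname(got), unname(cells_of_cohort(tab, k)))
  }
  # 2x2 table: 4 records, 3 cohorts, middle cohort has 2 cells
  small <- apc_table(matrix(c(10, 20, 30, 40), 2, 2),
                     c("40-44", "45-49"), c("1976-1980", "1981-1985"))
  obs2 <- residual_observations(apc_median_polish(small), small)
  expect_identical(nrow(obs2), 4L)
  expect_equal(as.integer(table(obs2$k)), c(1L, 2L, 1L))
})

test_that("unweighted coefficients equal per-cohort residual means (oracle)", {
  means <- oracle_cohort_means(male_fit$dec$residuals)
  expect_lt(max(abs(male_fit$fit$gamma - means)), 1e-10)
})

test_that("uniform weights reproduce the unweighted fit to 1e-10", {
  w <- cohort_weights(male_fit$obs, "uniform")
  wfit <- fit_cohort_effects(male_fit$obs, w)
  expect_lt(max(abs(wfit$gamma - male_fit$fit$gamma)), 1e-10)
  expect_lt(max(abs(wfit$se - male_fit$fit$se)), 1e-10)
})

test_that("weight strategies match hand-computed proportions and fail loudly", {
  tab <- toy_counted_table()
  obs <- residual_observations(apc_median_polish(tab), tab)
  # hand summation: deaths by cohort k=1..4 along anti-diagonals
  d <- tab$deaths
  by_cohort <- c(d[2, 1], d[1, 1] + d[2, 2], d[1, 2] + d[2, 3], d[1, 3])
  w <- cohort_weights(obs, "per_cohort_deaths")
  expect_equal(attr(w, "W_k"), by_cohort / sum(d), tolerance = 1e-12)
  wc <- cohort_weights(obs, "per_cell_deaths")
  expect_equal(as.numeric(wc), obs$deaths / sum(d), tolerance = 1e-12)
  expect_equal(sum(wc), 1)
  # equal deaths per cohort -> W_k all 1/K (cohort totals all 20)
  eq <- tab; eq$deaths <- matrix(c(10, 10, 20, 20, 10, 10), 2, 3, byrow = TRUE)
  obs_eq <- residual_observations(apc_median_polish(tab), eq)
  expect_equal(attr(cohort_weights(obs_eq, "per_cohort_deaths"), "W_k"),
               rep(0.25, 4))
  # degenerate: all deaths in one cohort
  one <- tab; one$deaths <- matrix(c(0, 0, 0, 99, 0, 0), 2, 3, byrow = TRUE)
  obs_one <- residual_observations(apc_median_polish(tab), one)
  expect_warning(w1 <- cohort_weights(obs_one, "per_cohort_deaths"),
                 "degenerate")
  expect_equal(sort(attr(w1, "W_k")), c(0, 0, 0, 1))
  expect_error(suppressWarnings(fit_cohort_effects(obs_one, w1)),
               "unidentifiable")
  # missing deaths
  noc <- residual_observations(male_fit$dec)
  expect_error(cohort_weights(noc, "per_cell_deaths"), "needs death counts")
})

test_that("zero residuals give zero effects and degenerate intervals", {
  tab <- additive_table()
  obs <- residual_observations(apc_median_polish(tab), tab)
  fit <- fit_cohort_effects(obs)
  expect_lt(max(abs(fit$gamma)), 1e-12)
  expect_lt(max(fit$se), 1e-12)
  rr <- rate_ratios(fit, ref = 1)
  expect_equal(rr$rr, rep(1, nrow(rr)), tolerance = 1e-10)
  width <- rr$ci_high - rr$ci_low
  expect_lt(max(width, na.rm = TRUE), 1e-10)
})

test_that("published unweighted rate ratios are reproduced (reference rows exact)", {
  rr <- rate_ratios(male_fit$fit, 1946)
  expect_identical(rr$rr[rr$cohort == 1946], 1)
  expect_true(is.na(rr$ci_low[rr$is_ref]))
  expect_rounded(rr$rr[rr$cohort == 1891], 0.75)
  expect_rounded(rr$rr[rr$cohort == 1936], 1.13)
  dec_f <- apc_median_polish(hcc_mortality("females"))
  rr_f <- rate_ratios(fit_cohort_effects(residual_observations(dec_f)), 1941)
  expect_rounded(rr_f$rr[rr_f$cohort == 1961], 0.42)
})

test_that("reference swaps are consistent and CIs are monotone in level", {
  fit <- male_fit$fit
  a <- rate_ratios(fit, 1891)
  b <- rate_ratios(fit, 1946)
  expect_equal(b$rr, a$rr / a$rr[a$cohort == 1946], tolerance = 1e-10)
  ci95 <- rate_ratios(fit, 1946, alpha_level = 0.05)
  ci99 <- rate_ratios(fit, 1946, alpha_level = 0.01)
  nonref <- !ci95$is_ref
  expect_true(all(ci99$ci_low[nonref] <= ci95$ci_low[nonref]))
  expect_true(all(ci99$ci_high[nonref] >= ci95$ci_high[nonref]))
  expect_true(all(ci95$ci_low[nonref] <= ci95$rr[nonref] &
                    ci95$rr[nonref] <= ci95$ci_high[nonref]))
  # t-based intervals are wider than normal ones at the same level
  cit <- rate_ratios(fit, 1946, use_t = TRUE)
  expect_true(all(cit$ci_low[nonref] <= ci95$ci_low[nonref]))
  expect_error(rate_ratios(fit, 1900), "not found")
})
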