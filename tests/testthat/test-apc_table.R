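test_that("fixtures load with the printed values, dimensions and digests", {
  males <- hcc_mortality("males")
  females <- hcc_mortality("females")
  expect_identical(dim(males), c(10L, 7L))
  expect_identical(dim(females), c(10L, 7L))
  expect_equal(males$rates["40-44", "1976-1980"], 31.41)
  expect_equal(males$rates["85+", "1976-1980"], 133.97)
  expect_equal(females$rates["85+", "2006-2010"], 196.03)
  # digest of all 70 printed values per sex
  expect_equal(sum(males$rates), 9866.02)
  expect_equal(sum(females$rates), 4195.21)
  expect_error(hcc_mortality("unknown"), "hcc_males, hcc_females")
})

test_that("constructor validates shapes, positivity and count consistency", {
  expect_error(apc_table(matrix(1, 1, 3), "a", c("p", "q", "r")), "at least 2")
  r <- matrix(c(1, 2, 0, 4), 2, 2)  # zero sits at (1, 2)
  expect_error(
    apc_table(r, c("40-44", "45-49"), c("1976-1980", "1981-1985")),
    "non-positive rate.*40-44.*1981-1985"
  )
  pop <- matrix(1e5, 2, 2)
  d <- matrix(c(10, 20, 30, 40), 2, 2)
  ok <- apc_table(d / pop * 1e5, c("40-44", "45-49"),
                  c("1976-1980", "1981-1985"), deaths = d, population = pop)
  expect_s3_class(ok, "apc_table")
  expect_error(
    apc_table(d / pop * 1e5 * 1.01, c("40-44", "45-49"),
              c("1976-1980", "1981-1985"), deaths = d, population = pop),
    "inconsistent"
  )
  # overridable
  expect_s3_class(
    apc_table(d / pop * 1e5 * 1.01, c("40-44", "45-49"),
              c("1976-1980", "1981-1985"), deaths = d, population = pop,
              check_consistency = FALSE),
    "apc_table"
  )
})

test_that("cohort indexing follows k = j - i + I with mid-cohort-year labels", {
  tab <- hcc_mortality("males")
  expect_equal(cohort_of_cell(tab, 10, 1), list(k = 1L, label = 1891))
  expect_equal(cohort_of_cell(tab, 1, 7), list(k = 16L, label = 1966))
  expect_equal(cohort_of_cell(tab, 10, 7)$k, 7L)      # (I, J) -> k = J
  expect_equal(cohort_index(tab)$cohort_labels, seq(1891, 1966, by = 5))
  expect_error(cohort_of_cell(tab, 11, 1), "outside")
  expect_error(cells_of_cohort(tab, 17), "outside")
})

test_that("cells_of_cohort enumerates anti-diagonals and partitions the grid", {
  tab <- hcc_mortality("males")
  expect_equal(cells_of_cohort(tab, 1), cbind(i = 10L, j = 1L))
  # k = 12 (1946): brute-force enumeration of j - i + 10 == 12
  brute <- NULL
  for (i in 1:10) for (j in 1:7) if (j - i + 10 == 12) brute <- rbind(brute, c(i, j))
  got <- cells_of_cohort(tab, 12)
  expect_equal(unname(got), unname(brute[order(brute[, 2]), , drop = FALSE]))
  expect_equal(nrow(got), min(10, 7, 12, 10 + 7 - 12))
  # disjoint cover of all 70 cells
  all_cells <- do.call(rbind, lapply(1:16, function(k) cells_of_cohort(tab, k)))
  expect_equal(nrow(all_cells), 70)
  expect_false(any(duplicated(all_cells)))
})

test_that("unequal age/period widths are rejected", {
  r <- matrix(1:6 + 0.5, 2, 3)
  expect_error(
    cohort_index(apc_table(r, c("40-44", "45-49"),
                           c("1976-1985", "1986-1995", "1996-2005"))),
    "widths"
  )
})

test_that("CSV round-trips are bit-identical in both layouts", {
  tab <- hcc_mortality("females")
  for (layout in c("wide", "long")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_apc_table(tab, path, layout = layout)
    back <- read_apc_table(path, layout = layout)
    expect_identical(back$rates, tab$rates)
  }
  # long layout carries deaths and population through
  counted <- toy_counted_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_apc_table(counted, path, layout = "long")
  back <- read_apc_table(path, layout = "long")
  expect_identical(back$deaths, counted$deaths)
  expect_identical(back$population, counted$population)
})

test_that("readers reject malformed files with cell-level messages", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,1976-1980,1981-1985", "40-44,1.0,2.0", "45-49,0,2.0"), path)
  expect_error(read_apc_table(path), "non-positive rate.*45-49")
  writeLines(c("age,period,rate", "40-44,1976-1980,1.0", "40-44,1981-1985,2.0",
               "45-49,1976-1980,3.0"), path)
  expect_error(read_apc_table(path, layout = "long"), "ragged|expected")
  writeLines(c("x,y,z", "1,2,3"), path)
  expect_error(read_apc_table(path, layout = "long"), "requires columns")
  expect_error(read_apc_table(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("a minimal 2x2 long table is valid and has 3 cohorts", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,period,rate",
               "40-44,1976-1980,1.0", "40-44,1981-1985,1.0",
               "45-49,1976-1980,1.0", "45-49,1981-1985,1.0"), path)
  tab <- read_apc_table(path, layout = "long")
  expect_identical(dim(tab), c(2L, 2L))
  expect_equal(cohort_index(tab)$n_cohorts, 3L)
})
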