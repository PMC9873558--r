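test_that("the drug panel matches the assay design", {
  panel <- all_drug_panel()
  expect_equal(nrow(panel), 18)
  expect_equal(sum(panel$class == "antimetabolite"), 4)
  expect_equal(sum(panel$class == "non-antimetabolite cytotoxic"), 6)
  expect_equal(sum(panel$class == "tyrosine kinase inhibitor"), 5)
  expect_equal(sum(panel$class == "HDAC inhibitor"), 2)
  expect_equal(sum(panel$class == "BH3-mimetic"), 1)
  g <- concentration_grid("venetoclax")
  expect_length(g, 6)
  expect_true(all(diff(g) > 0))
  expect_equal(g[1], 0.001)
  expect_equal(g[6], 100)
  expect_error(concentration_grid("aspirin"), "unknown drug")
})

test_that("censor bounds map to exactly 0 and 1 for every drug", {
  panel <- all_drug_panel()
  for (i in seq_len(nrow(panel))) {
    expect_identical(normalize_lc50(panel$min_conc[i] / 2, panel$drug[i]), 0)
    expect_identical(normalize_lc50(2 * panel$max_conc[i], panel$drug[i]), 1)
  }
})

test_that("normalization midpoint and round-trip are exact", {
  expect_equal(normalize_lc50(sqrt(0.05 * 20000), "dasatinib"), 0.5)
  set.seed(3)
  panel <- all_drug_panel()
  for (i in seq_len(nrow(panel))) {
    raw <- 10^runif(5, log10(panel$min_conc[i] / 2), log10(2 * panel$max_conc[i]))
    v <- normalize_lc50(raw, panel$drug[i])
    back <- denormalize_lc50(v, panel$drug[i])
    expect_lt(max(abs(back - raw) / raw), 1e-10)
  }
})

test_that("min-max normalization preserves within-drug ranks and agrees with fold-median ranks", {
  set.seed(4)
  raw <- 10^runif(40, log10(0.05), log10(20000))
  v <- normalize_lc50(raw, "dasatinib")
  expect_identical(order(v), order(raw))
  fm <- fold_median_lc50(raw)
  expect_identical(order(fm), order(v))
})

test_that("fold-median values match direct arithmetic", {
  x <- c(1, 2, 4, 8)
  expect_equal(fold_median_lc50(x), log2(x / 3))
  expect_equal(fold_median_lc50(c(5, NA, 5))[1], 0)
  expect_equal(fold_median_lc50(c(4, 1, NA))[1], log2(4 / 2.5))
  expect_warning(out <- fold_median_lc50(c(NA_real_, NA_real_)), "all values missing")
  expect_true(all(is.na(out)))
})

test_that("MRD transform applies the half-detection-limit rule", {
  expect_equal(transform_mrd(0), log10(0.005))
  expect_equal(transform_mrd(0.009), log10(0.005))
  expect_equal(transform_mrd(1), 0)
  expect_equal(transform_mrd(5), log10(5))
  expect_error(transform_mrd(-1), "non-negative")
})

test_that("MRD categories partition the measurement range with left-closed bins", {
  expect_equal(as.character(categorize_mrd(0.5, 15)), "0.01 to <1%")
  expect_equal(as.character(categorize_mrd(5, 15)), ">=5%")
  expect_equal(as.character(categorize_mrd(0.01, 15)), "0.01 to <1%")
  expect_equal(as.character(categorize_mrd(1.2, 42)), ">=1%")
  expect_equal(as.character(categorize_mrd(0.009, 42)), "<0.01%")
  # partition: every value maps to exactly one bin
  set.seed(5)
  vals <- c(0, 10^runif(200, -3, 1.5), 0.01, 1, 5)
  for (day in c(15, 42)) {
    cats <- categorize_mrd(vals, day)
    expect_false(anyNA(cats))
    expect_equal(nlevels(cats), if (day == 15) 4 else 3)
  }
})

test_that("longitudinal MRD groups enumerate the 4 x 2 cross in resistance order", {
  # day-15 categories x day-42 positivity, ordered by increasing resistance
  expect_equal(mrd_longitudinal_group(0.001, 0.001), 1L)
  expect_equal(mrd_longitudinal_group(0.001, 0.5), 2L)
  expect_equal(mrd_longitudinal_group(0.5, 0.001), 3L)
  expect_equal(mrd_longitudinal_group(0.5, 0.5), 4L)
  expect_equal(mrd_longitudinal_group(2, 0.001), 5L)
  expect_equal(mrd_longitudinal_group(2, 0.5), 6L)
  expect_equal(mrd_longitudinal_group(7, 0.001), 7L)
  expect_equal(mrd_longitudinal_group(7, 0.5), 8L)
  expect_true(is.na(mrd_longitudinal_group(NA, 0.5)))
  expect_true(is.na(mrd_longitudinal_group(0.5, NA)))
})

test_that("build_analysis_table assembles the matrix, mask and missingness", {
  est <- data.frame(sample_id = c("A", "A", "B", "C", "C"),
                    drug = c("prednisolone", "dasatinib", "prednisolone",
                             "prednisolone", "dasatinib"),
                    normalized = c(0.2, 0.8, 0.5, 0.9, 0.1))
  pats <- data.frame(patient_id = c("A", "B", "C"))
  out <- build_analysis_table(est, pats)
  expect_equal(dim(out$lc50$values), c(3, 2))
  expect_equal(sum(out$lc50$mask), 1)
  expect_true(out$lc50$mask["B", "dasatinib"])
  expect_equal(out$missingness$observed,
               c(3L, 2L)[match(out$missingness$drug, c("prednisolone", "dasatinib"))])

  dup <- rbind(est, est[1, ])
  expect_error(build_analysis_table(dup, pats), "duplicate")

  empty <- build_analysis_table(est[0, ], pats[0, , drop = FALSE])
  expect_equal(nrow(empty$lc50$values), 0)
})

test_that("lc50_matrix rejects out-of-range values", {
  v <- matrix(c(0.5, 1.2), 1, 2, dimnames = list("P1", c("dasatinib", "prednisolone")))
  expect_error(lc50_matrix(v), "\\[0, 1\\]")
})
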