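test_that("a complete matrix passes through imputation unchanged", {
  x <- toy_lc50()
  imp <- impute_chained(x, m = 3, seed = 1)
  for (mm in imp$imputations) expect_identical(mm, x)
})

test_that("observed cells are never altered and imputed values stay in range", {
  co <- simulate_cohort(cohort_config(n_patients = 150L), seed = 21)
  imp <- impute_chained(co$lc50, m = 3, maxit = 5, seed = 22, min_obs = 10)
  obs <- !co$lc50$mask
  for (mm in imp$imputations) {
    expect_identical(mm[obs], co$lc50$values[obs])
    expect_true(all(mm >= 0 & mm <= 1))
    expect_false(anyNA(mm))
  }
})

test_that("imputation is bit-reproducible under a seed and leaves the RNG stream alone", {
  x <- simulate_mvn_matrix(80, 5, seed = 31)
  set.seed(99); before <- runif(1)
  imp1 <- impute_chained(x, m = 4, maxit = 5, seed = 7)
  imp2 <- impute_chained(x, m = 4, maxit = 5, seed = 7)
  expect_identical(imp1$imputations, imp2$imputations)
  set.seed(99); expect_identical(runif(1), before)
})

test_that("chained imputation beats column-median fill on correlated data", {
  set.seed(41)
  sigma <- matrix(0.6, 8, 8); diag(sigma) <- 1
  truth <- matrix(rnorm(200 * 8), 200, 8) %*% chol(sigma)
  colnames(truth) <- paste0("V", 1:8)
  mask <- simulate_missingness(truth, rate = 0.3)
  x <- truth; x[mask] <- NA
  imp <- impute_chained(x, m = 10, maxit = 5, seed = 42)
  pmm_mean <- Reduce(`+`, imp$imputations) / imp$m
  mae_pmm <- mean(abs(pmm_mean[mask] - truth[mask]))
  med <- x
  for (j in 1:8) med[mask[, j], j] <- median(x[, j], na.rm = TRUE)
  mae_med <- mean(abs(med[mask] - truth[mask]))
  expect_lt(mae_pmm, mae_med)
})

test_that("degenerate inputs raise informative errors", {
  expect_error(impute_chained(matrix(1:10, ncol = 1)), "at least 2 columns")
  x <- matrix(c(NA, NA, 1, 2, NA, 3), 3, 2)
  expect_error(impute_chained(x), "all-missing rows")
  x2 <- simulate_mvn_matrix(40, 4, seed = 1)
  expect_error(impute_chained(x2, on_sparse_column = "error", min_obs = 50),
               "observation threshold")
  expect_warning(
    expect_error(impute_chained(x2, min_obs = 50), "fewer than 2 columns"),
    "excluding sparse"
  )
})

test_that("LOO validation recovers exactly determined cells and reports coverage", {
  set.seed(51)
  a <- runif(60)
  x <- cbind(A = a, B = 2 * a, C = runif(60))   # B is an exact function of A
  cells <- cbind(row = c(5L, 20L), col = c(2L, 2L))
  rep <- loo_validate(x, m = 5, maxit = 5, seed = 52, cells = cells)
  expect_equal(nrow(rep$cells), 2)
  expect_lt(max(abs(rep$cells$imputed_mean - rep$cells$observed)), 0.12)
  expect_true(all(rep$cells$covered == 1))
  expect_true(all(rep$cells$ci_lower <= rep$cells$imputed_mean))
  expect_true(all(rep$cells$imputed_mean <= rep$cells$ci_upper))
})

test_that("LOO coverage on well-specified Gaussian data is near nominal", {
  x <- simulate_mvn_matrix(150, 6, rho = 0.6, missing_rate = 0.3, seed = 61)
  rep <- loo_validate(x, m = 10, maxit = 5, seed = 62, cells = 60L)
  expect_gte(rep$coverage, 0.8)
  expect_lte(rep$coverage, 1.0)
  expect_error(loo_validate(x, cells = 1e6), "more cells")
  expect_error(loo_validate(matrix(1:5, ncol = 1)), "at least 2 columns")
})

test_that("distribution comparison: identical data gives statistic 0, a shift is detected", {
  set.seed(71)
  x <- simulate_mvn_matrix(300, 4, rho = 0.5, missing_rate = 0.3, seed = 71)
  imp <- impute_chained(x, m = 5, maxit = 5, seed = 72)
  # identical observed and "imputed": plant imputations equal to observed deciles
  fake <- imp
  for (i in seq_along(fake$imputations)) {
    for (j in 1:4) {
      miss <- is.na(x[, j])
      fake$imputations[[i]][miss, j] <- sample(x[!miss, j], sum(miss), replace = TRUE)
    }
  }
  out <- compare_distributions(x, fake)
  expect_true(all(out$p > 0.001, na.rm = TRUE))

  shifted <- imp
  for (i in seq_along(shifted$imputations)) {
    miss_all <- is.na(x)
    shifted$imputations[[i]][miss_all] <- shifted$imputations[[i]][miss_all] + 2
  }
  out2 <- compare_distributions(x, shifted)
  expect_true(all(out2$p_bh < 0.05, na.rm = TRUE))
})

test_that("identical observed and imputed vectors give a zero chi-squared statistic", {
  set.seed(91)
  obs_vals <- runif(40)
  x <- matrix(NA_real_, 80, 2, dimnames = list(NULL, c("d1", "d2")))
  x[1:40, 1] <- obs_vals
  x[, 2] <- runif(80)
  completed <- x
  completed[41:80, 1] <- obs_vals   # imputed multiset identical to observed
  imp <- structure(list(imputations = list(completed), m = 1),
                   class = "imputation_set")
  out <- compare_distributions(x, imp)
  expect_equal(out$statistic[out$drug == "d1"], 0)
  expect_equal(out$p[out$drug == "d1"], 1)
  expect_true(is.na(out$statistic[out$drug == "d2"]))  # nothing was missing
})

test_that("coefficient comparison returns r = 1 for identical completed copies", {
  set.seed(81)
  x <- toy_lc50(n_per = 15)
  x <- x + matrix(runif(length(x), -0.05, 0.05), nrow(x))
  x <- pmin(pmax(x, 0), 1)
  mrd <- drop(x %*% c(0.5, 0.2, -0.3, 0.1)) + rnorm(nrow(x), sd = 0.1)
  imp <- structure(list(imputations = list(x, x, x), m = 3),
                   class = "imputation_set")
  out <- compare_coefficients(x, imp, mrd)
  expect_equal(out$r, 1, tolerance = 1e-10)
  expect_equal(out$table$beta_measured, out$table$beta_imputed)
})

test_that("coefficient comparison flags undefined correlations", {
  x <- toy_lc50(n_per = 15)
  mrd <- rep(c(0, 1), each = 15)
  const <- matrix(0.5, nrow(x), 3,
                  dimnames = list(rownames(x), c("d1", "d2", "d3")))
  imp <- structure(list(imputations = list(const), m = 1),
                   class = "imputation_set")
  expect_warning(out <- compare_coefficients(const, imp, mrd), "undefined")
  expect_true(is.na(out$r))
})
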