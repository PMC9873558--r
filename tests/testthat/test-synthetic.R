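test_that("the default cohort matches the design: size, subtype mix, observed cells", {
  props <- with(pharmacotypeR:::subtype_table(), setNames(count / sum(count), subtype))
  freq_err <- obs_cells <- numeric(10)
  for (s in 1:10) {
    co <- simulate_cohort(cohort_config(), seed = 100 + s)
    expect_equal(nrow(co$clinical), 805)
    expect_equal(ncol(co$true_lc50), 18)
    f <- table(factor(co$clinical$subtype, levels = names(props))) / 805
    freq_err[s] <- max(abs(f - props))
    obs_cells[s] <- sum(!co$mask)
  }
  expect_lt(max(freq_err), 0.03)
  expect_true(all(abs(obs_cells - 5447) / 5447 < 0.02))
})

test_that("zero archetype noise reproduces the centroids exactly and seeds reproduce cohorts", {
  cfg <- cohort_config(n_patients = 60L, noise_sd = 0)
  co <- simulate_cohort(cfg, seed = 9)
  arch <- cfg$archetypes
  expect_equal(co$true_lc50, arch[co$true_cluster, ],
               ignore_attr = TRUE)
  co2 <- simulate_cohort(cfg, seed = 9)
  expect_identical(co, co2)
  co3 <- simulate_cohort(cfg, seed = 10)
  expect_false(identical(co$true_lc50, co3$true_lc50))
})

test_that("missingness mechanisms respect their rates and never empty a row", {
  x <- matrix(runif(200 * 18), 200, 18)
  expect_true(all(!simulate_missingness(x, rate = 0)))
  set.seed(11)
  m <- simulate_missingness(x, rate = 0.6)
  expect_true(all(rowSums(!m) >= 1))
  expect_equal(mean(m), 0.6, tolerance = 0.05)
  set.seed(12)
  md <- simulate_missingness(x, mechanism = "drug-dependent",
                             drug_rates = c(rep(0.1, 9), rep(0.9, 9)))
  expect_lt(mean(md[, 1:9]), 0.2)
  expect_gt(mean(md[, 10:18]), 0.8)
  expect_error(simulate_missingness(x, mechanism = "drug-dependent"), "drug_rates")
})

test_that("fully missing data fails downstream with an informative error", {
  cfg <- cohort_config(n_patients = 30L, missing_rate = 1)
  co <- simulate_cohort(cfg, seed = 13)
  expect_error(impute_chained(co$lc50), "all-missing rows")
})

test_that("a noise-free single-coefficient MRD model yields R^2 = 1 on unfloored cases", {
  panel <- all_drug_panel()
  beta <- setNames(rep(0, 18), panel$drug)
  beta["prednisolone"] <- 0.30
  cfg <- cohort_config(n_patients = 300L, beta_day15 = beta, mrd_sd = 0,
                       mrd_age_effect = 0, mrd_wbc_effect = 0,
                       mrd_intercept_day15 = 0.5)
  co <- simulate_cohort(cfg, seed = 14)
  keep <- co$mrd$day15 >= cfg$detection_limit & co$mrd$day15 < 90
  fit <- lm(log10(co$mrd$day15[keep]) ~ co$true_lc50[keep, "prednisolone"])
  expect_gt(suppressWarnings(summary(fit)$r.squared), 1 - 1e-10)  # exact fit
  expect_equal(unname(coef(fit)[2]), 0.30, tolerance = 1e-10)
})

test_that("MRD generation responds to the planted coefficients", {
  cfg <- cohort_config(n_patients = 500L)
  co <- simulate_cohort(cfg, seed = 15)
  z <- transform_mrd(co$mrd$day15)
  lin_pred <- drop(co$true_lc50 %*% cfg$beta_day15)
  expect_gt(cor(lin_pred, z), 0.2)
  # day-42 MRD is attenuated but driven by the same profile
  z42 <- transform_mrd(co$mrd$day42)
  expect_gt(cor(lin_pred, z42), 0.1)
})

test_that("survival generator produces the requested censoring structure", {
  cfg <- cohort_config(n_patients = 200L,
                       followup_range = c(1e6, 1e6 + 1))
  co <- simulate_cohort(cfg, seed = 16)
  keep <- !is.na(co$survival$event)
  expect_true(all(co$survival$event[keep] == 1))   # no administrative censoring
  expect_true(all(co$survival$efs_time[keep] > 0))
  # protocols outside the survival set carry NA follow-up
  drop_idx <- !(co$clinical$protocol %in% cfg$survival_protocols)
  expect_true(all(is.na(co$survival$efs_time[drop_idx])))
  bad <- cohort_config(n_patients = 50L,
                       baseline_hazard = c("TXV low" = -1, "TXV std/high" = 0.02,
                                           "TXVI low" = 0.02, "TXVI std/high" = 0.02))
  expect_error(simulate_cohort(bad, seed = 1), "positive")
})

test_that("viability curves round-trip through the dose-response module", {
  panel <- all_drug_panel()
  set.seed(17)
  for (drug in c("prednisolone", "venetoclax", "ibrutinib")) {
    g <- concentration_grid(drug)
    lc50 <- sqrt(g[3] * g[4])
    cv <- simulate_viability(lc50, drug, hill = 1.2, noise_sd = 0)
    est <- estimate_lc50(cv$concentration, cv$viability)
    expect_equal(est$censor, "interval")
    expect_lt(abs(est$raw_lc50 - lc50) / lc50, 1e-3)
  }
  # LC50 outside the tested range forces the censor rules
  g <- concentration_grid("dasatinib")
  low <- simulate_viability(g[1] / 10, "dasatinib", noise_sd = 0)
  expect_equal(estimate_lc50(low$concentration, low$viability)$censor, "left")
  high <- simulate_viability(g[6] * 10, "dasatinib", noise_sd = 0)
  expect_equal(estimate_lc50(high$concentration, high$viability)$censor, "right")
})

test_that("config validation rejects malformed inputs", {
  expect_error(cohort_config(frobnicate = 1), "unknown config field")
  expect_error(cohort_config(missing_rate = 1.5), "missing_rate")
})
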