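test_that("QC thresholds are strict exactly as specified", {
  expect_true(qc_filter("MTT", blast_fraction = 0.71, optical_density = 0.06))
  expect_false(qc_filter("MTT", blast_fraction = 0.70, optical_density = 0.06))
  expect_false(qc_filter("MTT", blast_fraction = 0.71, optical_density = 0.050))
  expect_true(qc_filter("coculture", viable_blasts = 1000))
  expect_false(qc_filter("coculture", viable_blasts = 999))
  expect_error(qc_filter("MTT", blast_fraction = 0.9), "optical_density")
  expect_error(qc_filter("coculture"), "viable_blasts")
  expect_error(qc_filter("elisa", viable_blasts = 10))
})

test_that("4PL fit recovers noiseless parameters and is deterministic", {
  for (drug in c("asparaginase", "venetoclax", "mercaptopurine")) {
    cv <- noiseless_curve(drug, ec50 = concentration_grid(drug)[3], hill = 1)
    fit <- fit_four_pl(cv$conc, cv$viability)
    expect_true(fit$converged)
    expect_lt(abs(fit$ec50 - cv$conc[3]) / cv$conc[3], 1e-6)
    fit2 <- fit_four_pl(cv$conc, cv$viability)
    expect_identical(fit, fit2)
  }
})

test_that("4PL fit beats the best flat line on a graded curve", {
  g <- concentration_grid("dasatinib")
  v <- c(0.9, 0.8, 0.6, 0.4, 0.2, 0.1)
  fit <- fit_four_pl(g, v)
  flat_rss <- min(vapply(seq(0, 1.5, by = 1e-4),
                         function(c0) sum((v - c0)^2), numeric(1)))
  expect_lt(fit$rss, flat_rss)
})

test_that("flat viability gives a degenerate but non-crashing fit", {
  g <- concentration_grid("vincristine")
  fit <- fit_four_pl(g, rep(1, 6))
  expect_s3_class(fit, "four_pl_fit")
  expect_true(is.finite(fit$rss))
})

test_that("censoring rules fire on endpoint viabilities before any fit", {
  g_asp <- concentration_grid("asparaginase")
  est <- estimate_lc50(g_asp, c(0.4, 0.3, 0.25, 0.2, 0.15, 0.1))
  expect_equal(est$raw_lc50, 0.032 / 2)
  expect_equal(est$censor, "left")

  g_ven <- concentration_grid("venetoclax")
  est <- estimate_lc50(g_ven, c(1, 0.95, 0.9, 0.85, 0.8, 0.75))
  expect_equal(est$raw_lc50, 2 * 100)
  expect_equal(est$censor, "right")
})

test_that("symmetric noiseless curves give LC50 equal to ec50 (dense-grid oracle)", {
  for (drug in c("prednisolone", "trametinib")) {
    g <- concentration_grid(drug)
    ec50 <- sqrt(g[3] * g[4])
    cv <- noiseless_curve(drug, ec50 = ec50, hill = 1.5)
    est <- estimate_lc50(cv$conc, cv$viability)
    expect_equal(est$censor, "interval")
    # dense-grid oracle for the 0.5 crossing of the generating curve
    dense <- 10^seq(log10(g[1]), log10(g[6]), length.out = 20001)
    vd <- 1 / (1 + 10^(1.5 * (log10(dense) - log10(ec50))))
    oracle <- dense[which.min(abs(vd - 0.5))]
    expect_lt(abs(log10(est$raw_lc50) - log10(oracle)), 1e-3)
    expect_lt(abs(log10(est$raw_lc50) - log10(ec50)), 1e-4)
  }
})

test_that("LC50 estimation is invariant to rescaling concentration units", {
  g <- concentration_grid("cytarabine")
  v <- noiseless_curve("cytarabine", ec50 = g[4], hill = 0.8)$viability
  est1 <- estimate_lc50(g, v)
  est2 <- estimate_lc50(g * 1000, v)   # uM -> nM
  expect_equal(est2$raw_lc50 / est1$raw_lc50, 1000, tolerance = 1e-6)
  expect_equal(est1$censor, est2$censor)
})

test_that("monotone decreasing curves crossing 0.5 give interval estimates", {
  set.seed(42)
  for (i in 1:50) {
    drug <- sample(all_drug_panel()$drug, 1)
    g <- concentration_grid(drug)
    v <- sort(runif(6, 0, 1), decreasing = TRUE)
    if (v[1] <= 0.5 || v[6] > 0.5) next
    est <- estimate_lc50(g, v)
    expect_equal(est$censor, "interval")
    expect_gt(est$raw_lc50, g[1] / 2)
    expect_lt(est$raw_lc50, 2 * g[6])
  }
})

test_that("low-noise 4PL refits recover log10 LC50 within 0.1 (property sample)", {
  set.seed(7)
  ok <- 0; tot <- 0
  for (i in 1:100) {
    drug <- all_drug_panel()$drug[(i %% 18) + 1]
    g <- concentration_grid(drug)
    ec50 <- 10^runif(1, log10(g[2]), log10(g[5]))
    hill <- runif(1, 0.7, 2)
    v <- pmax(1 / (1 + 10^(hill * (log10(g) - log10(ec50)))) + rnorm(6, 0, 0.02), 0)
    est <- estimate_lc50(g, v)
    tot <- tot + 1
    ok <- ok + (est$censor == "interval" &&
                  abs(log10(est$raw_lc50) - log10(ec50)) < 0.1)
  }
  expect_gte(ok / tot, 0.95)
})

test_that("fit_lc50_table drives QC, fitting and censoring over a long table", {
  g <- concentration_grid("prednisolone")
  curve <- noiseless_curve("prednisolone", ec50 = g[3])
  long <- rbind(
    data.frame(sample_id = "S1", drug = "prednisolone",
               concentration = g, viability = curve$viability,
               assay_kind = "MTT", blast_fraction = 0.9, optical_density = 0.1),
    data.frame(sample_id = "S2", drug = "prednisolone",
               concentration = g, viability = curve$viability,
               assay_kind = "MTT", blast_fraction = 0.5, optical_density = 0.1)
  )
  out <- fit_lc50_table(long)
  expect_equal(nrow(out), 2)
  s1 <- out[out$sample_id == "S1", ]
  expect_true(s1$qc_pass)
  expect_equal(s1$censor, "interval")
  expect_lt(abs(log10(s1$raw_lc50) - log10(g[3])), 1e-3)
  s2 <- out[out$sample_id == "S2", ]
  expect_false(s2$qc_pass)
  expect_true(is.na(s2$raw_lc50))
  expect_error(fit_lc50_table(long[, -3]), "missing columns")
})
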