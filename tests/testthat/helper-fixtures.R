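# Shared fixtures, built in code at test time.

# Noise-free 4PL viability curve on a drug's grid.
noiseless_curve <- function(drug, ec50, hill = 1, bottom = 0, top = 1) {
  g <- concentration_grid(drug)
  list(conc = g,
       viability = bottom + (top - bottom) /
         (1 + 10^(hill * (log10(g) - log10(ec50)))))
}

# Tiny complete LC50 matrix with block structure (two groups of patients).
toy_lc50 <- function(n_per = 10, drugs = c("prednisolone", "asparaginase",
                                           "dasatinib", "venetoclax")) {
  a <- matrix(rep(c(0.1, 0.2, 0.8, 0.9), each = n_per), n_per, length(drugs))
  b <- matrix(rep(c(0.9, 0.8, 0.2, 0.1), each = n_per), n_per, length(drugs))
  values <- rbind(a, b)
  dimnames(values) <- list(sprintf("P%02d", seq_len(2 * n_per)), drugs)
  values
}

# Brute-force product-limit estimator for uncensored/censored toy data.
brute_km <- function(time, event, at) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  for (t in ut[ut <= at]) {
    d <- sum(time == t & event == 1)
    n <- sum(time >= t)
    s <- s * (1 - d / n)
  }
  s
}

# Brute-force two-group log-rank statistic (squared standardized O-E sum).
brute_logrank <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  ut <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}
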