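# Synthetic pharmacotyping cohort with exported ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# 805 patients spanning 23 molecular subtypes at the observed cohort
# frequencies, six drug-sensitivity archetypes (cluster centroids on the
# normalized [0, 1] LC50 scale) with Gaussian patient-level noise, ~62%
# missing LC50 cells (calibrated so ~5,447 of the 805 x 18 cells are
# observed), log10 MRD generated linearly from the true LC50 profile, and
# proportional-hazards event-free survival differing by cluster. Every
# ground-truth quantity (true complete matrix, true cluster labels, true
# beta vector) is exported so recovery analyses never re-derive the model.

subtype_table <- function() {
  s <- rbind(
    c("ETV6-RUNX1", 190, "B"), c("Hyperdiploid", 178, "B"),
    c("T-ALL", 113, "T"), c("B Other", 59, "B"),
    c("PAX5alt", 36, "B"), c("DUX4", 34, "B"), c("KMT2A", 32, "B"),
    c("TCF3-PBX1", 30, "B"), c("BCR-ABL1", 21, "B"), c("CRLF2", 21, "B"),
    c("ETP", 16, "T"), c("ETV6-RUNX1-like", 14, "B"),
    c("BCR-ABL1-like", 13, "B"), c("iAMP21", 9, "B"), c("MEF2D", 9, "B"),
    c("Near haploid", 8, "B"), c("ZNF384", 8, "B"), c("NUTM1", 5, "B"),
    c("PAX5 P80R", 3, "B"), c("Low hypodiploid", 2, "B"),
    c("TCF3-HLF", 2, "B"), c("BCL2/MYC", 1, "B"), c("IKZF1 N159Y", 1, "B")
  )
  data.frame(subtype = s[, 1], count = as.numeric(s[, 2]), lineage = s[, 3],
             stringsAsFactors = FALSE)
}

# Six archetype centroids on the normalized LC50 scale (rows: clusters
# I-VI, columns: panel drugs). Qualitative pattern: I = dasatinib/ibrutinib
# sensitive; II = venetoclax/trametinib sensitive; III = asparaginase +
# glucocorticoid sensitive; IV = glucocorticoid sensitive but asparaginase
# resistant; V = pan-cytotoxic resistant with partial targeted sensitivity;
# VI = glucocorticoid resistant but venetoclax/bortezomib sensitive (the
# ZNF384-like pattern). Centroid values are free simulation parameters, not
# measured quantities; they are chosen well-separated so that cluster
# identity remains identifiable from the ~7 cells per patient that survive
# the missingness mask (a recovery simulation is meaningless when even an
# oracle cannot recover the planted labels).
default_archetypes <- function(panel = all_drug_panel()) {
  # column order: asp, bort, chz, cyta, dasa, dauno, dexa, ibru, merc, nela,
  #               pano, pred, ruxo, thio, tram, vene, vincr, vori
  a <- rbind(
    I   = c(0.63, 0.43, 0.11, 0.57, 0.03, 0.57, 0.50, 0.03, 0.57, 0.43,
            0.24, 0.57, 0.05, 0.57, 0.43, 0.70, 0.50, 0.37),
    II  = c(0.30, 0.57, 0.76, 0.37, 0.97, 0.37, 0.24, 0.76, 0.37, 0.63,
            0.57, 0.24, 0.76, 0.37, 0.03, 0.03, 0.30, 0.63),
    III = c(0.03, 0.24, 0.97, 0.24, 0.97, 0.24, 0.03, 0.97, 0.17, 0.76,
            0.70, 0.03, 0.97, 0.14, 0.97, 0.57, 0.17, 0.24),
    IV  = c(0.97, 0.50, 0.43, 0.24, 0.76, 0.70, 0.08, 0.43, 0.24, 0.24,
            0.43, 0.03, 0.57, 0.24, 0.76, 0.95, 0.70, 0.76),
    V   = c(0.97, 0.76, 0.30, 0.97, 0.95, 0.97, 0.97, 0.24, 0.97, 0.95,
            0.76, 0.97, 0.37, 0.97, 0.17, 0.24, 0.97, 0.82),
    VI  = c(0.57, 0.05, 0.63, 0.63, 0.63, 0.63, 0.97, 0.63, 0.63, 0.57,
            0.24, 0.97, 0.63, 0.63, 0.50, 0.17, 0.63, 0.43)
  )
  colnames(a) <- panel$drug
  a
}

# Subtype -> archetype assignment probabilities (rows sum to 1), following
# the qualitative cluster compositions: BCR-ABL1 and half of T-ALL in the
# dasatinib-sensitive cluster I, hyperdiploid enriched in II, ETV6-RUNX1 in
# III, DUX4/KMT2A and heterogeneous B subtypes in IV, ETP and resistant
# subtypes in V, glucocorticoid-resistant subtypes (incl. TCF3-HLF) in VI.
default_cluster_probs <- function() {
  st <- subtype_table()$subtype
  p <- matrix(0, length(st), 6, dimnames = list(st, c("I", "II", "III", "IV", "V", "VI")))
  set_p <- function(sub, probs) p[sub, ] <<- probs
  set_p("ETV6-RUNX1",      c(0,    0,    0.80, 0.20, 0,    0))
  set_p("Hyperdiploid",    c(0,    0.45, 0.30, 0.25, 0,    0))
  set_p("T-ALL",           c(0.50, 0,    0,    0,    0.35, 0.15))
  set_p("B Other",         c(0,    0.20, 0,    0.50, 0,    0.30))
  set_p("PAX5alt",         c(0,    0,    0,    0.60, 0,    0.40))
  set_p("DUX4",            c(0,    0,    0,    0.80, 0,    0.20))
  set_p("KMT2A",           c(0,    0,    0,    0.30, 0.20, 0.50))
  set_p("TCF3-PBX1",       c(0.30, 0,    0.20, 0.50, 0,    0))
  set_p("BCR-ABL1",        c(0.80, 0,    0,    0,    0,    0.20))
  set_p("CRLF2",           c(0,    0,    0,    0.20, 0.30, 0.50))
  set_p("ETP",             c(0,    0,    0,    0,    0.70, 0.30))
  set_p("ETV6-RUNX1-like", c(0,    0.50, 0,    0.50, 0,    0))
  set_p("BCR-ABL1-like",   c(0,    0,    0,    0,    0.40, 0.60))
  set_p("iAMP21",          c(0,    0,    0,    0.70, 0,    0.30))
  set_p("MEF2D",           c(0,    0,    0,    0.70, 0,    0.30))
  set_p("Near haploid",    c(0,    0,    0,    0,    0.50, 0.50))
  set_p("ZNF384",          c(0,    0.40, 0,    0,    0,    0.60))
  set_p("NUTM1",           c(0,    0,    0.60, 0.40, 0,    0))
  set_p("PAX5 P80R",       c(0,    0,    0,    0,    1,    0))
  set_p("Low hypodiploid", c(0,    0,    0,    0,    1,    0))
  set_p("TCF3-HLF",        c(0,    0,    0,    0,    0,    1))
  set_p("BCL2/MYC",        c(0,    0,    0,    0,    1,    0))
  set_p("IKZF1 N159Y",     c(0,    0,    0,    1,    0,    0))
  stopifnot(all(abs(rowSums(p) - 1) < 1e-12))
  p
}

# Day-15 B-lineage MRD regression coefficients (log10 MRD per unit
# normalized LC50) used as generator defaults; day-42 coefficients are
# these attenuated by `day42_attenuation`.
default_beta_day15 <- function(panel = all_drug_panel()) {
  beta <- stats::setNames(rep(0, nrow(panel)), panel$drug)
  beta[c("asparaginase", "prednisolone", "dexamethasone",
         "mercaptopurine", "thioguanine", "cytarabine")] <-
    c(0.30, 0.30, 0.28, 0.17, 0.18, 0.15)
  beta
}

#' Configuration of the synthetic pharmacotyping cohort
#'
#' All defaults encode the study conditions the analysis assumes: 805
#' patients, the 18-drug panel, the observed subtype frequencies, six
#' drug-sensitivity archetypes, a missingness rate leaving ~5,447 observed
#' cells, a linear log10-MRD model and proportional-hazards EFS. Any field
#' can be overridden by name.
#'
#' @param ... named overrides of the default fields.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(...) {
  panel <- all_drug_panel()
  cfg <- list(
    n_patients = 805L,
    panel = panel,
    subtypes = subtype_table(),
    archetypes = default_archetypes(panel),
    cluster_probs = default_cluster_probs(),
    noise_sd = 0.12,
    missing_rate = 1 - 5447 / (805 * 18),   # ~0.6241 missing cells
    missing_mechanism = "MCAR",
    drug_missing_rates = NULL,
    beta_day15 = default_beta_day15(panel),
    day42_attenuation = 0.7,
    mrd_intercept_day15 = -2.0,
    mrd_intercept_day42 = -2.8,
    mrd_sd = 1.0,
    mrd_age_effect = 0.02,      # log10 MRD per year of age (centered at 7)
    mrd_wbc_effect = 0.25,      # log10 MRD per log10 WBC (centered)
    detection_limit = 0.01,     # percent
    mrd_cap = 90,               # percent; upper truncation of simulated MRD
    cluster_loghr = stats::setNames(
      c(log(3.0), 0, log(0.5), log(0.5), log(1.8), log(1.4)),
      c("I", "II", "III", "IV", "V", "VI")),
    baseline_hazard = c("TXV low" = 0.018, "TXV std/high" = 0.030,
                        "TXVI low" = 0.015, "TXVI std/high" = 0.025),
    followup_range = c(4, 12),  # years of administrative follow-up
    survival_protocols = c("TXV", "TXVI"),
    protocol_probs = c(TXV = 0.40, TXVI = 0.42, TXVII = 0.18),
    viability_hill = 1.2,
    viability_sd = 0.05
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  props <- cfg$subtypes$count / sum(cfg$subtypes$count)
  if (abs(sum(props) - 1) > 1e-8) stop("subtype proportions must sum to 1")
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1) stop("missing_rate must be in [0, 1]")
  if (nrow(cfg$archetypes) != ncol(cfg$cluster_probs)) {
    stop("archetype count must match cluster_probs columns")
  }
  structure(cfg, class = "cohort_config")
}

#' Simulate the MCAR / drug-dependent missingness mask
#'
#' @param true_values complete matrix (patients x drugs).
#' @param rate overall missing-cell probability (the default leaves ~5,447
#'   observed cells on the full 805 x 18 grid).
#' @param mechanism `"MCAR"` or `"drug-dependent"` (per-drug rates).
#' @param drug_rates per-drug missing probabilities (drug-dependent mode).
#' @return Logical matrix, `TRUE` = missing. Rows that would lose every
#'   cell keep one randomly chosen observed cell, so no all-missing rows
#'   are produced.
#' @export
simulate_missingness <- function(true_values, rate = 1 - 5447 / (805 * 18),
                                 mechanism = c("MCAR", "drug-dependent"),
                                 drug_rates = NULL) {
  mechanism <- match.arg(mechanism)
  n <- nrow(true_values); p <- ncol(true_values)
  if (mechanism == "MCAR") {
    mask <- matrix(stats::runif(n * p) < rate, n, p)
  } else {
    if (is.null(drug_rates)) stop("drug-dependent mechanism needs drug_rates")
    drug_rates <- rep_len(drug_rates, p)
    mask <- matrix(stats::runif(n * p), n, p) <
      matrix(drug_rates, n, p, byrow = TRUE)
  }
  dimnames(mask) <- dimnames(true_values)
  all_missing <- rowSums(!mask) == 0
  if (any(all_missing) && rate < 1 && p > 0) {
    for (i in which(all_missing)) mask[i, sample.int(p, 1)] <- FALSE
  }
  mask
}

#' Simulate day-15 and day-42 MRD from the true LC50 profile
#'
#' log10 MRD = intercept + sum(beta_d * LC50_d) + age and WBC terms +
#' Gaussian noise; back-transformed to percent and truncated at 90%. Day-42
#' coefficients are the day-15 vector attenuated by `day42_attenuation`
#' (later time points reflect more cumulative clearance).
#'
#' @param true_values complete true LC50 matrix.
#' @param clinical data.frame with `age` and `wbc`.
#' @param config a [cohort_config()].
#' @return data.frame with `day15`, `day42` (percent; values below the
#'   detection limit represent below-LOD measurements).
#' @export
simulate_mrd <- function(true_values, clinical, config = cohort_config()) {
  beta <- config$beta_day15
  if (length(beta) != ncol(true_values)) stop("beta length must equal n_drugs")
  n <- nrow(true_values)
  covar <- config$mrd_age_effect * (clinical$age - 7) +
    config$mrd_wbc_effect * (log10(clinical$wbc) - mean(log10(clinical$wbc)))
  z15 <- config$mrd_intercept_day15 + drop(true_values %*% beta) + covar +
    stats::rnorm(n, sd = config$mrd_sd)
  z42 <- config$mrd_intercept_day42 +
    drop(true_values %*% (beta * config$day42_attenuation)) + covar +
    stats::rnorm(n, sd = config$mrd_sd)
  data.frame(day15 = pmin(10^z15, config$mrd_cap),
             day42 = pmin(10^z42, config$mrd_cap))
}

#' Simulate proportional-hazards event-free survival by cluster
#'
#' Exponential event times with hazard `baseline(arm) * exp(loghr[cluster])`
#' and independent uniform administrative censoring. Patients outside the
#' survival protocols (immature follow-up) get `NA` times.
#'
#' @param clinical data.frame with `protocol` and `arm`.
#' @param cluster per-patient true cluster labels (names of
#'   `config$cluster_loghr`).
#' @param config a [cohort_config()].
#' @return data.frame with `efs_time` (years), `event` (0/1), `arm`.
#' @export
simulate_survival <- function(clinical, cluster, config = cohort_config()) {
  if (any(config$baseline_hazard <= 0)) stop("baseline hazards must be positive")
  n <- nrow(clinical)
  hz <- config$baseline_hazard[clinical$arm] *
    exp(config$cluster_loghr[as.character(cluster)])
  t_event <- stats::rexp(n) / hz
  t_cens <- stats::runif(n, config$followup_range[1], config$followup_range[2])
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  out <- data.frame(efs_time = time, event = event, arm = clinical$arm,
                    stringsAsFactors = FALSE)
  drop_idx <- !(clinical$protocol %in% config$survival_protocols)
  out$efs_time[drop_idx] <- NA_real_
  out$event[drop_idx] <- NA_integer_
  out
}

#' Simulate a 6-point viability curve for one sample-drug pair
#'
#' Forward 4PL generator (bottom 0, top 1, configurable hill, ec50 = the
#' raw LC50) plus Gaussian noise, truncated at 0.
#'
#' @param raw_lc50 raw LC50 in the drug's units (may lie outside the grid).
#' @param drug drug id.
#' @param panel drug panel.
#' @param hill hill slope of the generating curve.
#' @param noise_sd viability noise standard deviation.
#' @return data.frame with `concentration`, `viability`.
#' @export
simulate_viability <- function(raw_lc50, drug, panel = all_drug_panel(),
                               hill = 1.2, noise_sd = 0.05) {
  grid <- concentration_grid(drug, panel)
  v <- four_pl(grid, bottom = 0, top = 1, hill = hill, ec50 = raw_lc50)
  v <- pmax(v + stats::rnorm(length(grid), sd = noise_sd), 0)
  data.frame(concentration = grid, viability = v)
}

#' Simulate the full synthetic cohort
#'
#' Draws patients (subtype, lineage, age, WBC, sex, ancestry, NCI risk,
#' protocol and arm), assigns each patient a drug-sensitivity archetype via
#' the subtype-to-cluster probabilities, builds the true LC50 matrix
#' (archetype + noise, clamped to \[0, 1\]), applies the missingness mask,
#' and generates MRD and EFS from the true values.
#'
#' @param config a [cohort_config()].
#' @param seed integer master seed; the same seed reproduces the cohort
#'   bit-for-bit.
#' @return Object of class `syn_cohort`: list with `clinical`, `true_lc50`
#'   (complete matrix), `lc50` (observed [lc50_matrix()]), `mask`,
#'   `true_cluster`, `mrd`, `survival`, `beta_day15`, `config`, `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  with_seed(seed, {
    n <- config$n_patients
    st <- config$subtypes
    props <- st$count / sum(st$count)
    # fixed cohort composition (largest-remainder apportionment of the
    # subtype frequencies), randomly ordered across patients
    quota <- floor(props * n)
    rem <- n - sum(quota)
    if (rem > 0) {
      extra <- order(props * n - quota, decreasing = TRUE)[seq_len(rem)]
      quota[extra] <- quota[extra] + 1
    }
    subtype <- sample(rep(st$subtype, times = quota))
    lineage <- st$lineage[match(subtype, st$subtype)]

    age_group <- sample(1:3, n, replace = TRUE, prob = c(0.009, 0.749, 0.242))
    age <- c(stats::runif(n, 0.3, 1), stats::runif(n, 1, 10),
             stats::runif(n, 10, 18.9))[(age_group - 1) * n + seq_len(n)]
    wbc <- 10^stats::rnorm(n, 1.28, 0.65)
    sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.547, 0.453))
    anc_p <- c(European = 0.660, African = 0.129, `Admixed American` = 0.122,
               Other = 0.081, Unknown = 0.009)
    ancestry <- sample(names(anc_p), n, replace = TRUE, prob = anc_p / sum(anc_p))
    nci_risk <- ifelse(age < 10 & wbc < 50, "standard", "high")
    protocol <- sample(names(config$protocol_probs), n, replace = TRUE,
                       prob = config$protocol_probs)
    arm <- paste(protocol, ifelse(nci_risk == "standard", "low", "std/high"))

    clusters <- rownames(config$archetypes)
    cp <- config$cluster_probs[subtype, , drop = FALSE]
    true_cluster <- apply(cp, 1, function(pr) sample(clusters, 1, prob = pr))

    p <- ncol(config$archetypes)
    true_lc50 <- config$archetypes[true_cluster, , drop = FALSE] +
      matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
    true_lc50 <- clamp01(true_lc50, warn = FALSE)
    ids <- sprintf("P%04d", seq_len(n))
    dimnames(true_lc50) <- list(ids, colnames(config$archetypes))

    mask <- simulate_missingness(true_lc50, rate = config$missing_rate,
                                 mechanism = config$missing_mechanism,
                                 drug_rates = config$drug_missing_rates)
    observed <- true_lc50
    observed[mask] <- NA

    clinical <- data.frame(patient_id = ids, subtype = subtype,
                           lineage = lineage, age = age, wbc = wbc, sex = sex,
                           ancestry = ancestry, nci_risk = nci_risk,
                           protocol = protocol, arm = arm,
                           stringsAsFactors = FALSE)
    mrd <- cbind(patient_id = ids,
                 simulate_mrd(true_lc50, clinical, config))
    surv <- cbind(patient_id = ids,
                  simulate_survival(clinical, true_cluster, config))

    structure(list(clinical = clinical, true_lc50 = true_lc50,
                   lc50 = lc50_matrix(observed), mask = mask,
                   true_cluster = stats::setNames(true_cluster, ids),
                   mrd = mrd, survival = surv,
                   beta_day15 = config$beta_day15,
                   config = config, seed = seed),
              class = "syn_cohort")
  })
}

#' @export
print.syn_cohort <- function(x, ...) {
  cat(sprintf("syn_cohort: %d patients x %d drugs, %d observed LC50 cells\n",
              nrow(x$true_lc50), ncol(x$true_lc50), sum(!x$mask)))
  invisible(x)
}

#' Multivariate-normal validation matrix with MCAR missingness
#'
#' Equicorrelated Gaussian matrix used to check imputation calibration on
#' data where the per-column linear imputation model is exactly correct.
#'
#' @param n,p dimensions.
#' @param rho common pairwise correlation.
#' @param missing_rate MCAR cell-missingness probability.
#' @param seed integer seed.
#' @return Numeric matrix with `NA` for missing cells (no all-missing rows).
#' @export
simulate_mvn_matrix <- function(n = 200L, p = 8L, rho = 0.6,
                                missing_rate = 0.3, seed = NULL) {
  with_seed(seed, {
    sigma <- matrix(rho, p, p); diag(sigma) <- 1
    x <- matrix(stats::rnorm(n * p), n, p) %*% chol(sigma)
    colnames(x) <- paste0("V", seq_len(p))
    mask <- simulate_missingness(x, rate = missing_rate)
    x[mask] <- NA
    x
  })
}
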