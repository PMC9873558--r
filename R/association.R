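# Drug-MRD association by multiple linear regression, and nonparametric
# group comparisons of normalized LC50 values.
#
# The regression models log10 MRD as the response and one drug's normalized
# LC50 as the predictor, adjusting for treatment protocol (categorical),
# age and WBC at diagnosis. Because LC50 is scaled to [0, 1], the
# coefficient beta is the log10 MRD difference between the most resistant
# (LC50 = 1) and most sensitive (LC50 = 0) patients: beta = 0.30 means MRD
# is twice as high in resistant patients, beta = -0.30 half as high.

#' Regress log10 MRD on one drug's normalized LC50
#'
#' @param lc50 normalized LC50 values (one drug), `NA` for unmeasured.
#' @param mrd_log10 log10-transformed MRD (see [transform_mrd()]).
#' @param covariates optional data.frame with columns among `protocol`
#'   (categorical), `age` (years) and `wbc` (x 10^9/L); `wbc` enters
#'   log10-transformed when `log_wbc = TRUE` (default; the raw scale is also
#'   supported).
#' @param min_n minimum number of complete cases.
#' @param log_wbc log10-transform the WBC covariate.
#' @return List with `beta`, `se`, `ci_lower`, `ci_upper`, `p`, `n`.
#' @export
regress_lc50_on_mrd <- function(lc50, mrd_log10, covariates = NULL,
                                min_n = 10L, log_wbc = TRUE) {
  df <- data.frame(lc50 = lc50, mrd = mrd_log10)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if ("protocol" %in% names(covariates)) df$protocol <- factor(covariates$protocol)
    if ("age" %in% names(covariates)) df$age <- as.numeric(covariates$age)
    if ("wbc" %in% names(covariates)) {
      w <- as.numeric(covariates$wbc)
      df$wbc <- if (log_wbc) log10(w) else w
    }
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < min_n) {
    stop(sprintf("only %d complete cases (minimum %d)", nrow(df), min_n))
  }
  if (stats::sd(df$lc50) == 0) {
    stop("LC50 predictor is constant; coefficient undefined")
  }
  if ("protocol" %in% names(df)) df$protocol <- droplevels(df$protocol)
  rhs <- c("lc50", intersect(c("protocol", "age", "wbc"), names(df)))
  fit <- stats::lm(stats::reformulate(rhs, response = "mrd"), data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear terms: ", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, "lc50")
  list(beta = unname(sm["lc50", "Estimate"]),
       se = unname(sm["lc50", "Std. Error"]),
       ci_lower = unname(ci[1]), ci_upper = unname(ci[2]),
       p = unname(sm["lc50", "Pr(>|t|)"]),
       n = nrow(df))
}

#' Drug-by-drug MRD association table
#'
#' Runs [regress_lc50_on_mrd()] for every drug column and BH-adjusts the p
#' values across the drug family. Intended to be run separately per lineage
#' (B and T cell ALL) and per MRD time point.
#'
#' @param x [lc50_matrix()] or numeric matrix.
#' @param mrd_log10 log10 MRD, one value per row of `x`.
#' @param covariates see [regress_lc50_on_mrd()].
#' @param timepoint label stored in the output (e.g. `"day15"`).
#' @inheritParams regress_lc50_on_mrd
#' @return data.frame, one row per drug: `drug`, `timepoint`, `beta`, `se`,
#'   `ci_lower`, `ci_upper`, `p`, `p_bh`, `fold_change`, `n`.
#' @export
associate_mrd <- function(x, mrd_log10, covariates = NULL, timepoint = "day15",
                          min_n = 10L, log_wbc = TRUE) {
  values <- as_values_matrix(x)
  rows <- lapply(colnames(values), function(d) {
    res <- tryCatch(
      regress_lc50_on_mrd(values[, d], mrd_log10, covariates,
                          min_n = min_n, log_wbc = log_wbc),
      error = function(e) NULL
    )
    if (is.null(res)) {
      return(data.frame(drug = d, timepoint = timepoint, beta = NA_real_,
                        se = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                        p = NA_real_, n = NA_integer_, stringsAsFactors = FALSE))
    }
    data.frame(drug = d, timepoint = timepoint, beta = res$beta, se = res$se,
               ci_lower = res$ci_lower, ci_upper = res$ci_upper, p = res$p,
               n = res$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- NA_real_
  ok <- !is.na(out$p)
  out$p_bh[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out$fold_change <- interpret_beta(out$beta)
  out
}

#' MRD fold change implied by a regression coefficient
#'
#' `10^beta`: the multiplicative MRD difference between the most resistant
#' (normalized LC50 = 1) and most sensitive (LC50 = 0) patients.
#'
#' @param beta regression coefficient on the log10 MRD scale.
#' @export
#' @examples
#' interpret_beta(0.30)   # ~2: MRD twice as high
#' interpret_beta(-0.30)  # ~0.5: half as high
interpret_beta <- function(beta) 10^beta

#' Nonparametric comparison of LC50 between patient groups
#'
#' Two groups are compared with a two-sided Mann-Whitney U-test (exact for
#' combined n <= 12 without ties, normal approximation with tie correction
#' otherwise); more than two groups with a Kruskal-Wallis test.
#'
#' @param values normalized LC50 values for one drug.
#' @param groups grouping vector (factor or coercible).
#' @param min_per_group minimum measured values per group.
#' @return List with `test`, `statistic`, `p`, `medians` (per group) and
#'   `n` (per group).
#' @export
compare_groups <- function(values, groups, min_per_group = 3L) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  sizes <- table(groups)
  if (nlevels(groups) < 2) stop("need at least 2 non-empty groups")
  if (any(sizes < min_per_group)) {
    stop("each group needs at least ", min_per_group, " measured values")
  }
  medians <- c(tapply(values, groups, stats::median))
  if (length(unique(values)) == 1L) {
    warning("all values tied; p = 1")
    return(list(test = "degenerate", statistic = 0, p = 1,
                medians = medians, n = as.integer(sizes)))
  }
  if (nlevels(groups) == 2) {
    a <- values[groups == levels(groups)[1]]
    b <- values[groups == levels(groups)[2]]
    exact <- (length(a) + length(b)) <= 12 && !anyDuplicated(values)
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = !exact)
    )
    list(test = "mann-whitney", statistic = unname(wt$statistic), p = wt$p.value,
         medians = medians, n = as.integer(sizes))
  } else {
    kt <- stats::kruskal.test(values, groups)
    list(test = "kruskal-wallis", statistic = unname(kt$statistic),
         p = kt$p.value, medians = medians, n = as.integer(sizes))
  }
}

#' Trend of LC50 across the longitudinal MRD groups
#'
#' Kruskal-Wallis test of one drug's LC50 across the eight longitudinal MRD
#' groups (see [mrd_longitudinal_group()]); group medians are returned for
#' plotting.
#'
#' @param values normalized LC50 values for one drug.
#' @param groups longitudinal group labels (1..8 or any factor).
#' @return List with `statistic`, `df`, `p`, `medians`, `n`.
#' @export
trend_across_mrd_groups <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep], levels = sort(unique(groups[keep]))))
  if (nlevels(groups) < 2) stop("need at least 2 non-empty MRD groups")
  medians <- c(tapply(values, groups, stats::median))
  n <- as.integer(table(groups))
  if (length(unique(values)) == 1L) {
    warning("all values identical; p = 1")
    return(list(statistic = 0, df = nlevels(groups) - 1L, p = 1,
                medians = medians, n = n))
  }
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, medians = medians, n = n)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard BH step-up, optionally within explicit test families.
#'
#' @param p p values in \[0, 1\].
#' @param family optional vector of family labels; adjustment is applied
#'   within each family separately.
#' @export
bh_adjust <- function(p, family = NULL) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p values must lie in [0, 1]")
  if (is.null(family)) return(stats::p.adjust(p, method = "BH"))
  out <- rep(NA_real_, length(p))
  for (f in unique(family)) {
    i <- which(family == f)
    out[i] <- stats::p.adjust(p[i], method = "BH")
  }
  out
}
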