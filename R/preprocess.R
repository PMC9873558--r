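# Normalization of raw LC50 values and MRD transforms.
#
# Raw LC50 values (with censored values already assigned to min_conc/2 or
# 2*max_conc) are log10-transformed and min-max normalized per drug so the
# censor bounds map exactly to 0 (most sensitive) and 1 (most resistant):
#
#   LC50_normalized = (log10 LC50 - log10(min/2)) / (log10(2*max) - log10(min/2))
#
# Min-max normalization on the log scale is invariant to the log base; base
# 10 is fixed here for reproducibility.

#' Min-max normalize raw LC50 values onto \[0, 1\]
#'
#' @param raw_lc50 raw LC50 values in the drug's concentration units
#'   (censored values already at `min_conc/2` or `2*max_conc`).
#' @param drug drug id (scalar or vector recycled against `raw_lc50`).
#' @param panel drug panel, see [all_drug_panel()].
#' @return Normalized values in \[0, 1\]; left-censored inputs map to exactly
#'   0 and right-censored inputs to exactly 1.
#' @export
#' @examples
#' normalize_lc50(0.016, "asparaginase")                 # 0 (left censor bound)
#' normalize_lc50(20000, "dasatinib")                    # 1 (right censor bound)
#' normalize_lc50(sqrt(0.05 * 20000), "dasatinib")       # 0.5 (log midpoint)
normalize_lc50 <- function(raw_lc50, drug, panel = all_drug_panel()) {
  i <- match_drug(drug, panel)
  lo <- log10(panel$min_conc[i] / 2)
  hi <- log10(2 * panel$max_conc[i])
  if (any(!is.na(raw_lc50) & raw_lc50 <= 0)) stop("raw LC50 must be positive")
  clamp01((log10(raw_lc50) - lo) / (hi - lo))
}

#' Invert the min-max normalization back to a raw concentration
#'
#' @inheritParams normalize_lc50
#' @param value normalized LC50 in \[0, 1\].
#' @export
denormalize_lc50 <- function(value, drug, panel = all_drug_panel()) {
  i <- match_drug(drug, panel)
  lo <- log10(panel$min_conc[i] / 2)
  hi <- log10(2 * panel$max_conc[i])
  if (any(!is.na(value) & (value < -1e-8 | value > 1 + 1e-8))) {
    stop("normalized values must lie in [0, 1]")
  }
  10^(lo + value * (hi - lo))
}

#' Log2 fold change from the per-drug median LC50
#'
#' Alternative normalization: `log2(raw / median)` with the median computed
#' over the measured (non-missing) values of the drug.
#'
#' @param raw_lc50 numeric vector of one drug's raw LC50 values (may contain
#'   `NA`).
#' @export
fold_median_lc50 <- function(raw_lc50) {
  if (all(is.na(raw_lc50))) {
    warning("all values missing; returning NA column")
    return(raw_lc50)
  }
  med <- stats::median(raw_lc50, na.rm = TRUE)
  log2(raw_lc50 / med)
}

#' Log10-transform MRD with below-detection handling
#'
#' MRD values below the detection limit (default 0.01%) are assigned half
#' the detection limit before log-transformation.
#'
#' @param raw MRD in percent (non-negative).
#' @param detection_limit detection limit in percent.
#' @export
#' @examples
#' transform_mrd(0)      # log10(0.005) = -2.301
#' transform_mrd(1)      # 0
transform_mrd <- function(raw, detection_limit = 0.01) {
  if (any(!is.na(raw) & raw < 0)) stop("MRD must be non-negative")
  out <- ifelse(raw < detection_limit, log10(detection_limit / 2), log10(raw))
  out[is.na(raw)] <- NA_real_
  out
}

mrd_levels <- function(day) {
  if (day == 15) c("<0.01%", "0.01 to <1%", "1 to <5%", ">=5%")
  else if (day == 42) c("<0.01%", "0.01 to <1%", ">=1%")
  else stop("day must be 15 or 42")
}

#' Categorize MRD into the clinical bins
#'
#' Day 15 uses four bins (<0.01%; 0.01 to <1%; 1 to <5%; >=5%), day 42
#' three (<0.01%; 0.01 to <1%; >=1%); all boundaries are closed on the left.
#'
#' @param raw MRD in percent.
#' @param day 15 or 42.
#' @return Ordered factor.
#' @export
categorize_mrd <- function(raw, day) {
  raw <- as.numeric(raw)
  if (any(!is.na(raw) & raw < 0)) stop("MRD must be non-negative")
  breaks <- if (day == 15) c(-Inf, 0.01, 1, 5, Inf) else c(-Inf, 0.01, 1, Inf)
  cut(raw, breaks = breaks, labels = mrd_levels(day), right = FALSE,
      ordered_result = TRUE)
}

#' Longitudinal MRD group (1-8) from day 15 and day 42 measurements
#'
#' Crosses the four day-15 categories with day-42 positivity (>= 0.01%) into
#' eight groups ordered by increasing resistance: group 1 is day-15 < 0.01%
#' and day-42 negative; group 8 is day-15 >= 5% and day-42 positive. Within
#' each day-15 category the day-42-negative group precedes the positive one.
#'
#' @param day15_raw,day42_raw MRD in percent.
#' @param detection_limit positivity threshold in percent.
#' @return Integer group in 1..8, `NA` when either time point is missing.
#' @export
mrd_longitudinal_group <- function(day15_raw, day42_raw, detection_limit = 0.01) {
  c15 <- as.integer(categorize_mrd(day15_raw, 15))
  pos42 <- as.integer(!is.na(day42_raw) & day42_raw >= detection_limit)
  out <- 2L * (c15 - 1L) + pos42 + 1L
  out[is.na(day15_raw) | is.na(day42_raw)] <- NA_integer_
  out
}

#' Patient-by-drug LC50 matrix
#'
#' Thin container for the central analysis object: a patients x drugs matrix
#' of normalized LC50 values with `NA` marking unmeasured cells.
#'
#' @param values numeric matrix (patients x drugs) with row and column
#'   names; observed entries must lie in \[0, 1\].
#' @return Object of class `lc50_matrix`.
#' @export
lc50_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("values must have drug column names")
  if (is.null(rownames(values))) rownames(values) <- as.character(seq_len(nrow(values)))
  obs <- values[!is.na(values)]
  if (length(obs) && (min(obs) < -1e-8 || max(obs) > 1 + 1e-8)) {
    stop("observed normalized LC50 values must lie in [0, 1]")
  }
  structure(list(values = values, mask = is.na(values)), class = "lc50_matrix")
}

#' @export
print.lc50_matrix <- function(x, ...) {
  cat(sprintf("lc50_matrix: %d patients x %d drugs, %d observed cells (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values), sum(!x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' @export
as.matrix.lc50_matrix <- function(x, ...) x$values

# Accept either an lc50_matrix or a plain numeric matrix.
as_values_matrix <- function(x) {
  if (inherits(x, "lc50_matrix")) x$values else as.matrix(x)
}

#' Assemble the analysis-ready table
#'
#' Joins LC50 estimates (long format) with the clinical covariate table and
#' optional MRD measurements into an [lc50_matrix()] plus aligned covariates.
#'
#' @param estimates data.frame with `sample_id`, `drug` and either
#'   `normalized` (already on \[0,1\]) or `raw_lc50` (normalized here using
#'   `panel`). Rows failing QC (`qc_pass == FALSE`) are dropped.
#' @param patients data.frame with a `patient_id` column; one row per
#'   patient. Patients without any estimate get an all-missing row.
#' @param mrd optional data.frame with `patient_id`, `day15`, `day42` (MRD
#'   in percent).
#' @param panel drug panel.
#' @return List with `lc50` (an `lc50_matrix`), `covariates`, `mrd`, and a
#'   per-drug `missingness` summary.
#' @export
build_analysis_table <- function(estimates, patients, mrd = NULL,
                                 panel = all_drug_panel()) {
  if (!nrow(estimates)) {
    values <- matrix(NA_real_, 0, nrow(panel), dimnames = list(NULL, panel$drug))
    return(list(lc50 = lc50_matrix(values), covariates = patients, mrd = mrd,
                missingness = data.frame(drug = panel$drug, observed = 0L,
                                         missing_fraction = NA_real_)))
  }
  if ("qc_pass" %in% names(estimates)) {
    estimates <- estimates[is.na(estimates$qc_pass) | estimates$qc_pass, , drop = FALSE]
  }
  dup <- duplicated(estimates[, c("sample_id", "drug")])
  if (any(dup)) {
    off <- estimates[dup, c("sample_id", "drug")]
    stop("duplicate patient-drug pairs: ",
         paste(paste(off$sample_id, off$drug, sep = "/"), collapse = ", "))
  }
  if (!"normalized" %in% names(estimates)) {
    estimates$normalized <- normalize_lc50(estimates$raw_lc50, estimates$drug, panel)
  }
  ids <- as.character(patients$patient_id)
  drugs <- intersect(panel$drug, unique(estimates$drug))
  values <- matrix(NA_real_, length(ids), length(drugs),
                   dimnames = list(ids, drugs))
  ri <- match(as.character(estimates$sample_id), ids)
  if (anyNA(ri)) {
    stop("estimates contain sample ids absent from the patient table: ",
         paste(unique(estimates$sample_id[is.na(ri)]), collapse = ", "))
  }
  ci <- match(estimates$drug, drugs)
  values[cbind(ri, ci)] <- estimates$normalized
  x <- lc50_matrix(values)
  missingness <- data.frame(
    drug = drugs,
    observed = colSums(!x$mask),
    missing_fraction = colMeans(x$mask),
    row.names = NULL
  )
  if (!is.null(mrd)) {
    mrd <- mrd[match(ids, as.character(mrd$patient_id)), , drop = FALSE]
    rownames(mrd) <- NULL
  }
  list(lc50 = x, covariates = patients, mrd = mrd, missingness = missingness)
}
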