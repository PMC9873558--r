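# Censored LC50 estimation from 6-point viability curves.
#
# Viability is expressed as a fraction of the vehicle control (1 = no drug
# effect). The dose-response model is a four-parameter logistic in log10
# concentration:
#
#   v(x) = bottom + (top - bottom) / (1 + 10^(hill * (x - log10 ec50)))
#
# with hill > 0 for curves that decrease with dose. LC50 is defined as the
# concentration at which the fitted curve crosses absolute viability 0.5
# (half of the control), not the curve midpoint, so LC50 == ec50 only for the
# symmetric case bottom = 0, top = 1.

#' Assay-level quality control
#'
#' MTT assays pass when the control wells contain more than 70% leukemic
#' blasts and the blank-adjusted optical density exceeds 0.050 absorbance
#' units (both strict). Co-culture assays pass when at least 1,000 viable
#' blast cells remain in the drug-free control wells.
#'
#' @param assay_kind `"MTT"` or `"coculture"` (vectorized).
#' @param blast_fraction fraction of leukemic cells in control wells, in
#'   \[0, 1\] (MTT only).
#' @param optical_density blank-adjusted absorbance of control wells (MTT
#'   only).
#' @param viable_blasts viable blast count in the drug-free control wells
#'   (co-culture only).
#' @return Logical vector: `TRUE` where the sample passes QC.
#' @export
#' @examples
#' qc_filter("MTT", blast_fraction = 0.71, optical_density = 0.06)  # TRUE
#' qc_filter("MTT", blast_fraction = 0.70, optical_density = 0.06)  # FALSE
#' qc_filter("coculture", viable_blasts = 999)                      # FALSE
qc_filter <- function(assay_kind, blast_fraction = NULL, optical_density = NULL,
                      viable_blasts = NULL) {
  assay_kind <- as.character(assay_kind)
  if (!all(assay_kind %in% c("MTT", "coculture"))) {
    stop("assay_kind must be 'MTT' or 'coculture'")
  }
  n <- length(assay_kind)
  rec <- function(x) if (is.null(x)) rep(NA_real_, n) else rep_len(as.numeric(x), n)
  bf <- rec(blast_fraction); od <- rec(optical_density); vb <- rec(viable_blasts)
  out <- logical(n)
  mtt <- assay_kind == "MTT"
  if (any(mtt & (is.na(bf) | is.na(od)))) {
    stop("MTT records require blast_fraction and optical_density")
  }
  if (any(!mtt & is.na(vb))) {
    stop("coculture records require viable_blasts")
  }
  out[mtt] <- bf[mtt] > 0.70 & od[mtt] > 0.050
  out[!mtt] <- vb[!mtt] >= 1000
  out
}

four_pl <- function(conc, bottom, top, hill, ec50) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10(conc) - log10(ec50))))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Bounded least squares in log10-concentration space with a deterministic
#' multi-start (no randomness): `top` starts at the maximum viability,
#' `bottom` at the minimum, `ec50` at the concentration nearest viability
#' 0.5, and the hill slope is tried at 0.5, 1 and 2 with its sign fixed by
#' the observed direction of the curve. Bounds: bottom in \[0, 0.5\], top in
#' \[0.5, 1.5\], |hill| in \[0.05, 10\], ec50 within a tenfold margin of the
#' tested range.
#'
#' @param conc concentrations (positive, increasing recommended).
#' @param viability viability fractions, one per concentration.
#' @return An object of class `four_pl_fit`: list with `bottom`, `top`,
#'   `hill`, `ec50`, `rss`, `converged`.
#' @export
fit_four_pl <- function(conc, viability) {
  ok <- is.finite(conc) & is.finite(viability) & conc > 0
  conc <- conc[ok]; viability <- viability[ok]
  if (length(unique(conc)) < 4) {
    stop("need at least 4 distinct concentrations with finite viabilities")
  }
  x <- log10(conc)
  v <- viability

  # direction: decreasing viability with dose => hill > 0
  slope <- stats::cov(x, v)
  sgn <- if (slope <= 0) 1 else -1

  lower <- c(bottom = 0, top = 0.5, ahill = 0.05, lec50 = min(x) - 1)
  upper <- c(bottom = 0.5, top = 1.5, ahill = 10, lec50 = max(x) + 1)

  obj <- function(par) {
    pred <- par[1] + (par[2] - par[1]) / (1 + 10^(sgn * par[3] * (x - par[4])))
    sum((v - pred)^2)
  }

  b0 <- min(max(min(v), 0), 0.5)
  t0 <- min(max(max(v), 0.5), 1.5)
  e0 <- x[which.min(abs(v - 0.5))]
  e0 <- min(max(e0, lower[4]), upper[4])

  best <- NULL
  for (h0 in c(0.5, 1, 2)) {
    fit <- tryCatch(
      stats::optim(c(b0, t0, h0, e0), obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 1000, factr = 10, pgtol = 1e-12)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(bottom = NA_real_, top = NA_real_, hill = NA_real_,
                          ec50 = NA_real_, rss = NA_real_, converged = FALSE),
                     class = "four_pl_fit"))
  }
  # Gauss-Newton polish from the multi-start optimum (tightens the last
  # digits that quasi-Newton box optimization leaves on the table)
  polish <- tryCatch({
    df <- data.frame(x = x, v = v)
    st <- as.list(stats::setNames(best$par, c("bottom", "top", "ahill", "lec50")))
    nf <- suppressWarnings(stats::nls(
      v ~ bottom + (top - bottom) / (1 + 10^(sgn * ahill * (x - lec50))),
      data = df, start = st, algorithm = "port",
      lower = lower, upper = upper,
      control = stats::nls.control(maxiter = 200, warnOnly = TRUE)
    ))
    list(par = stats::coef(nf), value = sum(stats::residuals(nf)^2))
  }, error = function(e) NULL)
  if (!is.null(polish) && is.finite(polish$value) && polish$value <= best$value) {
    best$par <- polish$par
    best$value <- polish$value
  }
  p <- best$par
  structure(list(
    bottom = unname(p[1]), top = unname(p[2]), hill = unname(sgn * p[3]),
    ec50 = unname(10^p[4]), rss = unname(best$value),
    converged = best$convergence == 0
  ), class = "four_pl_fit")
}

#' @export
print.four_pl_fit <- function(x, ...) {
  cat(sprintf("4PL fit: bottom=%.3f top=%.3f hill=%.3f ec50=%.4g rss=%.4g (%s)\n",
              x$bottom, x$top, x$hill, x$ec50, x$rss,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' @export
predict.four_pl_fit <- function(object, conc, ...) {
  four_pl(conc, object$bottom, object$top, object$hill, object$ec50)
}

# Concentration at which the fitted curve crosses viability 0.5, or NA if
# 0.5 is outside the (bottom, top) span or the fit is unusable.
lc50_crossing <- function(fit) {
  if (!is.finite(fit$ec50) || !is.finite(fit$hill) || fit$hill == 0) return(NA_real_)
  if (!(fit$bottom < 0.5 && fit$top > 0.5)) return(NA_real_)
  # solve bottom + (top-bottom)/(1+10^(hill*(x - m))) = 0.5
  r <- (fit$top - fit$bottom) / (0.5 - fit$bottom) - 1
  if (r <= 0) return(NA_real_)
  10^(log10(fit$ec50) + log10(r) / fit$hill)
}

# Monotone (non-increasing) piecewise log-linear interpolation fallback for
# the 0.5 crossing, used when the 4PL fit fails or never crosses 0.5.
monotone_crossing <- function(conc, viability) {
  o <- order(conc)
  x <- log10(conc[o]); v <- viability[o]
  iso <- stats::isoreg(x, -v)       # non-decreasing fit of -v => v non-increasing
  vm <- -iso$yf
  if (all(vm > 0.5) || all(vm < 0.5)) return(NA_real_)
  i <- which(vm <= 0.5)[1]
  if (i == 1) return(10^x[1])
  if (vm[i - 1] == vm[i]) return(10^x[i])
  10^(x[i - 1] + (0.5 - vm[i - 1]) / (vm[i] - vm[i - 1]) * (x[i] - x[i - 1]))
}

#' Censored LC50 estimate from a viability curve
#'
#' Censoring is decided on the observed endpoint viabilities before any
#' curve interpolation: if even the lowest tested concentration kills more
#' than half the cells (endpoint viability < 0.5) the LC50 is left-censored
#' at half the minimum tested concentration; if viability exceeds 0.5 at the
#' highest tested concentration it is right-censored at twice the maximum.
#' Otherwise the LC50 is the absolute-50% crossing of the fitted 4PL curve,
#' falling back to monotone log-linear interpolation when the fit fails or
#' never crosses 0.5 inside the censor bounds; a crossing still outside the
#' bounds is assigned to the nearer censored bound and flagged.
#'
#' @param conc tested concentrations (the grid).
#' @param viability observed viability fractions (replicate means).
#' @param fit optional precomputed [fit_four_pl()] result.
#' @return List with `raw_lc50`, `censor` (`"interval"`, `"left"`,
#'   `"right"`), `method` (`"4pl"`, `"interpolation"`, `"bound"`, or
#'   `"censor-rule"`) and the `fit` used (if any).
#' @export
estimate_lc50 <- function(conc, viability, fit = NULL) {
  if (length(conc) != length(viability)) stop("conc and viability lengths differ")
  ok <- is.finite(conc) & is.finite(viability) & conc > 0
  if (any(viability[is.finite(viability)] < 0)) stop("negative viability")
  conc <- conc[ok]; viability <- viability[ok]
  if (length(conc) < 2) stop("need at least 2 usable concentrations")
  o <- order(conc)
  conc <- conc[o]; viability <- viability[o]
  lower <- min(conc) / 2
  upper <- 2 * max(conc)

  if (viability[1] < 0.5) {
    return(list(raw_lc50 = lower, censor = "left", method = "censor-rule", fit = fit))
  }
  if (viability[length(viability)] > 0.5) {
    return(list(raw_lc50 = upper, censor = "right", method = "censor-rule", fit = fit))
  }

  if (is.null(fit)) {
    fit <- tryCatch(fit_four_pl(conc, viability), error = function(e) NULL)
  }
  cross <- NA_real_
  method <- "4pl"
  if (!is.null(fit) && isTRUE(fit$converged)) cross <- lc50_crossing(fit)
  if (!is.finite(cross)) {
    cross <- monotone_crossing(conc, viability)
    method <- "interpolation"
  }
  if (!is.finite(cross)) {
    # endpoints straddle 0.5 but no interior crossing found; assign nearer bound
    nearer <- if (mean(viability) < 0.5) "left" else "right"
    return(list(raw_lc50 = if (nearer == "left") lower else upper,
                censor = nearer, method = "bound", fit = fit))
  }
  if (cross <= lower || cross >= upper) {
    nearer <- if (cross <= lower) "left" else "right"
    return(list(raw_lc50 = if (nearer == "left") lower else upper,
                censor = nearer, method = "bound", fit = fit))
  }
  list(raw_lc50 = cross, censor = "interval", method = method, fit = fit)
}

#' Estimate LC50 for every sample-drug curve in a long-format table
#'
#' Driver over a long table of viability measurements (one row per well /
#' concentration). QC is applied per sample-drug record; failing records are
#' retained with `qc_pass = FALSE` and no LC50.
#'
#' @param data data.frame with columns `sample_id`, `drug`, `concentration`,
#'   `viability`, `assay_kind`, and the QC columns `blast_fraction`,
#'   `optical_density` (MTT) or `viable_blasts` (co-culture). Column names
#'   can be remapped via `cols`.
#' @param cols named character vector mapping the canonical names above to
#'   the columns of `data`.
#' @param panel drug panel (used to validate drug ids); `NULL` skips the
#'   check.
#' @return data.frame with one row per sample-drug pair: `sample_id`,
#'   `drug`, `raw_lc50`, `censor`, `qc_pass`, `method`.
#' @export
fit_lc50_table <- function(data, cols = NULL, panel = all_drug_panel()) {
  canon <- c(sample_id = "sample_id", drug = "drug",
             concentration = "concentration", viability = "viability",
             assay_kind = "assay_kind", blast_fraction = "blast_fraction",
             optical_density = "optical_density", viable_blasts = "viable_blasts")
  if (!is.null(cols)) canon[names(cols)] <- cols
  need <- canon[c("sample_id", "drug", "concentration", "viability", "assay_kind")]
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!is.null(panel)) match_drug(unique(data[[canon["drug"]]]), panel)

  key <- interaction(data[[canon["sample_id"]]], data[[canon["drug"]]], drop = TRUE)
  pieces <- split(seq_len(nrow(data)), key)
  rows <- lapply(pieces, function(idx) {
    d <- data[idx, , drop = FALSE]
    kind <- as.character(d[[canon["assay_kind"]]][1])
    getqc <- function(nm) {
      cn <- canon[nm]
      if (cn %in% names(d)) d[[cn]][1] else NULL
    }
    pass <- qc_filter(kind,
                      blast_fraction = getqc("blast_fraction"),
                      optical_density = getqc("optical_density"),
                      viable_blasts = getqc("viable_blasts"))
    out <- data.frame(sample_id = as.character(d[[canon["sample_id"]]][1]),
                      drug = as.character(d[[canon["drug"]]][1]),
                      raw_lc50 = NA_real_, censor = NA_character_,
                      qc_pass = pass, method = NA_character_,
                      stringsAsFactors = FALSE)
    if (pass) {
      est <- estimate_lc50(d[[canon["concentration"]]], d[[canon["viability"]]])
      out$raw_lc50 <- est$raw_lc50
      out$censor <- est$censor
      out$method <- est$method
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
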