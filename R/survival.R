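# Event-free survival across pharmacotype groups: Kaplan-Meier estimates
# with Greenwood standard errors, Mantel's log-rank test, and Cox
# proportional-hazards models with treatment-arm adjustment. Fitting is
# delegated to the survival package (survfit / survdiff / coxph with the
# Efron tie approximation); arm adjustment defaults to stratification
# (separate baseline hazards per arm), with covariate adjustment available.

#' Kaplan-Meier estimate with the 5-year survival per group
#'
#' @param time event-free survival time in years (positive).
#' @param event event indicator (1 = induction failure, relapse, second
#'   malignancy or death; 0 = censored at last contact).
#' @param group optional grouping vector (e.g. pharmacotype cluster).
#' @param at time at which the step-function survival is read (5 years).
#' @return Object of class `km_curve`: list with `fit` (a `survfit`) and
#'   `summary` (per group: `n`, `events`, `surv`, `se` at `at` years).
#' @export
km_estimate <- function(time, event, group = NULL, at = 5) {
  if (any(!is.na(time) & time <= 0)) stop("survival times must be positive")
  if (!all(stats::na.omit(event) %in% c(0, 1))) stop("event must be 0/1")
  df <- data.frame(time = time, event = event,
                   group = if (is.null(group)) factor("all") else factor(group))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sm <- summary(fit, times = at, extend = TRUE)
  strata <- if (is.null(sm$strata)) rep("all", length(sm$surv))
            else sub("^group=", "", as.character(sm$strata))
  out <- data.frame(group = strata,
                    n = as.vector(table(df$group)[strata]),
                    events = tapply(df$event, df$group, sum)[strata],
                    surv = sm$surv, se = sm$std.err,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(fit = fit, summary = out, at = at), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate at %g years:\n", x$at))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Mantel's log-rank test across groups
#'
#' @inheritParams km_estimate
#' @return List with `statistic` (chi-squared), `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  if (any(!is.na(time) & time <= 0)) stop("survival times must be positive")
  df <- data.frame(time = time, event = event, group = factor(group))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nlevels(droplevels(df$group)) < 2) stop("need at least 2 groups")
  if (sum(df$event) == 0) {
    warning("no events observed; p = 1")
    return(list(statistic = 0, df = nlevels(droplevels(df$group)) - 1L, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  df_ <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df_,
       p = stats::pchisq(sd$chisq, df_, lower.tail = FALSE))
}

#' Cox proportional-hazards model with treatment-arm adjustment
#'
#' Fits a Cox model (Efron ties) for EFS on the supplied terms. The
#' treatment arm enters as a stratification factor by default (separate
#' baseline hazard per arm, as when p values are "adjusted by treatment
#' arm"), or as a covariate.
#'
#' @param data data.frame containing `time`, `event`, the model terms and
#'   optionally an arm column.
#' @param terms character vector of covariate names (factors should already
#'   be factors): e.g. MRD positivity, age, WBC, lineage, cluster or
#'   dasatinib group.
#' @param arm name of the treatment-arm column, or `NULL`.
#' @param arm_mode `"strata"` or `"covariate"`.
#' @return Object of class `cox_result`: list with `fit` (the `coxph`
#'   object) and `table` (per term level: `hr`, `ci_lower`, `ci_upper`,
#'   `p`).
#' @export
cox_fit <- function(data, terms, arm = NULL,
                    arm_mode = c("strata", "covariate")) {
  arm_mode <- match.arg(arm_mode)
  if (!length(terms)) stop("no model terms supplied")
  miss <- setdiff(c("time", "event", terms, arm), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (sum(data$event, na.rm = TRUE) == 0) stop("no events; nothing to estimate")
  rhs <- terms
  if (!is.null(arm)) {
    rhs <- c(rhs, if (arm_mode == "strata") sprintf("strata(%s)", arm) else arm)
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(rhs, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = "efron")
  co <- stats::coef(fit)
  if (any(!is.finite(co)) || any(abs(co) > 15)) {
    stop("monotone likelihood / separation detected; consider grouping ",
         "levels or penalized regression")
  }
  sm <- summary(fit)
  tab <- data.frame(term = rownames(sm$coefficients),
                    hr = sm$conf.int[, "exp(coef)"],
                    ci_lower = sm$conf.int[, "lower .95"],
                    ci_upper = sm$conf.int[, "upper .95"],
                    p = sm$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(fit = fit, table = tab, n = sm$n, events = sm$nevent),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox model: n=%d, events=%d\n", x$n, x$events))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Dichotomize dasatinib sensitivity
#'
#' Sensitive iff normalized dasatinib LC50 < 0.25 (strict); the threshold
#' is configurable. Missing LC50 gives `NA` (unclassified).
#'
#' @param lc50 normalized dasatinib LC50 values.
#' @param cutoff sensitivity threshold on the normalized scale.
#' @return Factor with levels `sensitive`, `resistant`.
#' @export
#' @examples
#' dichotomize_dasatinib(c(0.20, 0.25, 1.0))  # sensitive, resistant, resistant
dichotomize_dasatinib <- function(lc50, cutoff = 0.25) {
  factor(ifelse(lc50 < cutoff, "sensitive", "resistant"),
         levels = c("sensitive", "resistant"))
}
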