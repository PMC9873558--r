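# Drug panel: the 18 agents screened against primary ALL cells, with the
# minimum and maximum tested concentrations and the pharmacological class of
# each agent. Six concentrations per drug were assayed; the shipped grid is
# geometric between min and max (the printed ranges are consistent with a
# constant dilution factor, e.g. mercaptopurine 91.8-2938 uM is 2-fold steps).

#' Default ALL drug panel
#'
#' The 18-drug screening panel: four antimetabolites, six non-antimetabolite
#' cytotoxics, five tyrosine kinase inhibitors, two HDAC inhibitors and one
#' BH3-mimetic, each with the minimum and maximum tested concentration.
#' Censored LC50 values are assigned at `min_conc / 2` (more sensitive than
#' the tested range) and `2 * max_conc` (more resistant), and the min-max
#' normalization maps exactly those bounds to 0 and 1.
#'
#' @return A data.frame with columns `drug`, `min_conc`, `max_conc`, `unit`,
#'   `class`, one row per drug.
#' @export
#' @examples
#' panel <- all_drug_panel()
#' nrow(panel)  # 18
all_drug_panel <- function() {
  p <- rbind(
    c("asparaginase",  0.032,   10,      "IU/ml", "non-antimetabolite cytotoxic"),
    c("bortezomib",    0.98,    1000,    "nM",    "non-antimetabolite cytotoxic"),
    c("chz868",        0.1,     10000,   "nM",    "tyrosine kinase inhibitor"),
    c("cytarabine",    0.04,    41.1,    "uM",    "antimetabolite"),
    c("dasatinib",     0.1,     10000,   "nM",    "tyrosine kinase inhibitor"),
    c("daunorubicin",  0.004,   3.55,    "uM",    "non-antimetabolite cytotoxic"),
    c("dexamethasone", 0.00035, 11.6,    "uM",    "non-antimetabolite cytotoxic"),
    c("ibrutinib",     1.5625,  50,      "uM",    "tyrosine kinase inhibitor"),
    c("mercaptopurine", 91.8,   2938,    "uM",    "antimetabolite"),
    c("nelarabine",    1.03,    250,     "uM",    "antimetabolite"),
    c("panobinostat",  0.98,    1000,    "nM",    "HDAC inhibitor"),
    c("prednisolone",  91.8,    2938,    "uM",    "non-antimetabolite cytotoxic"),
    c("ruxolitinib",   0.1,     10000,   "nM",    "tyrosine kinase inhibitor"),
    c("thioguanine",   9.35,    299,     "uM",    "antimetabolite"),
    c("trametinib",    0.01,    1000,    "nM",    "tyrosine kinase inhibitor"),
    c("venetoclax",    0.001,   100,     "nM",    "BH3-mimetic"),
    c("vincristine",   0.0017,  54.169,  "uM",    "non-antimetabolite cytotoxic"),
    c("vorinostat",    102.88,  25000,   "nM",    "HDAC inhibitor")
  )
  out <- data.frame(
    drug = p[, 1],
    min_conc = as.numeric(p[, 2]),
    max_conc = as.numeric(p[, 3]),
    unit = p[, 4],
    class = p[, 5],
    stringsAsFactors = FALSE
  )
  stopifnot(all(out$min_conc > 0), all(out$min_conc < out$max_conc))
  out
}

match_drug <- function(drug, panel = all_drug_panel()) {
  i <- match(drug, panel$drug)
  if (anyNA(i)) {
    stop(sprintf("unknown drug(s): %s", paste(unique(drug[is.na(i)]), collapse = ", ")),
         call. = FALSE)
  }
  i
}

#' Tested concentration grid for a drug
#'
#' Six strictly increasing concentrations, geometric between the panel's
#' minimum and maximum tested concentration for the drug.
#'
#' @param drug drug identifier present in `panel`.
#' @param panel drug panel data.frame, see [all_drug_panel()].
#' @param n number of concentrations (6 in the assay design).
#' @return Numeric vector of length `n`, strictly increasing, all positive.
#' @export
concentration_grid <- function(drug, panel = all_drug_panel(), n = 6L) {
  i <- match_drug(drug, panel)
  if (length(i) != 1L) stop("one drug at a time")
  10^seq(log10(panel$min_conc[i]), log10(panel$max_conc[i]), length.out = n)
}

# Censor bounds on the raw concentration scale.
censor_bounds <- function(drug, panel = all_drug_panel()) {
  i <- match_drug(drug, panel)
  cbind(lower = panel$min_conc[i] / 2, upper = 2 * panel$max_conc[i])
}
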