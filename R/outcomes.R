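#' Stratify FOVs by immune cell infiltration
#'
#' Infiltration is the fraction of a FOV's cells belonging to the immune
#' lineages (default T/NK, B/Plasma and Myeloid). FOVs are split at the
#' median fraction: strictly above -> `"high"`, ties and below -> `"low"`.
#'
#' @param cells validated cell table.
#' @param immune_types character vector of immune lineage labels.
#' @return data.frame(fov_id, n_cells, immune_fraction, stratum) with the
#'   cutpoint and type set as attributes.
#' @export
immune_fraction <- function(cells,
                            immune_types = c("T.NK", "B.Plasma",
                                             "Myeloid")) {
  cells <- validate_cells(cells)
  .assert(length(intersect(immune_types, unique(cells$cell_type))) > 0,
          "none of the immune_types occur in cells")
  fovs <- unique(cells$fov_id)
  frac <- vapply(fovs, function(f) {
    w <- cells$fov_id == f
    mean(cells$cell_type[w] %in% immune_types)
  }, numeric(1))
  n <- vapply(fovs, function(f) sum(cells$fov_id == f), integer(1))
  cut <- median(frac)
  stratum <- ifelse(frac > cut, "high", "low")
  if (all(stratum == "low"))
    warning("all FOVs tied at the median infiltration; every stratum is 'low'")
  out <- data.frame(fov_id = fovs, n_cells = n, immune_fraction = frac,
                    stratum = stratum, row.names = NULL)
  attr(out, "cutpoint") <- cut
  attr(out, "immune_types") <- immune_types
  out
}

#' Differential expression between high- and low-infiltration FOVs
#'
#' Cells of `cell_type` are grouped by their FOV's infiltration stratum
#' and compared gene-by-gene with the same Wilcoxon + Benjamini-Hochberg
#' machinery as [proximity_de()]. Log2 fold changes are high-over-low.
#'
#' @param normalized normalized gene x cell matrix.
#' @param cells validated cell table aligned with the matrix.
#' @param cell_type type whose cells are tested.
#' @param strata output of [immune_fraction()].
#' @param gene_subset optional genes to test.
#' @return data.frame(gene, mean_high, mean_low, log2fc, statistic, p, q).
#' @export
infiltration_de <- function(normalized, cells, cell_type, strata,
                            gene_subset = NULL) {
  cells <- validate_cells(cells)
  st <- strata$stratum[match(cells$fov_id, strata$fov_id)]
  sel <- cells$cell_type == cell_type & !is.na(st)
  .assert(any(sel), "cell_type '%s' absent", cell_type)
  col <- match(cells$cell_id, colnames(normalized))
  hi <- col[sel & st == "high"]
  lo <- col[sel & st == "low"]
  .assert(length(hi) >= 2 && length(lo) >= 2,
          "'%s' missing from a stratum (high n = %d, low n = %d)",
          cell_type, length(hi), length(lo))
  .wilcox_de_table(normalized, hi, lo, "high", "low", gene_subset)
}

#' Dichotomize a covariate into high/low groups
#'
#' `"median"` splits at the median, `"quantile"` at the q-th quantile;
#' values strictly above the cutpoint are `"high"`, ties go to `"low"`.
#'
#' @param values numeric vector (non-constant).
#' @param rule `"median"` or `"quantile"`.
#' @param q quantile level when `rule = "quantile"`.
#' @return character vector of `"high"`/`"low"` with `attr(, "cutpoint")`.
#' @export
dichotomize <- function(values, rule = c("median", "quantile"), q = 0.5) {
  rule <- match.arg(rule)
  .assert(all(is.finite(values)), "values must be finite")
  .assert(length(unique(values)) > 1, "values are constant; no cutpoint")
  cut <- if (rule == "median") median(values) else {
    .assert(q > 0 && q < 1, "q must be in (0, 1)")
    unname(quantile(values, q))
  }
  out <- ifelse(values > cut, "high", "low")
  attr(out, "cutpoint") <- cut
  out
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function with a risk table,
#' via [survival::survfit()]. Censored observations reduce the risk set
#' without dropping the curve; tied event times form a single step.
#'
#' @param time positive event/censoring times (months).
#' @param event 0/1 event indicators.
#' @return object of class `km_curve`: data.frame(time, n_risk, n_event,
#'   n_censor, surv), right-continuous steps at event times.
#' @export
km_curve <- function(time, event) {
  .assert(length(time) > 0, "empty survival input")
  .assert(all(time > 0), "times must be positive")
  .assert(all(event %in% c(0, 1)), "event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank: at each event time, observed minus
#' hypergeometric-expected events in one group, summed and scaled by the
#' summed hypergeometric variance; the statistic is chi-squared with 1
#' degree of freedom. Backed by [survival::survdiff()].
#'
#' @param time positive times.
#' @param event 0/1 event indicators (>= 1 event overall).
#' @param group two-level group labels.
#' @return list(statistic, df = 1, p).
#' @export
logrank_test <- function(time, event, group) {
  .assert(length(unique(group)) == 2, "exactly two groups required")
  .assert(sum(event) >= 1, "no events in either group")
  .assert(all(time > 0), "times must be positive")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(statistic = unname(sd$chisq), df = 1,
       p = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}
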