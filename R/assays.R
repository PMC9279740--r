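#' Relative quantification by the 2^-ddCt method
#'
#' Computes the fold change of a target transcript in a treated group
#' relative to a control group, each normalized to a reference gene (the
#' qPCR experiments here use rpl13a): \eqn{\Delta Ct = Ct_{target} -
#' Ct_{ref}} per group, \eqn{\Delta\Delta Ct = \Delta Ct_{treated} -
#' \Delta Ct_{control}}, fold change \eqn{2^{-\Delta\Delta Ct}}. Vector
#' inputs are replicate Ct values and are averaged per group before the
#' differences are taken (set \code{paired = TRUE} to pair replicates
#' element-wise and average the per-replicate fold changes instead).
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   cycle-threshold values (scalars or replicate vectors).
#' @param paired pair replicates element-wise instead of averaging Ct
#'   values first (vectors must then share a common length).
#' @return Positive fold change (treated relative to control).
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control,
                             paired = FALSE) {
  vals <- list(ct_target_treated, ct_ref_treated,
               ct_target_control, ct_ref_control)
  if (any(!vapply(vals, function(v) length(v) > 0 && all(is.finite(v)),
                  logical(1))))
    stopf("all Ct values must be finite and non-empty")
  if (any(unlist(vals) <= 0) || any(unlist(vals) >= 45))
    warnf("Ct value(s) outside the usual (0, 45) cycle range")
  if (paired) {
    n <- unique(lengths(vals))
    if (length(n) != 1L)
      stopf("paired replicates require equal-length Ct vectors")
    ddct <- (ct_target_treated - ct_ref_treated) -
      (ct_target_control - ct_ref_control)
    return(mean(2^(-ddct)))
  }
  dct_treated <- mean(ct_target_treated) - mean(ct_ref_treated)
  dct_control <- mean(ct_target_control) - mean(ct_ref_control)
  2^(-(dct_treated - dct_control))
}

#' Complement-dependent cytotoxicity percentage
#'
#' \eqn{\%\,cytotoxicity = 100 \times (OD_{control} - OD_{experimental}) /
#' OD_{control}} from OD450 viability readings. Values above the control
#' give a negative percentage, returned as-is unless \code{clamp = TRUE}.
#'
#' @param od_control positive control-group absorbance.
#' @param od_experimental non-negative experimental-group absorbance.
#' @param clamp truncate negative percentages to 0.
#' @return Percentage (vectorized over the experimental readings).
#' @export
cytotoxicity_percent <- function(od_control, od_experimental, clamp = FALSE) {
  if (!is.numeric(od_control) || any(!is.finite(od_control)) ||
      any(od_control <= 0))
    stopf("'od_control' must be positive")
  if (any(!is.finite(od_experimental)) || any(od_experimental < 0))
    stopf("'od_experimental' must be non-negative")
  pct <- 100 * (od_control - od_experimental) / od_control
  if (clamp) pct <- pmax(pct, 0)
  pct
}

#' Geometric mean fluorescence intensity
#'
#' The flow-cytometry summary statistic Gmean: \eqn{\exp(\mathrm{mean}(\log
#' x))} over strictly positive intensities.
#'
#' @param values positive numeric vector.
#' @return Positive scalar.
#' @export
geometric_mean_intensity <- function(values) {
  if (!length(values)) stopf("'values' must be non-empty")
  if (any(!is.finite(values)) || any(values <= 0))
    stopf("'values' must be positive and finite")
  gmean(values)
}

#' Two-sample Student's t-test with group summaries
#'
#' Classical equal-variance two-tailed t-test (df = n1 + n2 - 2) with the
#' mean +/- SEM presentation used for the validation assays.
#'
#' @param group1,group2 numeric vectors, each with at least two values.
#' @return List with \code{t}, \code{df}, \code{p} and per-group
#'   \code{mean} and \code{sem}.
#' @export
two_sample_t <- function(group1, group2) {
  if (length(group1) < 2 || length(group2) < 2)
    stopf("each group needs at least two observations")
  if (stats::var(group1) + stats::var(group2) == 0)
    stopf("zero pooled variance: groups are degenerate")
  ht <- stats::t.test(group1, group2, var.equal = TRUE)
  list(t = unname(ht$statistic),
       df = unname(ht$parameter),
       p = ht$p.value,
       mean = c(group1 = mean(group1), group2 = mean(group2)),
       sem = c(group1 = stats::sd(group1) / sqrt(length(group1)),
               group2 = stats::sd(group2) / sqrt(length(group2))))
}
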