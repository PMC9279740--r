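#' Per-sample size factors
#'
#' Estimates sequencing-depth normalization factors, rescaled so their
#' geometric mean is 1. \code{"total-count"} uses library totals;
#' \code{"median-of-ratios"} uses the median across genes of the ratio of
#' each sample's count to the per-gene geometric-mean reference (computed
#' over genes with nonzero counts in every sample), the standard bulk
#' RNA-seq location estimator robust to a minority of regulated genes.
#'
#' @param x a [count_matrix()].
#' @param method \code{"median-of-ratios"} (default) or \code{"total-count"}.
#' @return Named numeric vector of positive factors, geometric mean 1.
#' @export
size_factors <- function(x, method = c("median-of-ratios", "total-count")) {
  method <- match.arg(method)
  counts <- x$counts
  zero_samples <- colnames(counts)[colSums(counts) == 0]
  if (length(zero_samples))
    stopf("sample(s) with all-zero counts: %s",
          paste(zero_samples, collapse = ", "))
  f <- switch(method,
    "total-count" = colSums(counts),
    "median-of-ratios" = {
      keep <- rowSums(counts == 0) == 0
      if (!any(keep))
        stopf("median-of-ratios needs at least one gene with nonzero counts in every sample")
      logc <- log(counts[keep, , drop = FALSE])
      ref <- rowMeans(logc)               # log geometric-mean reference
      exp(apply(logc - ref, 2, stats::median))
    })
  f <- f / gmean(f)
  stats::setNames(f, colnames(counts))
}

#' Per-contrast log2 fold changes with standard errors
#'
#' For each gene and each treatment condition versus control, estimates the
#' log2 fold change from pseudocounted means of normalized counts,
#' \deqn{\widehat{\mathrm{lfc}} = \log_2 \frac{\bar n_t + c}{\bar n_0 + c},}
#' with a delta-method standard error under Poisson sampling,
#' \deqn{\mathrm{se}^2 = \frac{1}{(\ln 2)^2}\left(\frac{1}{n_t \mu_t} +
#'   \frac{1}{n_0 \mu_0}\right),}
#' where \eqn{\mu} are the pseudocounted condition means and \eqn{n} the
#' replicate numbers. These are the \eqn{x}, \eqn{y} and combined-effect
#' estimates that feed the synergy tests.
#'
#' @param x a [count_matrix()].
#' @param factors per-sample size factors; defaults to [size_factors()].
#' @param pseudocount non-negative value added to condition means before the
#'   ratio (default 0.5; keeps estimates finite at zero counts).
#' @return data.frame with columns \code{gene_id}, \code{contrast}
#'   (\code{"A-vs-control"} etc.), \code{log2_fch}, \code{se}; one row per
#'   gene per treatment contrast.
#' @export
estimate_effects <- function(x, factors = size_factors(x), pseudocount = 0.5) {
  if (!is_scalar_number(pseudocount) || pseudocount < 0)
    stopf("'pseudocount' must be a non-negative number")
  conds <- levels(x$condition)
  factors <- align_factors(factors, x)
  norm <- sweep(x$counts, 2, factors, `/`)
  cond_mean <- vapply(conds, function(cc)
    rowMeans(norm[, x$condition == cc, drop = FALSE]),
    numeric(nrow(norm)))
  if (!is.matrix(cond_mean))   # single-gene edge case
    cond_mean <- matrix(cond_mean, nrow = 1,
                        dimnames = list(rownames(norm), conds))
  n_rep <- table(x$condition)
  ref <- conds[1]
  mu0 <- cond_mean[, ref] + pseudocount
  out <- lapply(conds[-1], function(cc) {
    mut <- cond_mean[, cc] + pseudocount
    se2 <- (1 / log(2))^2 *
      (1 / (n_rep[[cc]] * mut) + 1 / (n_rep[[ref]] * mu0))
    data.frame(gene_id = rownames(x$counts),
               contrast = paste0(cc, "-vs-", ref),
               log2_fch = log2(mut / mu0),
               se = sqrt(se2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## Match factors to sample columns and rescale to geometric mean 1, so
## results are invariant to the overall scale of the supplied factors.
align_factors <- function(factors, x) {
  if (length(factors) != ncol(x$counts))
    stopf("'factors' must have one value per sample")
  if (!is.null(names(factors))) {
    missing <- setdiff(colnames(x$counts), names(factors))
    if (length(missing))
      stopf("no size factor for sample(s): %s", paste(missing, collapse = ", "))
    factors <- factors[colnames(x$counts)]
  } else {
    names(factors) <- colnames(x$counts)
  }
  if (any(!is.finite(factors)) || any(factors <= 0))
    stopf("size factors must be positive and finite")
  factors / gmean(factors)
}

## Exact two-sided conditional Poisson p-value: given the two pooled counts
## and exposures, k_t | (k_t + k_c) ~ Binomial(k_t + k_c, p0). Two-sided by
## doubling the smaller tail, capped at 1.
poisson_rate_p <- function(k_t, k_c, p0) {
  total <- k_t + k_c
  if (total == 0) return(1)
  lower <- stats::pbinom(k_t, total, p0)
  upper <- stats::pbinom(k_t - 1, total, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Exact conditional Poisson differential expression test
#'
#' The Poisson-based differential expression call: replicate counts are
#' pooled within each condition (sums of Poissons are Poisson), and the
#' treatment total is compared to the control total by the exact conditional
#' binomial test: given \eqn{k_t + k_c}, \eqn{k_t \sim
#' \mathrm{Bin}(k_t + k_c,\, E_t/(E_t + E_c))} where the exposures \eqn{E}
#' are summed size factors. Two-sided p-values double the smaller tail
#' (capped at 1) and are Benjamini-Hochberg adjusted across genes. A gene is
#' flagged differentially expressed when the fold change (in either
#' direction) exceeds \code{fc_threshold} and the adjusted p-value is below
#' \code{alpha} — the classic "fold change > 1.5 and adjusted P < 0.05"
#' rule.
#'
#' @param x a [count_matrix()].
#' @param factors per-sample size factors; defaults to [size_factors()].
#' @param condition treatment condition label (default the combined
#'   stimulation, the last design level).
#' @param reference reference condition label (default the first level).
#' @param fc_threshold linear fold-change threshold (default 1.5), applied
#'   to \code{max(FC, 1/FC)}.
#' @param alpha adjusted p-value threshold (default 0.05).
#' @param pseudocount pseudocount for the reported fold change (default
#'   0.5); the exact test itself uses raw counts.
#' @return data.frame with columns \code{gene_id}, \code{contrast},
#'   \code{log2_fch}, \code{fold_change}, \code{p_raw}, \code{p_adj},
#'   \code{is_de}.
#' @export
poisson_de_test <- function(x, factors = size_factors(x),
                            condition = levels(x$condition)[nlevels(x$condition)],
                            reference = levels(x$condition)[1],
                            fc_threshold = 1.5, alpha = 0.05,
                            pseudocount = 0.5) {
  if (!condition %in% levels(x$condition) ||
      !reference %in% levels(x$condition))
    stopf("'condition' and 'reference' must be design condition labels")
  if (!is_scalar_number(fc_threshold) || fc_threshold < 1)
    stopf("'fc_threshold' must be >= 1")
  assert_prob(alpha, "alpha")
  factors <- align_factors(factors, x)
  t_cols <- x$condition == condition
  c_cols <- x$condition == reference
  if (!any(t_cols) || !any(c_cols))
    stopf("both condition groups must be non-empty")
  e_t <- sum(factors[t_cols])
  e_c <- sum(factors[c_cols])
  if (e_t + e_c <= 0) stopf("zero total exposure")
  p0 <- e_t / (e_t + e_c)
  k_t <- rowSums(x$counts[, t_cols, drop = FALSE])
  k_c <- rowSums(x$counts[, c_cols, drop = FALSE])
  p_raw <- mapply(poisson_rate_p, k_t, k_c, MoreArgs = list(p0 = p0))

  norm <- sweep(x$counts, 2, factors, `/`)
  mu_t <- rowMeans(norm[, t_cols, drop = FALSE]) + pseudocount
  mu_c <- rowMeans(norm[, c_cols, drop = FALSE]) + pseudocount
  fc <- mu_t / mu_c
  p_adj <- bh_adjust(p_raw)
  data.frame(gene_id = rownames(x$counts),
             contrast = paste0(condition, "-vs-", reference),
             log2_fch = log2(fc),
             fold_change = fc,
             p_raw = unname(p_raw),
             p_adj = p_adj,
             is_de = pmax(fc, 1 / fc) > fc_threshold & p_adj < alpha,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, returned in input order. Inputs
#' are validated to lie in [0, 1]; the adjustment itself is the standard
#' \code{p.adjust(method = "BH")} procedure.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order as \code{p}.
#' @export
bh_adjust <- function(p) {
  if (length(p) && (any(!is.finite(p)) || any(p < 0) || any(p > 1)))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
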