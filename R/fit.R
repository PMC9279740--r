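#' Fit the factorial cytokine-synergy model to a count matrix
#'
#' The one-stop fitting function for a four-condition stimulation
#' experiment. It normalizes the counts, estimates the per-gene log2
#' fold-change triplet (x = cytokine A vs control, y = cytokine B vs
#' control, xy = combination vs control) with delta-method standard
#' errors, calls differential expression per contrast with the exact
#' conditional Poisson test and Benjamini-Hochberg adjustment, and
#' classifies eligible genes as synergistic (positive/negative), additive,
#' or antagonistic via Wald tests of xy against x + y (Test 1) and against
#' each of x and y (Test 2).
#'
#' @param x a [count_matrix()], or an integer matrix if \code{condition}
#'   is supplied.
#' @param condition condition labels per sample (ignored when \code{x} is
#'   already a \code{count_matrix}).
#' @param normalization size-factor method, see [size_factors()].
#' @param pseudocount pseudocount for fold-change estimation (default 0.5).
#' @param fc_threshold,de_alpha differential-expression thresholds
#'   (default fold change > 1.5, adjusted p < 0.05).
#' @param test_alpha significance level for the synergy tests (default
#'   0.05).
#' @param eligibility which genes enter classification, see
#'   [classify_all()].
#' @param adjust_interaction BH-adjust the synergy-test p-values across
#'   genes (default \code{FALSE}).
#'
#' @return An object of class \code{"synergy_fit"} with components
#'   \code{data} (the count matrix), \code{size_factors}, \code{effects}
#'   (long per-contrast table), \code{triplets}, \code{de} (stacked DE
#'   tables for the three contrasts), \code{interaction} (an
#'   \code{interaction_calls} object) and \code{params}. Methods:
#'   \code{print}, \code{summary}, \code{coef} (triplet matrix),
#'   \code{fitted} (expected counts), \code{residuals} (Pearson),
#'   \code{predict}, \code{simulate}, \code{plot}.
#'
#' @examples
#' sim <- simulate_factorial_counts(sim_config(n_genes = 200, seed = 11))
#' fit <- synergy_fit(sim$counts)
#' summary(fit)
#' head(coef(fit))
#' @export
synergy_fit <- function(x, condition = NULL,
                        normalization = c("median-of-ratios", "total-count"),
                        pseudocount = 0.5,
                        fc_threshold = 1.5, de_alpha = 0.05,
                        test_alpha = 0.05,
                        eligibility = c("combined", "any", "none"),
                        adjust_interaction = FALSE) {
  normalization <- match.arg(normalization)
  eligibility <- match.arg(eligibility)
  if (!inherits(x, "count_matrix")) {
    if (is.null(condition))
      stopf("'condition' is required when 'x' is not a count_matrix")
    x <- count_matrix(x, condition)
  }
  sf <- size_factors(x, method = normalization)
  effects <- estimate_effects(x, sf, pseudocount = pseudocount)
  conds <- levels(x$condition)
  de <- do.call(rbind, lapply(conds[-1], function(cc)
    poisson_de_test(x, sf, condition = cc, reference = conds[1],
                    fc_threshold = fc_threshold, alpha = de_alpha,
                    pseudocount = pseudocount)))
  rownames(de) <- NULL
  triplets <- effect_triplets(effects,
                              contrasts = paste0(conds[-1], "-vs-", conds[1]))
  interaction <- classify_all(
    triplets, de, alpha = test_alpha, eligibility = eligibility,
    adjust = adjust_interaction,
    combined_contrast = paste0(conds[4], "-vs-", conds[1]))
  structure(
    list(data = x,
         size_factors = sf,
         effects = effects,
         triplets = triplets,
         de = de,
         interaction = interaction,
         params = list(normalization = normalization,
                       pseudocount = pseudocount,
                       fc_threshold = fc_threshold,
                       de_alpha = de_alpha,
                       test_alpha = test_alpha,
                       eligibility = eligibility,
                       adjust_interaction = adjust_interaction)),
    class = "synergy_fit")
}

#' @export
print.synergy_fit <- function(x, ...) {
  cat("Factorial cytokine-synergy fit\n")
  print(x$data)
  cat(sprintf("normalization: %s; DE rule: FC > %g & p_adj < %g; test alpha %g\n",
              x$params$normalization, x$params$fc_threshold,
              x$params$de_alpha, x$params$test_alpha))
  print(x$interaction)
  invisible(x)
}

#' @export
summary.synergy_fit <- function(object, ...) {
  de_counts <- tapply(object$de$is_de, object$de$contrast, sum)
  s <- object$interaction$summary
  asg <- s[c("synergistic_positive", "synergistic_negative", "additive"), ,
           drop = FALSE]
  out <- list(n_genes = nrow(object$data$counts),
              n_samples = ncol(object$data$counts),
              de_counts = de_counts,
              n_eligible = object$interaction$n_eligible,
              category_direction = s,
              n_synergistic = sum(s["synergistic_positive", ]) +
                sum(s["synergistic_negative", ]),
              n_additive = sum(s["additive", ]),
              n_asg = sum(asg),
              n_up = sum(asg[, "up"]),
              n_down = sum(asg[, "down"]),
              params = object$params)
  class(out) <- "summary.synergy_fit"
  out
}

#' @export
print.summary.synergy_fit <- function(x, ...) {
  cat(sprintf("%d genes x %d samples\n", x$n_genes, x$n_samples))
  cat("differentially expressed per contrast:\n")
  print(x$de_counts)
  cat(sprintf("eligible for classification: %d\n", x$n_eligible))
  print(x$category_direction)
  cat(sprintf("synergistic: %d; additive: %d; ASGs: %d (%d up, %d down)\n",
              x$n_synergistic, x$n_additive, x$n_asg, x$n_up, x$n_down))
  invisible(x)
}

#' @describeIn synergy_fit matrix of per-gene effect estimates
#'   (columns x, y, xy); \code{se = TRUE} appends the standard errors.
#' @param object,... method arguments.
#' @param se include standard-error columns.
#' @export
coef.synergy_fit <- function(object, se = FALSE, ...) {
  t <- object$triplets
  m <- as.matrix(t[, if (se) c("x", "se_x", "y", "se_y", "xy", "se_xy")
                   else c("x", "y", "xy")])
  rownames(m) <- t$gene_id
  m
}

## Expected normalized mean per gene and condition.
condition_means <- function(object) {
  x <- object$data
  norm <- sweep(x$counts, 2, object$size_factors, `/`)
  m <- vapply(levels(x$condition), function(cc)
    rowMeans(norm[, x$condition == cc, drop = FALSE]),
    numeric(nrow(norm)))
  if (!is.matrix(m))   # single-gene edge case
    m <- matrix(m, nrow = 1,
                dimnames = list(rownames(norm), levels(x$condition)))
  m
}

#' @describeIn synergy_fit fitted expected counts (condition mean scaled by
#'   the sample's size factor), gene x sample.
#' @export
fitted.synergy_fit <- function(object, ...) {
  mu <- condition_means(object)[, as.character(object$data$condition),
                                drop = FALSE]
  mu <- sweep(mu, 2, object$size_factors, `*`)
  colnames(mu) <- colnames(object$data$counts)
  mu
}

#' @describeIn synergy_fit Pearson residuals under the Poisson model,
#'   \code{(count - fitted)/sqrt(fitted)}.
#' @export
residuals.synergy_fit <- function(object, ...) {
  mu <- fitted(object)
  (object$data$counts - mu) / sqrt(pmax(mu, .Machine$double.eps))
}

#' @describeIn synergy_fit expected counts for new samples given their
#'   condition labels and optional size factors.
#' @param newdata character vector of condition labels (default: the
#'   fitted design).
#' @param size_factors size factors for the new samples (default 1).
#' @export
predict.synergy_fit <- function(object, newdata = NULL, size_factors = NULL,
                                ...) {
  if (is.null(newdata))
    return(fitted(object))
  newdata <- as.character(newdata)
  bad <- setdiff(newdata, levels(object$data$condition))
  if (length(bad))
    stopf("unknown condition label(s): %s", paste(bad, collapse = ", "))
  if (is.null(size_factors)) size_factors <- rep(1, length(newdata))
  mu <- condition_means(object)[, newdata, drop = FALSE]
  sweep(mu, 2, size_factors, `*`)
}

#' @describeIn synergy_fit parametric simulation: draws Poisson counts at
#'   the fitted means, returning a list of \code{count_matrix} objects.
#' @param nsim number of simulated datasets.
#' @param seed RNG seed.
#' @export
simulate.synergy_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- fitted(object)
  with_seed(seed, lapply(seq_len(nsim), function(k) {
    counts <- matrix(stats::rpois(length(mu), mu), nrow = nrow(mu),
                     dimnames = dimnames(mu))
    count_matrix(counts,
                 stats::setNames(as.character(object$data$condition),
                                 colnames(mu)),
                 conditions = levels(object$data$condition))
  }))
}

#' @describeIn synergy_fit diagnostic plot: combined effect xy against the
#'   additive expectation x + y, colored by category; points on the
#'   identity line behave additively, points beyond it synergistically.
#' @param y unused (for the generic).
#' @export
plot.synergy_fit <- function(x, y, ...) {
  calls <- x$interaction$calls
  if (!nrow(calls)) {
    plot(0, 0, type = "n", xlab = "x + y (log2)", ylab = "xy (log2)",
         main = "no eligible genes")
    return(invisible(x))
  }
  pal <- c(synergistic_positive = "firebrick",
           synergistic_negative = "navy",
           additive = "black",
           antagonistic_excluded = "darkorange",
           not_classified = "grey60")
  plot(calls$x + calls$y, calls$xy,
       col = pal[as.character(calls$category)], pch = 16, cex = 0.6,
       xlab = "x + y (log2 fold change)",
       ylab = "combined xy (log2 fold change)", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = names(pal), col = pal, pch = 16,
                   cex = 0.7, bty = "n")
  invisible(x)
}
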