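CATEGORY_LEVELS <- c("synergistic_positive", "synergistic_negative",
                     "additive", "antagonistic_excluded", "not_classified")

#' Effect triplets for the synergy tests
#'
#' Assembles per-gene (x, y, xy) log2 fold-change triplets from the long
#' effect table produced by [estimate_effects()]: \code{x} is the first
#' single-cytokine effect, \code{y} the second, \code{xy} the combined
#' stimulation effect, each versus control with its standard error.
#'
#' @param effects data.frame from [estimate_effects()] (columns
#'   \code{gene_id}, \code{contrast}, \code{log2_fch}, \code{se}).
#' @param contrasts character(3): the contrast labels to use as x, y and
#'   xy, in that order. Defaults to the three treatment-vs-control
#'   contrasts in design order.
#' @return data.frame with columns \code{gene_id}, \code{x}, \code{se_x},
#'   \code{y}, \code{se_y}, \code{xy}, \code{se_xy}.
#' @export
effect_triplets <- function(effects, contrasts = NULL) {
  if (is.null(contrasts)) {
    contrasts <- unique(effects$contrast)
    if (length(contrasts) != 3L)
      stopf("expected exactly 3 contrasts, found %d", length(contrasts))
  }
  pick <- function(cc) {
    sub <- effects[effects$contrast == cc, , drop = FALSE]
    if (!nrow(sub)) stopf("contrast '%s' not present in effects", cc)
    sub[order(sub$gene_id), , drop = FALSE]
  }
  ex <- pick(contrasts[1]); ey <- pick(contrasts[2]); exy <- pick(contrasts[3])
  if (!identical(ex$gene_id, ey$gene_id) ||
      !identical(ex$gene_id, exy$gene_id))
    stopf("contrasts cover different gene sets")
  data.frame(gene_id = ex$gene_id,
             x = ex$log2_fch, se_x = ex$se,
             y = ey$log2_fch, se_y = ey$se,
             xy = exy$log2_fch, se_xy = exy$se,
             stringsAsFactors = FALSE)
}

wald_p <- function(delta, se2) {
  if (any(se2 <= 0)) stopf("zero or negative variance in Wald test")
  2 * stats::pnorm(-abs(delta) / sqrt(se2))
}

#' Test 1: combined effect versus the sum of single effects
#'
#' Wald test of H0: xy = x + y against the two-sided alternative, i.e.
#' whether the combined-stimulation log2 fold change differs from the sum
#' of the single-cytokine log2 fold changes. The z statistic is
#' \eqn{(xy - x - y)/\sqrt{se_{xy}^2 + se_x^2 + se_y^2}}.
#'
#' @param t data.frame with columns \code{x}, \code{se_x}, \code{y},
#'   \code{se_y}, \code{xy}, \code{se_xy} (one or more rows).
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns \code{p_value} and \code{passes}
#'   (\code{p_value < alpha}).
#' @export
test_sum <- function(t, alpha = 0.05) {
  assert_prob(alpha, "alpha")
  p <- wald_p(t$xy - t$x - t$y, t$se_xy^2 + t$se_x^2 + t$se_y^2)
  data.frame(p_value = p, passes = p < alpha)
}

#' Test 2: combined effect versus each single effect
#'
#' Two Wald tests of H0: xy = x and H0: xy = y against two-sided
#' alternatives. \code{passes_both} additionally requires the combined
#' effect to exceed both single effects in magnitude
#' (\code{|xy| > |x|} and \code{|xy| > |y|}): the combined response must be
#' greater than, not merely different from, each individual response.
#'
#' @inheritParams test_sum
#' @return data.frame with columns \code{p_vs_x}, \code{p_vs_y},
#'   \code{passes_both}.
#' @export
test_dominance <- function(t, alpha = 0.05) {
  assert_prob(alpha, "alpha")
  p_x <- wald_p(t$xy - t$x, t$se_xy^2 + t$se_x^2)
  p_y <- wald_p(t$xy - t$y, t$se_xy^2 + t$se_y^2)
  data.frame(p_vs_x = p_x, p_vs_y = p_y,
             passes_both = p_x < alpha & p_y < alpha &
               abs(t$xy) > abs(t$x) & abs(t$xy) > abs(t$y))
}

#' Classify genes as synergistic, additive or antagonistic
#'
#' Applies the decision cascade to each effect triplet:
#' \enumerate{
#'   \item \strong{synergistic} if Test 1 rejects additivity and
#'     \code{|xy| > |x + y|}; positive if \code{xy > 0}, negative
#'     otherwise. The synergy increase is \code{|xy| - |x + y|}.
#'   \item else \strong{antagonistic_excluded} if the combined effect is
#'     significantly different from a single effect while being smaller in
#'     magnitude (\code{p < alpha} with \code{|xy| < |x|}, or the analogue
#'     for y) — the combined response collapses below an individual
#'     response and the gene is excluded.
#'   \item else \strong{additive} if Test 2 passes for both x and y (the
#'     combined effect significantly exceeds each single effect but not
#'     their sum).
#'   \item else \strong{not_classified}.
#' }
#'
#' @param t data.frame of effect triplets (see [effect_triplets()]); a
#'   \code{gene_id} column is carried through if present.
#' @param alpha per-gene significance level for both tests (default 0.05).
#' @param adjust if \code{TRUE}, BH-adjust each test family (Test 1, Test 2
#'   vs x, Test 2 vs y) across the supplied genes before applying
#'   \code{alpha}. Default \code{FALSE}: per-gene decisions use raw
#'   p-values, with the false-discovery-rate control applied at the
#'   differential-expression stage instead.
#' @return data.frame with columns \code{gene_id} (if supplied),
#'   \code{category} (factor), \code{direction} (\code{"up"} if
#'   \code{xy > 0} else \code{"down"}), \code{synergy_increase}
#'   (\code{|xy| - |x + y|}), \code{p_test1}, \code{p_test2_x},
#'   \code{p_test2_y}.
#' @export
classify_genes <- function(t, alpha = 0.05, adjust = FALSE) {
  assert_prob(alpha, "alpha")
  if (!nrow(t)) {
    out <- data.frame(gene_id = character(),
                      category = factor(character(), levels = CATEGORY_LEVELS),
                      direction = character(),
                      synergy_increase = numeric(),
                      p_test1 = numeric(), p_test2_x = numeric(),
                      p_test2_y = numeric(), stringsAsFactors = FALSE)
    if (is.null(t$gene_id)) out$gene_id <- NULL
    return(out)
  }
  if (any(!is.finite(t$x)) || any(!is.finite(t$y)) || any(!is.finite(t$xy)))
    stopf("effect estimates must be finite")
  t1 <- test_sum(t, alpha)
  t2 <- test_dominance(t, alpha)
  p1 <- t1$p_value; p2x <- t2$p_vs_x; p2y <- t2$p_vs_y
  if (adjust) {
    p1 <- bh_adjust(p1); p2x <- bh_adjust(p2x); p2y <- bh_adjust(p2y)
  }
  syn <- p1 < alpha & abs(t$xy) > abs(t$x + t$y)
  antag <- !syn & ((p2x < alpha & abs(t$xy) < abs(t$x)) |
                   (p2y < alpha & abs(t$xy) < abs(t$y)))
  addv <- !syn & !antag &
    p2x < alpha & p2y < alpha & abs(t$xy) > abs(t$x) & abs(t$xy) > abs(t$y)
  category <- rep("not_classified", nrow(t))
  category[syn] <- ifelse(t$xy[syn] > 0,
                          "synergistic_positive", "synergistic_negative")
  category[antag] <- "antagonistic_excluded"
  category[addv] <- "additive"
  out <- data.frame(
    category = factor(category, levels = CATEGORY_LEVELS),
    direction = ifelse(t$xy > 0, "up", "down"),
    synergy_increase = abs(t$xy) - abs(t$x + t$y),
    p_test1 = p1, p_test2_x = p2x, p_test2_y = p2y,
    stringsAsFactors = FALSE)
  if (!is.null(t$gene_id)) out <- cbind(gene_id = t$gene_id, out)
  rownames(out) <- NULL
  out
}

#' Classify all eligible genes and summarise the calls
#'
#' Joins the effect triplets with differential-expression results, applies
#' the eligibility filter, runs the classification cascade on eligible
#' genes, and tabulates category-by-direction counts. The default filter
#' admits genes differentially expressed under combined stimulation versus
#' control — the combined-response gene list from which additive and
#' synergistic genes (ASGs) are screened.
#'
#' @param triplets data.frame from [effect_triplets()].
#' @param de_results data.frame from [poisson_de_test()]; for
#'   \code{eligibility = "any"} it may stack several contrasts.
#' @param alpha significance level for the synergy tests (default 0.05).
#' @param eligibility \code{"combined"} (default: DE in the combined-vs-
#'   control contrast), \code{"any"} (DE in at least one contrast present
#'   in \code{de_results}), or \code{"none"} (classify every gene).
#' @param adjust passed to [classify_genes()].
#' @param combined_contrast label of the combined-vs-control contrast in
#'   \code{de_results} (used by the default eligibility filter).
#' @return A list of class \code{"interaction_calls"}:
#'   \code{calls} — per-eligible-gene classification table, sorted by gene
#'   id, including the triplet columns; \code{summary} — category x
#'   direction count table; \code{n_eligible}, \code{n_total}.
#' @export
classify_all <- function(triplets, de_results, alpha = 0.05,
                         eligibility = c("combined", "any", "none"),
                         adjust = FALSE, combined_contrast = "AB-vs-control") {
  eligibility <- match.arg(eligibility)
  if (eligibility != "none") {
    extra <- setdiff(de_results$gene_id, triplets$gene_id)
    missing <- setdiff(triplets$gene_id, de_results$gene_id)
    if (length(extra) || length(missing))
      stopf("gene id mismatch between triplets and DE results (%d unmatched)",
            length(extra) + length(missing))
  }
  eligible_ids <- switch(eligibility,
    none = triplets$gene_id,
    combined = {
      comb <- de_results$contrast == combined_contrast
      if (!any(comb))
        stopf("contrast '%s' not present in de_results", combined_contrast)
      de_results$gene_id[comb & de_results$is_de]
    },
    any = unique(de_results$gene_id[de_results$is_de]))
  sub <- triplets[triplets$gene_id %in% eligible_ids, , drop = FALSE]
  sub <- sub[order(sub$gene_id), , drop = FALSE]
  cls <- classify_genes(sub, alpha = alpha, adjust = adjust)
  calls <- cbind(sub, cls[, setdiff(names(cls), "gene_id"), drop = FALSE])
  rownames(calls) <- NULL
  summary_tab <- table(category = calls$category,
                       direction = factor(calls$direction,
                                          levels = c("up", "down")))
  structure(list(calls = calls,
                 summary = summary_tab,
                 n_eligible = nrow(calls),
                 n_total = nrow(triplets),
                 alpha = alpha,
                 eligibility = eligibility),
            class = "interaction_calls")
}

#' @export
print.interaction_calls <- function(x, ...) {
  cat(sprintf("interaction calls: %d eligible of %d genes (filter: %s)\n",
              x$n_eligible, x$n_total, x$eligibility))
  print(x$summary)
  n_asg <- sum(x$summary[c("synergistic_positive", "synergistic_negative",
                           "additive"), ])
  cat(sprintf("additive or synergistic genes (ASGs): %d\n", n_asg))
  invisible(x)
}
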