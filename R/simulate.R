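#' Simulation configuration for factorial stimulation counts
#'
#' Describes a four-condition factorial RNA-seq experiment (control, cytokine
#' A, cytokine B, combined A+B) with a known per-gene interaction structure.
#' Genes are split across six ground-truth categories:
#' \describe{
#'   \item{null}{no response to either cytokine.}
#'   \item{single_only}{responds to exactly one cytokine, no interaction.}
#'   \item{additive}{responds to both cytokines in the same direction with
#'     zero interaction, so the combined log2 effect is exactly the sum.}
#'   \item{synergistic_pos / synergistic_neg}{a nonzero interaction term in
#'     the direction of the single effects, so the combined effect exceeds
#'     the sum in magnitude (upward resp. downward).}
#'   \item{antagonistic}{an interaction term opposing the single effects,
#'     strong enough that the combined effect is smaller in magnitude than
#'     the larger single effect.}
#' }
#'
#' @param n_genes number of genes.
#' @param n_replicates replicates per condition (the study design has three).
#' @param conditions ordered condition labels; the second and third entries
#'   are the single stimulations, the fourth the combination.
#' @param baseline_log2_mean,baseline_log2_sd mean and sd of the per-gene
#'   baseline expression on the log2 scale (default mean 6, sd 2: control
#'   counts mostly in the tens to thousands, typical bulk RNA-seq depth).
#' @param baseline_log2_min lower truncation for the baseline draw on the
#'   log2 scale (\code{-Inf} = no truncation). Used by the strong-effect
#'   scenario to keep every gene above the detection floor.
#' @param library_size_factors positive per-sample scaling of expected
#'   counts; \code{NULL} means all 1.
#' @param category_fractions named proportions over the six categories;
#'   must sum to 1.
#' @param effect_size_log2 list with elements \code{x}, \code{y},
#'   \code{interaction}: each a length-2 magnitude range (log2 units) from
#'   which effect sizes are drawn uniformly.
#' @param dispersion non-negative; 0 gives Poisson counts, values > 0 give
#'   negative-binomial counts with size = 1/dispersion.
#' @param seed integer RNG seed; identical configurations give bit-identical
#'   output.
#'
#' @return An object of class \code{"sim_config"}.
#' @seealso [simulate_factorial_counts()], [sim_config_strong()]
#' @export
sim_config <- function(n_genes = 1000L,
                       n_replicates = 3L,
                       conditions = c("control", "A", "B", "AB"),
                       baseline_log2_mean = 6,
                       baseline_log2_sd = 2,
                       baseline_log2_min = -Inf,
                       library_size_factors = NULL,
                       category_fractions = c(null = 0.30,
                                              single_only = 0.10,
                                              additive = 0.20,
                                              synergistic_pos = 0.15,
                                              synergistic_neg = 0.15,
                                              antagonistic = 0.10),
                       effect_size_log2 = list(x = c(0.6, 2),
                                               y = c(0.6, 2),
                                               interaction = c(1.5, 2.5)),
                       dispersion = 0,
                       seed = 1L) {
  if (!is_scalar_number(n_genes) || n_genes < 1)
    stopf("'n_genes' must be a positive integer")
  if (!is_scalar_number(n_replicates) || n_replicates < 1)
    stopf("'n_replicates' must be a positive integer")
  if (length(conditions) != 4L || anyDuplicated(conditions))
    stopf("'conditions' must be four distinct labels")
  required <- c("null", "single_only", "additive",
                "synergistic_pos", "synergistic_neg", "antagonistic")
  if (!all(required %in% names(category_fractions)))
    stopf("'category_fractions' must name all of: %s",
          paste(required, collapse = ", "))
  category_fractions <- category_fractions[required]
  if (any(category_fractions < 0) ||
      abs(sum(category_fractions) - 1) > 1e-9)
    stopf("'category_fractions' must be non-negative and sum to 1")
  n_samples <- 4L * as.integer(n_replicates)
  if (is.null(library_size_factors))
    library_size_factors <- rep(1, n_samples)
  if (length(library_size_factors) != n_samples ||
      any(library_size_factors <= 0))
    stopf("'library_size_factors' must be %d positive values", n_samples)
  for (nm in c("x", "y", "interaction")) {
    r <- effect_size_log2[[nm]]
    if (is.null(r) || length(r) != 2L || any(r < 0) || r[2] < r[1])
      stopf("effect_size_log2$%s must be an increasing non-negative range", nm)
  }
  if (!is_scalar_number(dispersion) || dispersion < 0)
    stopf("'dispersion' must be a non-negative number")
  structure(
    list(n_genes = as.integer(n_genes),
         n_replicates = as.integer(n_replicates),
         conditions = as.character(conditions),
         baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd,
         baseline_log2_min = baseline_log2_min,
         library_size_factors = as.numeric(library_size_factors),
         category_fractions = category_fractions,
         effect_size_log2 = effect_size_log2,
         dispersion = dispersion,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config")
}

#' Strong-effect benchmark scenario
#'
#' The default parameter-recovery scenario: every interaction effect is at
#' least 1.5 log2 units and every baseline control mean is at least 64
#' counts (log2 baseline drawn from N(8, 1) truncated below at 6), with
#' three Poisson replicates per condition. Under these conditions the
#' classifier is expected to recover synergistic and additive genes with
#' high precision and recall.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of genes (default 1000).
#' @param ... further arguments passed to [sim_config()].
#' @return A \code{"sim_config"} object.
#' @export
sim_config_strong <- function(seed = 1L, n_genes = 1000L, ...) {
  sim_config(n_genes = n_genes,
             baseline_log2_mean = 8,
             baseline_log2_sd = 1,
             baseline_log2_min = 6,
             seed = seed,
             ...)
}

## Largest-remainder apportionment of n items over named fractions.
## Deterministic: ties in the fractional part go to the earlier category.
quota_counts <- function(fractions, n) {
  quota <- fractions * n
  base <- floor(quota)
  short <- n - sum(base)
  if (short > 0) {
    frac <- quota - base
    ord <- order(-frac, seq_along(frac))
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

runif_sign <- function(n, range) {
  stats::runif(n, range[1], range[2]) * sample(c(-1, 1), n, replace = TRUE)
}

#' Simulate a factorial stimulation count matrix with known truth
#'
#' Draws per-gene baseline expression and category-specific log2 effects,
#' then samples counts with expectation
#' \deqn{\mu_{gs} = f_s \, 2^{b_g + x_g [s \in A, AB] + y_g [s \in B, AB]
#'   + i_g [s \in AB]}}
#' where \eqn{f_s} is the library size factor, \eqn{b_g} the log2 baseline,
#' \eqn{x_g, y_g} the single-cytokine effects and \eqn{i_g} the interaction.
#' Counts are Poisson when \code{dispersion = 0}, negative binomial with
#' size \code{1/dispersion} otherwise. Category labels are assigned by a
#' deterministic largest-remainder quota, so truth-table category counts
#' match \code{round(category_fractions * n_genes)} exactly.
#'
#' @param config a [sim_config()] object.
#' @return A list with elements \code{counts} (a [count_matrix()]) and
#'   \code{truth} (data.frame: \code{gene_id}, \code{true_category},
#'   \code{true_x}, \code{true_y}, \code{true_interaction},
#'   \code{baseline_mean}).
#' @examples
#' sim <- simulate_factorial_counts(sim_config(n_genes = 50, seed = 7))
#' table(sim$truth$true_category)
#' @export
simulate_factorial_counts <- function(config) {
  if (!inherits(config, "sim_config"))
    stopf("'config' must be a sim_config object")
  with_seed(config$seed, {
    n <- config$n_genes
    ncat <- quota_counts(config$category_fractions, n)
    category <- rep(names(ncat), times = ncat)

    b <- stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
    b <- pmax(b, config$baseline_log2_min)

    es <- config$effect_size_log2
    x <- numeric(n); y <- numeric(n); i <- numeric(n)

    idx <- which(category == "single_only")
    if (length(idx)) {
      which_x <- sample(c(TRUE, FALSE), length(idx), replace = TRUE)
      eff <- runif_sign(length(idx), es$x)
      x[idx[which_x]] <- eff[which_x]
      y[idx[!which_x]] <- eff[!which_x]
    }
    idx <- which(category == "additive")
    if (length(idx)) {
      s <- sample(c(-1, 1), length(idx), replace = TRUE)
      x[idx] <- s * stats::runif(length(idx), es$x[1], es$x[2])
      y[idx] <- s * stats::runif(length(idx), es$y[1], es$y[2])
    }
    for (cat_nm in c("synergistic_pos", "synergistic_neg")) {
      idx <- which(category == cat_nm)
      if (length(idx)) {
        s <- if (cat_nm == "synergistic_pos") 1 else -1
        x[idx] <- s * stats::runif(length(idx), es$x[1], es$x[2])
        y[idx] <- s * stats::runif(length(idx), es$y[1], es$y[2])
        i[idx] <- s * stats::runif(length(idx),
                                   es$interaction[1], es$interaction[2])
      }
    }
    idx <- which(category == "antagonistic")
    if (length(idx)) {
      s <- sample(c(-1, 1), length(idx), replace = TRUE)
      x[idx] <- s * stats::runif(length(idx), es$x[1], es$x[2])
      y[idx] <- s * stats::runif(length(idx), es$y[1], es$y[2])
      ## combined effect shrinks to a quarter of the larger single effect:
      ## |combined| < max(|x|, |y|) by construction
      combined <- s * 0.25 * pmax(abs(x[idx]), abs(y[idx]))
      i[idx] <- combined - x[idx] - y[idx]
    }

    conds <- config$conditions
    n_rep <- config$n_replicates
    cond_per_sample <- rep(conds, each = n_rep)
    sample_id <- paste0(cond_per_sample, "_", rep(seq_len(n_rep), times = 4))
    in_a <- cond_per_sample %in% conds[c(2, 4)]
    in_b <- cond_per_sample %in% conds[c(3, 4)]
    is_ab <- cond_per_sample == conds[4]

    log2_mu <- outer(b, rep(1, length(sample_id))) +
      outer(x, as.numeric(in_a)) +
      outer(y, as.numeric(in_b)) +
      outer(i, as.numeric(is_ab))
    mu <- sweep(2^log2_mu, 2, config$library_size_factors, `*`)

    counts <- if (config$dispersion == 0) {
      matrix(stats::rpois(length(mu), mu), nrow = n)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu,
                            size = 1 / config$dispersion), nrow = n)
    }
    gene_id <- sprintf("gene_%0*d", nchar(n), seq_len(n))
    dimnames(counts) <- list(gene_id, sample_id)

    list(
      counts = count_matrix(counts, stats::setNames(cond_per_sample, sample_id),
                            conditions = conds),
      truth = data.frame(gene_id = gene_id,
                         true_category = category,
                         true_x = x,
                         true_y = y,
                         true_interaction = i,
                         baseline_mean = 2^b,
                         stringsAsFactors = FALSE))
  })
}
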