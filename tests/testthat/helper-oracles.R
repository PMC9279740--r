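## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: tail probabilities are accumulated term by term
## from the mass functions.

## Two-sided conditional binomial p-value by exhaustive enumeration:
## doubles the smaller of the two inclusive tails, capped at 1.
enum_binom_p <- function(k_t, k_c, p0) {
  total <- k_t + k_c
  if (total == 0) return(1)
  mass <- vapply(0:total, function(j) choose(total, j) * p0^j *
                   (1 - p0)^(total - j), numeric(1))
  lower <- sum(mass[seq_len(k_t + 1)])
  upper <- sum(mass[(k_t + 1):(total + 1)])
  min(1, 2 * min(lower, upper))
}

## Hypergeometric upper tail P(X >= k) by term-wise enumeration.
enum_hyper_p <- function(k, set_size, universe_size, query_size) {
  hi <- min(set_size, query_size)
  if (k > hi) return(0)
  j <- k:hi
  sum(choose(set_size, j) * choose(universe_size - set_size, query_size - j)) /
    choose(universe_size, query_size)
}

## Small factorial count_matrix from explicit per-condition columns.
toy_counts <- function(control, a = control, b = control, ab = control,
                       n_rep = NULL) {
  m <- cbind(control, a, b, ab)
  n_rep <- n_rep %||% 1L
  if (n_rep > 1) m <- m[, rep(seq_len(4), each = n_rep), drop = FALSE]
  cond <- rep(c("control", "A", "B", "AB"), each = n_rep)
  colnames(m) <- paste0(cond, "_", rep(seq_len(n_rep), times = 4))
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  count_matrix(m, cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## One-row effect-triplet table.
triplet <- function(x, se_x, y, se_y, xy, se_xy, gene_id = "g1") {
  data.frame(gene_id = gene_id, x = x, se_x = se_x, y = y, se_y = se_y,
             xy = xy, se_xy = se_xy, stringsAsFactors = FALSE)
}
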