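#' Construct a factorial count matrix
#'
#' Bundles an integer gene-by-sample count matrix with the condition label of
#' each sample. This is the input container for normalization, differential
#' expression and the synergy classifier. Conditions follow the four-group
#' factorial stimulation design: an unstimulated control, each single cytokine
#' (\code{"A"}, \code{"B"}) and the combined stimulation (\code{"AB"}).
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). No missing values; all entries must
#'   be non-negative whole numbers.
#' @param condition character vector of condition labels, one per column of
#'   \code{counts}, or a named vector matched to \code{colnames(counts)}.
#' @param conditions the set of expected condition labels, in design order.
#'
#' @return An object of class \code{"count_matrix"}: a list with elements
#'   \code{counts} (integer matrix) and \code{condition} (factor, one level
#'   per design condition).
#' @export
count_matrix <- function(counts, condition,
                         conditions = c("control", "A", "B", "AB")) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stopf("count matrix must have at least one gene and one sample")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate gene id(s): %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample id(s): %s",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                collapse = ", "))
  if (any(!is.finite(counts)))
    stopf("count matrix contains missing or non-finite entries")
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("count matrix must contain non-negative whole numbers")
  storage.mode(counts) <- "integer"

  if (!is.null(names(condition))) {
    missing <- setdiff(colnames(counts), names(condition))
    if (length(missing))
      stopf("no condition label for sample(s): %s",
            paste(missing, collapse = ", "))
    condition <- condition[colnames(counts)]
  }
  condition <- as.character(condition)
  if (length(condition) != ncol(counts))
    stopf("'condition' must have one label per sample (%d needed, %d given)",
          ncol(counts), length(condition))
  bad <- setdiff(unique(condition), conditions)
  if (length(bad))
    stopf("unknown condition label(s): %s", paste(bad, collapse = ", "))
  absent <- setdiff(conditions, unique(condition))
  if (length(absent))
    stopf("condition(s) missing from the design: %s",
          paste(absent, collapse = ", "))
  structure(
    list(counts = counts,
         condition = factor(condition, levels = conditions)),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$condition)
  cat("replicates per condition:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

gene_ids <- function(x) rownames(x$counts)
sample_ids <- function(x) colnames(x$counts)
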