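## Deterministic TSV writer: fixed column order, no quoting, '.' decimal,
## UTF-8. Numeric columns are formatted with full precision so identical
## inputs give byte-identical files.
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.15g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Read and write count matrices
#'
#' The counts TSV has a header row of sample ids, gene ids in the first
#' column (named \code{gene_id}), and integer counts elsewhere. Reading is
#' strict: ragged rows, duplicated gene ids and non-integer cells are
#' errors that name the offending gene and sample. A metadata TSV with
#' columns \code{sample_id} and \code{condition} assigns each sample to a
#' design condition. \code{read_counts(write_counts(x, ...))} is the
#' identity.
#'
#' @param path file path.
#' @param metadata path of the sample-metadata TSV, or a data.frame with
#'   columns \code{sample_id} and \code{condition}.
#' @param conditions design condition labels, see [count_matrix()].
#' @return \code{read_counts}: a [count_matrix()]. \code{write_counts}:
#'   the path, invisibly.
#' @export
read_counts <- function(path, metadata,
                        conditions = c("control", "A", "B", "AB")) {
  if (!file.exists(path)) stopf("counts file not found: %s", path)
  nfields <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nfields)) != 1L)
    stopf("ragged counts file: rows have %s fields",
          paste(sort(unique(nfields)), collapse = ", "))
  raw <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           check.names = FALSE)
  if (ncol(raw) < 2L) stopf("counts file needs gene ids plus >= 1 sample")
  gene_id <- raw[[1]]
  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup))
    stopf("duplicate gene id(s) in counts file: %s", paste(dup, collapse = ", "))
  samples <- colnames(raw)[-1]
  mat <- matrix(NA_integer_, nrow = nrow(raw), ncol = length(samples),
                dimnames = list(gene_id, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1]]))
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad))
      stopf("non-integer count '%s' for gene %s, sample %s",
            raw[[j + 1]][bad[1]], gene_id[bad[1]], samples[j])
    mat[, j] <- as.integer(v)
  }
  md <- if (is.character(metadata)) read_sample_metadata(metadata) else metadata
  if (!all(c("sample_id", "condition") %in% names(md)))
    stopf("metadata must have columns 'sample_id' and 'condition'")
  count_matrix(mat, stats::setNames(md$condition, md$sample_id),
               conditions = conditions)
}

#' @rdname read_counts
#' @param x a [count_matrix()].
#' @export
write_counts <- function(x, path) {
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname read_counts
#' @export
read_sample_metadata <- function(path) {
  md <- read_tsv(path, colClasses = "character")
  if (!all(c("sample_id", "condition") %in% names(md)))
    stopf("metadata file must have columns 'sample_id' and 'condition'")
  md
}

#' @rdname read_counts
#' @export
write_sample_metadata <- function(x, path) {
  write_tsv(data.frame(sample_id = colnames(x$counts),
                       condition = as.character(x$condition),
                       stringsAsFactors = FALSE), path)
}

#' Read a GMT gene-set file
#'
#' Tab-separated gene-set format: one set per line — set name, description,
#' then member gene ids. Returns a named list of member vectors suitable
#' for [gene_set_collection()].
#'
#' @param path file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stopf("GMT line %d has fewer than 3 fields", short[1])
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stopf("duplicate gene-set name(s): %s",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  stats::setNames(lapply(fields, function(f) unique(f[-c(1, 2)])), nm)
}

#' Read a ligand-receptor pair table
#'
#' TSV with columns \code{ligand} and \code{receptor} (an optional
#' \code{pair} column labels the pair).
#'
#' @param path file path.
#' @return data.frame of unique pairs.
#' @export
read_pair_table <- function(path) {
  pairs <- read_tsv(path, colClasses = "character")
  if (!all(c("ligand", "receptor") %in% names(pairs)))
    stopf("pair table must have columns 'ligand' and 'receptor'")
  if (any(!nzchar(pairs$ligand)) || any(!nzchar(pairs$receptor)))
    stopf("ligand and receptor ids must be non-empty")
  pairs[!duplicated(pairs[c("ligand", "receptor")]), , drop = FALSE]
}
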