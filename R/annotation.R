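#' Gene-set collection for over-representation analysis
#'
#' Intersects each gene set with the tested universe (case-insensitive id
#' matching) and drops sets left empty, producing the collection used by
#' [ora_test()].
#'
#' @param sets named list of character vectors (set name -> member ids),
#'   e.g. from [read_gmt()].
#' @param universe character vector of all tested gene ids.
#' @return An object of class \code{"gene_set_collection"}: list with
#'   \code{sets} (filtered, ids upper-cased) and \code{universe}.
#' @export
gene_set_collection <- function(sets, universe) {
  if (!length(universe)) stopf("'universe' must be non-empty")
  universe <- unique(toupper(as.character(universe)))
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("all gene sets must be named")
  sets <- lapply(sets, function(s) intersect(unique(toupper(s)), universe))
  sets <- sets[lengths(sets) > 0]
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Hypergeometric over-representation test
#'
#' For each gene set, tests whether the query list overlaps the set more
#' than expected by chance, with the one-sided hypergeometric upper tail
#' \eqn{P(X \ge k)} (population = universe size, successes = set size,
#' draws = query size). P-values are Benjamini-Hochberg adjusted across
#' sets and the result is ranked by p-value.
#'
#' @param query character vector of gene ids (e.g. the ASG list).
#' @param collection a [gene_set_collection()].
#' @param mode \code{"strict"} (error if a query gene is absent from the
#'   universe) or \code{"lenient"} (drop such genes with a warning).
#' @return data.frame with columns \code{set}, \code{set_size},
#'   \code{overlap}, \code{query_size}, \code{universe_size}, \code{p_raw},
#'   \code{p_adj}, ordered by increasing p-value.
#' @export
ora_test <- function(query, collection, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (!inherits(collection, "gene_set_collection"))
    stopf("'collection' must be a gene_set_collection")
  query <- unique(toupper(as.character(query)))
  outside <- setdiff(query, collection$universe)
  if (length(outside)) {
    if (mode == "strict")
      stopf("query gene(s) absent from the universe: %s",
            paste(outside, collapse = ", "))
    warnf("dropping %d query gene(s) absent from the universe: %s",
          length(outside), paste(outside, collapse = ", "))
    query <- setdiff(query, outside)
  }
  n_univ <- length(collection$universe)
  n_query <- length(query)
  res <- lapply(names(collection$sets), function(nm) {
    members <- collection$sets[[nm]]
    k <- length(intersect(query, members))
    m <- length(members)
    ## upper tail P(X >= k)
    p <- stats::phyper(k - 1, m, n_univ - m, n_query, lower.tail = FALSE)
    data.frame(set = nm, set_size = m, overlap = k,
               query_size = n_query, universe_size = n_univ,
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(set = character(), set_size = integer(),
                      overlap = integer(), query_size = integer(),
                      universe_size = integer(), p_raw = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE))
  out$p_adj <- bh_adjust(out$p_raw)
  out <- out[order(out$p_raw, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ligand-receptor co-regulation report
#'
#' Given interaction calls with per-gene direction and a table of
#' ligand-receptor pairs, reports for each pair whether both members are
#' regulated in the same direction. Only genes classified as additive or
#' synergistic (the ASG list) count as regulated; a pair with at least one
#' member outside that list is reported \code{"incomplete"}.
#'
#' @param calls an \code{"interaction_calls"} object from [classify_all()],
#'   or its \code{calls} data.frame (columns \code{gene_id},
#'   \code{category}, \code{direction}).
#' @param pairs data.frame with columns \code{ligand}, \code{receptor} and
#'   optionally \code{pair} (label; default \code{"ligand-receptor"}).
#' @return data.frame with columns \code{pair}, \code{ligand},
#'   \code{receptor}, \code{ligand_direction}, \code{receptor_direction},
#'   \code{status} in \{both_up, both_down, discordant, incomplete\}.
#' @export
pair_coregulation <- function(calls, pairs) {
  if (inherits(calls, "interaction_calls")) calls <- calls$calls
  if (!all(c("ligand", "receptor") %in% names(pairs)))
    stopf("'pairs' must have columns 'ligand' and 'receptor'")
  if (!nrow(pairs))
    return(data.frame(pair = character(), ligand = character(),
                      receptor = character(), ligand_direction = character(),
                      receptor_direction = character(), status = character(),
                      stringsAsFactors = FALSE))
  if (any(!nzchar(pairs$ligand)) || any(!nzchar(pairs$receptor)))
    stopf("ligand and receptor ids must be non-empty")
  pairs <- pairs[!duplicated(pairs[c("ligand", "receptor")]), , drop = FALSE]
  asg <- calls$category %in% c("synergistic_positive", "synergistic_negative",
                               "additive")
  dir_map <- stats::setNames(calls$direction[asg], toupper(calls$gene_id[asg]))
  lig_dir <- unname(dir_map[toupper(pairs$ligand)])
  rec_dir <- unname(dir_map[toupper(pairs$receptor)])
  status <- ifelse(is.na(lig_dir) | is.na(rec_dir), "incomplete",
            ifelse(lig_dir == "up" & rec_dir == "up", "both_up",
            ifelse(lig_dir == "down" & rec_dir == "down", "both_down",
                   "discordant")))
  label <- if ("pair" %in% names(pairs)) pairs$pair else
    paste0(pairs$ligand, "-", pairs$receptor)
  out <- data.frame(pair = label,
                    ligand = pairs$ligand,
                    receptor = pairs$receptor,
                    ligand_direction = ifelse(is.na(lig_dir), NA_character_,
                                              lig_dir),
                    receptor_direction = ifelse(is.na(rec_dir), NA_character_,
                                                rec_dir),
                    status = status,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
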