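#' Pipeline configuration
#'
#' Collects paths, thresholds and options for [run_pipeline()]. A
#' configuration serializes to YAML with [write_config()] and parses back
#' losslessly with [read_config()].
#'
#' @param counts,metadata paths of the counts and sample-metadata TSVs.
#' @param output_dir directory for result tables (created if absent).
#' @param gene_sets optional GMT path for over-representation analysis.
#' @param pairs optional ligand-receptor pair TSV path.
#' @param fc_threshold,de_alpha differential-expression thresholds
#'   (defaults: fold change 1.5, adjusted p 0.05).
#' @param test_alpha synergy-test significance level (default 0.05).
#' @param normalization,pseudocount,eligibility,adjust_interaction options
#'   passed to [synergy_fit()].
#' @param seed integer seed recorded in the run manifest (the analysis
#'   itself is deterministic; the seed matters when inputs are simulated).
#' @param log_level \code{"info"}, \code{"quiet"} or \code{"debug"}.
#' @return An object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(counts, metadata, output_dir,
                            gene_sets = NULL, pairs = NULL,
                            fc_threshold = 1.5, de_alpha = 0.05,
                            test_alpha = 0.05,
                            normalization = "median-of-ratios",
                            pseudocount = 0.5,
                            eligibility = "combined",
                            adjust_interaction = FALSE,
                            seed = 1L,
                            log_level = "info") {
  if (!is_scalar_number(fc_threshold) || fc_threshold < 1)
    stopf("'fc_threshold' must be >= 1")
  assert_prob(de_alpha, "de_alpha")
  assert_prob(test_alpha, "test_alpha")
  if (!is_scalar_number(pseudocount) || pseudocount < 0)
    stopf("'pseudocount' must be non-negative")
  if (!normalization %in% c("median-of-ratios", "total-count"))
    stopf("unknown normalization '%s'", normalization)
  if (!eligibility %in% c("combined", "any", "none"))
    stopf("unknown eligibility mode '%s'", eligibility)
  if (!log_level %in% c("quiet", "info", "debug"))
    stopf("unknown log level '%s'", log_level)
  structure(
    list(counts = counts, metadata = metadata, output_dir = output_dir,
         gene_sets = gene_sets, pairs = pairs,
         fc_threshold = fc_threshold, de_alpha = de_alpha,
         test_alpha = test_alpha, normalization = normalization,
         pseudocount = pseudocount, eligibility = eligibility,
         adjust_interaction = isTRUE(adjust_interaction),
         seed = as.integer(seed), log_level = log_level),
    class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a \code{pipeline_config} object.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  if (!inherits(config, "pipeline_config"))
    stopf("'config' must be a pipeline_config")
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

log_msg <- function(config, level, fmt, ...) {
  levels <- c(quiet = 0, info = 1, debug = 2)
  if (levels[[config$log_level]] >= levels[[level]])
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
}

run_stage <- function(name, config, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  log_msg(config, "info", "stage %s done (%.2fs)", name,
          as.numeric(difftime(Sys.time(), t0, units = "secs")))
  res
}

#' Run the full synergy analysis pipeline
#'
#' Reads counts and sample metadata, fits the factorial synergy model,
#' and writes: one differential-expression table per treatment contrast,
#' the effect-triplet table, the per-gene interaction calls, the
#' category-by-direction summary, an over-representation report (when a
#' gene-set GMT is configured, run on the additive-or-synergistic gene
#' list against all tested genes), a ligand-receptor co-regulation report
#' (when a pair table is configured), and a JSON run manifest recording
#' the configuration, package version and seed. All tables are sorted by
#' gene id with a fixed column order, so repeated runs are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the fitted \code{"synergy_fit"} object
#'   and the paths of the written files.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stopf("'config' must be a pipeline_config")
  if (!dir.exists(config$output_dir))
    dir.create(config$output_dir, recursive = TRUE)

  x <- run_stage("read_input", config, {
    read_counts(config$counts, config$metadata)
  })
  fit <- run_stage("fit", config, {
    synergy_fit(x,
                normalization = config$normalization,
                pseudocount = config$pseudocount,
                fc_threshold = config$fc_threshold,
                de_alpha = config$de_alpha,
                test_alpha = config$test_alpha,
                eligibility = config$eligibility,
                adjust_interaction = config$adjust_interaction)
  })

  paths <- list()
  out <- function(name) file.path(config$output_dir, name)

  run_stage("write_de", config, {
    for (cc in unique(fit$de$contrast)) {
      sub <- fit$de[fit$de$contrast == cc, , drop = FALSE]
      sub <- sub[order(sub$gene_id), , drop = FALSE]
      p <- out(paste0("de_", gsub("[^A-Za-z0-9_.-]", "_", cc), ".tsv"))
      write_tsv(sub, p)
      paths[[paste0("de_", cc)]] <- p
    }
  })
  run_stage("write_effects", config, {
    trip <- fit$triplets[order(fit$triplets$gene_id), , drop = FALSE]
    paths$effects <- write_tsv(trip, out("effect_triplets.tsv"))
  })
  run_stage("write_calls", config, {
    calls <- fit$interaction$calls
    calls$category <- as.character(calls$category)
    paths$calls <- write_tsv(calls, out("interaction_calls.tsv"))
    s <- as.data.frame(fit$interaction$summary, stringsAsFactors = FALSE)
    names(s) <- c("category", "direction", "n")
    paths$summary <- write_tsv(s, out("summary.tsv"))
  })

  asg <- with(fit$interaction$calls,
              gene_id[category %in% c("synergistic_positive",
                                      "synergistic_negative", "additive")])
  if (!is.null(config$gene_sets)) {
    run_stage("ora", config, {
      collection <- gene_set_collection(read_gmt(config$gene_sets),
                                        universe = gene_ids(x))
      paths$ora <- write_tsv(ora_test(asg, collection, mode = "lenient"),
                              out("ora.tsv"))
    })
  }
  if (!is.null(config$pairs)) {
    run_stage("pairs", config, {
      report <- pair_coregulation(fit$interaction, read_pair_table(config$pairs))
      paths$pairs <- write_tsv(report, out("pair_coregulation.tsv"))
    })
  }
  run_stage("manifest", config, {
    manifest <- list(
      config = unclass(config),
      package = "synergyseq",
      version = as.character(utils::packageVersion("synergyseq")),
      n_genes = nrow(x$counts),
      n_samples = ncol(x$counts),
      seed = config$seed)
    paths$manifest <- out("manifest.json")
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
  })
  log_msg(config, "info", "pipeline complete: %d files in %s",
          length(paths), config$output_dir)
  invisible(list(fit = fit, paths = paths))
}
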