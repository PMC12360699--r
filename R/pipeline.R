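#' Default pipeline configuration
#'
#' A complete configuration for the one-command synthetic demonstration:
#' simulate a repertoire, ingest and filter it, score it with the
#' germline-anchored provider, build heavy-chain lineage trees, run the
#' edge-substitution analyses, and compute the association statistics.
#' Any element can be overridden via `...` (nested lists are replaced
#' wholesale).
#'
#' @param ... Named overrides, e.g. `seed = 7`,
#'   `simulate = list(n_cells = 200)`.
#' @return A config list accepted by [run_pipeline()].
#' @export
demo_config <- function(...) {
  cfg <- list(
    seed = 1L,
    simulate = list(n_cells = 300L),
    provider = list(name = "germline_anchored", q = 0.7),
    sources = c("full_vdj", "cdr3_from_vdj", "cdr3_only", "paired"),
    clonotype = "vfam_cdr3",
    trees = list(chains = "heavy", include_germline_edges = TRUE),
    stats = list(adjust = "holm"),
    frequency_table = NULL,
    affinity_table = NULL)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  base <- demo_config()
  for (nm in names(base)) if (is.null(config[[nm]])) config[[nm]] <- base[[nm]]
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  if (!config$provider$name %in% c("germline_anchored", "uniform", "profile")) {
    stop("unknown provider: ", config$provider$name)
  }
  bad <- setdiff(config$sources,
                 c("full_vdj", "cdr3_from_vdj", "cdr3_only", "paired"))
  if (length(bad)) stop("unknown source(s): ", paste(bad, collapse = ", "))
  if (!config$trees$chains %in% c("heavy", "paired")) {
    stop("trees$chains must be 'heavy' or 'paired'")
  }
  config
}

config_provider <- function(config) {
  p <- config$provider
  switch(p$name,
         germline_anchored = germline_anchored_provider(
           if (is.null(p$q)) 0.7 else p$q),
         uniform = uniform_provider(),
         profile = positional_profile_provider(
           if (is.null(p$concentration)) 0.25 else p$concentration,
           seed = config$seed))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate -> ingest -> score -> trees -> shm -> stats, writing
#' each stage's artifact into `out_dir` together with a manifest listing
#' every output file with its MD5 hash, the package version and the
#' seed. Re-running with an identical config reproduces the artifacts
#' byte for byte. Optional external tables (`frequency_table`,
#' `affinity_table`: CSV paths) enable the corresponding association
#' analyses; when absent those analyses are skipped with a notice.
#'
#' @param config Config list (see [demo_config()]) or path to a YAML
#'   file with the same structure.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results
#'   (`sim`, `rep`, `scored`, `forest`, `edge_records`, `stats`) and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(path) { written[[length(written) + 1L]] <<- path; path }
  stage <- function(name, expr) {
    message("[bcrlik] stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  sim <- stage("simulate", {
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    sim <- simulate_repertoire(do.call(sim_config, sim_args))
    for (f in write_simulated_repertoire(sim, out_dir)) emit(f)
    sim
  })

  rep <- stage("ingest", {
    records <- read_repertoire(file.path(out_dir, "repertoire.tsv"), "airr_tsv")
    rep <- filter_cells(records, clonotype = config$clonotype)
    write_repertoire(rep, emit(file.path(out_dir, "filtered.tsv")))
    write_filter_report(rep, emit(file.path(out_dir, "filter_report.json")))
    rep
  })

  provider <- config_provider(config)
  scored <- stage("score", {
    scored <- score_repertoire(rep, provider, sources = config$sources)
    utils::write.csv(scored, emit(file.path(out_dir, "scores.csv")),
                     row.names = FALSE)
    scored
  })

  forest <- stage("trees", {
    forest <- build_forest(rep, chains = config$trees$chains)
    nwk <- vapply(forest, as_newick, "")
    writeLines(nwk, emit(file.path(out_dir, "trees.nwk")))
    attrs <- do.call(rbind, lapply(names(forest), function(cl) {
      cbind(clone_id = cl, node_attributes(forest[[cl]]))
    }))
    utils::write.csv(attrs, emit(file.path(out_dir, "tree_nodes.csv")),
                     row.names = FALSE)
    forest
  })

  edge_records <- stage("shm", {
    recs <- forest_edge_substitutions(
      forest, provider,
      include_germline_edges = isTRUE(config$trees$include_germline_edges))
    utils::write.csv(recs, emit(file.path(out_dir, "edge_substitutions.csv")),
                     row.names = FALSE)
    cvm <- conserved_vs_mutating(forest, provider)
    summary <- list(
      n_substitution_rows = nrow(recs),
      mean_rank = if (nrow(recs)) mean_substitution_rank(recs)$grand_mean else NA,
      mean_rl_mutating = cvm$mean_rl_mutating,
      mean_rl_conserved = cvm$mean_rl_conserved,
      conserved_vs_mutating_p = cvm$p_value)
    jsonlite::write_json(summary, emit(file.path(out_dir, "shm_summary.json")),
                         auto_unbox = TRUE, digits = NA)
    recs
  })

  stats_out <- stage("stats", {
    feat <- sp_feature_table(scored, rep, forest = forest)
    utils::write.csv(feat, emit(file.path(out_dir, "feature_table.csv")),
                     row.names = FALSE)
    heavy_full <- feat[feat$locus == "heavy" & feat$source == "full_vdj", ]
    res <- list()
    if (sum(is.finite(heavy_full$hamming_shm)) >= 3L) {
      res$sp_vs_shm <- correlate(heavy_full$sp, heavy_full$hamming_shm,
                                 "pearson", analysis = "sp_vs_shm")
    }
    if (length(unique(heavy_full$clone_id)) >= 3L) {
      res$sp_vs_expansion <- correlate(heavy_full$sp,
                                       heavy_full$normalized_expansion,
                                       "pearson", analysis = "sp_vs_expansion")
    }
    if (all(is.finite(heavy_full$root_path_length)) &&
        nrow(heavy_full) >= 3L) {
      res$sp_vs_root_path <- correlate(heavy_full$sp,
                                       heavy_full$root_path_length,
                                       "pearson", analysis = "sp_vs_root_path")
    }
    iso <- group_compare(heavy_full, value = "sp", group = "isotype",
                         adjust = config$stats$adjust)
    utils::write.csv(iso, emit(file.path(out_dir, "isotype_compare.csv")),
                     row.names = FALSE)
    if (!is.null(config$frequency_table)) {
      freq <- utils::read.csv(config$frequency_table, stringsAsFactors = FALSE)
      res$frequency <- frequency_association(mean_sp_by(heavy_full, "v_family"),
                                             freq)
    } else message("[bcrlik] no frequency table supplied; association skipped")
    if (!is.null(config$affinity_table)) {
      aff <- utils::read.csv(config$affinity_table, stringsAsFactors = FALSE)
      res$affinity <- affinity_association(heavy_full, aff, "polyclonal")
    } else message("[bcrlik] no affinity table supplied; association skipped")
    cors <- do.call(rbind, res)
    if (!is.null(cors)) {
      utils::write.csv(cors, emit(file.path(out_dir, "associations.csv")),
                       row.names = FALSE)
    }
    list(correlations = cors, isotype = iso)
  })

  manifest <- list(
    package = "bcrlik",
    version = as.character(utils::packageVersion("bcrlik")),
    seed = config$seed,
    config = config[setdiff(names(config), "provider_object")],
    files = lapply(stats::setNames(written, basename(written)), function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)),
           bytes = file.size(f))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sim = sim, rep = rep, scored = scored, forest = forest,
                 edge_records = edge_records, stats = stats_out,
                 manifest = manifest))
}
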