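pipeline_defaults <- function() {
  list(seed = 1L,
       simulate = TRUE,
       expression_path = NULL, expression_meta_path = NULL,
       counts_path = NULL, counts_meta_path = NULL, gmt_path = NULL,
       vst_threshold = 3, min_samples = 2, min_trees = 3,
       bins = NULL,
       network_threshold = 5,
       hub_fraction = 0.20, high_quantile = 0.80,
       min_count = 10, filter_rule = "all",
       q_threshold = 0.01, fc_threshold = 1, delta_threshold = 1,
       enrichment_p = 0.05,
       n_gene_clusters = 5)
}

#' Pipeline configuration
#'
#' Stage parameters for [run_pipeline()], all defaulting to the analysis
#' cutoffs used throughout the package: VST filter at 3 (2 sections in 3
#' trees), CLR network threshold 5, top-20% hub fraction, q < 0.01 and
#' two-fold criteria for the ethylene-responsive call, enrichment p <
#' 0.05, five expression clusters. Unknown keys are rejected. With
#' `simulate = TRUE` (default) the input paths are ignored and synthetic
#' data with planted ground truth is generated from `seed`.
#'
#' @param ... Named overrides of the defaults (see
#'   `woodnet:::pipeline_defaults()`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- pipeline_defaults()
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  cfg <- modifyList(defaults, over, keep.null = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration (JSON or YAML by extension)
#'
#' @param config A [pipeline_config()].
#' @param path File path ending in `.json`, `.yml` or `.yaml`.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    writeLines(yaml::as.yaml(x), path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- if (grepl("\\.ya?ml$", path)) yaml::yaml.load_file(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x[!vapply(x, is.null, logical(1))])
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> expression prep -> MI/CLR network ->
#' centrality and hubs -> seed-gene modules -> differential expression and
#' the ethylene-responsive call -> enrichment, writing every stage output
#' plus a JSON summary and a parameter log under `out_dir`. In simulate
#' mode the modules are extracted around the planted hub genes and the
#' summary additionally reports recovery against the planted ground truth.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param module_seeds Optional gene ids to extract modules around;
#'   defaults to the planted hubs (simulate mode) or the top three hub
#'   genes otherwise.
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         module_seeds = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(stage, ...) {
    msg <- paste0("[", stage, "] ", paste0(...))
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (file.exists(log_path)) unlink(log_path)
  logf("config", "seed=", config$seed,
       " network_threshold=", config$network_threshold,
       " hub_fraction=", config$hub_fraction,
       " q=", config$q_threshold, " fc=", config$fc_threshold,
       " vst=", config$vst_threshold,
       " woodnet=", as.character(utils::packageVersion("woodnet")),
       " R=", as.character(getRversion()))

  truth <- NULL
  if (isTRUE(config$simulate)) {
    sim <- run_stage("simulate", {
      s <- generate_section_series(simulation_config(seed = config$seed))
      cexp <- generate_count_experiment(count_sim_config(
        seed = config$seed + 1L,
        responder_genes = default_gene_ids(2000L)[1:100]))
      module_sets <- setNames(
        lapply(s$truth$modules, `[[`, "members"),
        sprintf("PLANTED%02d", seq_along(s$truth$modules)))
      ann <- generate_annotation(seed = config$seed + 2L,
                                 genes = rownames(s$series$values),
                                 planted = module_sets)
      list(series = s$series,
           truth = c(s$truth, list(responders = cexp$truth$responders,
                                   planted_terms = names(module_sets))),
           experiment = cexp$experiment, annotation = ann)
    })
    series <- sim$series
    cexp <- sim$experiment
    collection <- sim$annotation$collection
    tf_table <- sim$annotation$tf_table
    truth <- sim$truth
    write_section_series(series, file.path(out_dir, "expression.tsv"),
                         file.path(out_dir, "sections.tsv"))
    write_count_experiment(cexp, file.path(out_dir, "counts.tsv"),
                           file.path(out_dir, "libraries.tsv"))
    write_gmt(collection$sets, file.path(out_dir, "gene_sets.gmt"))
    write_ground_truth(truth, file.path(out_dir, "ground_truth.json"))
    logf("simulate", "generated ", nrow(series$values), " genes x ",
         ncol(series$values), " sections and ", nrow(cexp$counts),
         " genes x ", ncol(cexp$counts), " libraries")
  } else {
    series <- run_stage("load", read_section_series(
      config$expression_path, config$expression_meta_path))
    cexp <- run_stage("load", read_count_experiment(
      config$counts_path, config$counts_meta_path))
    collection <- NULL
    tf_table <- NULL
    if (!is.null(config$gmt_path)) {
      sets <- run_stage("load", read_gmt(config$gmt_path))
      collection <- list(sets = sets, universe = rownames(series$values))
    }
    logf("load", "loaded ", nrow(series$values), " genes x ",
         ncol(series$values), " sections")
  }

  filtered <- run_stage("prep", filter_expressed(
    series, vst_threshold = config$vst_threshold,
    min_samples = config$min_samples, min_trees = config$min_trees))
  gene_clusters <- run_stage("prep", cluster_genes(
    filtered, k = min(config$n_gene_clusters, nrow(filtered$values))))
  write_cluster_assignment(gene_clusters,
                           file.path(out_dir, "gene_clusters.tsv"),
                           file.path(out_dir, "gene_linkage.json"))
  logf("prep", nrow(filtered$values), " expressed genes; ",
       gene_clusters$k, " gene clusters")

  net <- run_stage("network", {
    mi <- mi_matrix(filtered, bins = config$bins)
    build_network(clr_transform(mi), filtered,
                  threshold = config$network_threshold)
  })
  write_network_edges(net, file.path(out_dir, "network_edges.tsv"))
  write_network_graphml(net, file.path(out_dir, "network.graphml"))
  logf("network", igraph::ecount(net$graph), " edges at threshold ",
       config$network_threshold)

  ctab <- run_stage("centrality", centrality_table(
    net, hub_fraction = config$hub_fraction,
    high_quantile = config$high_quantile))
  write_centrality_table(ctab, file.path(out_dir, "centrality.tsv"))
  hubs <- ctab$gene[ctab$hub]
  logf("centrality", length(hubs), " hubs (top ",
       100 * config$hub_fraction, "% by betweenness)")

  rtab <- run_stage("de", response_table(
    cexp, min_count = config$min_count, filter_rule = config$filter_rule,
    fc_threshold = config$fc_threshold, q_threshold = config$q_threshold,
    delta_threshold = config$delta_threshold))
  write_response_table(rtab, file.path(out_dir, "response.tsv"))
  responsive <- rtab$gene[rtab$responsive]
  logf("de", length(responsive), " ethylene-responsive genes of ",
       nrow(rtab), " tested")

  if (is.null(module_seeds)) {
    module_seeds <- if (!is.null(truth)) {
      intersect(truth$hubs, net$genes)
    } else head(ctab$gene[order(ctab$btw_rank)], 3)
  }
  modules <- run_stage("modules", lapply(module_seeds, function(sd) {
    extract_module(net, sd, threshold = config$network_threshold,
                   centrality = ctab, response = rtab,
                   tf_table = tf_table)
  }))
  names(modules) <- module_seeds
  for (sd in module_seeds)
    write_module(modules[[sd]],
                 file.path(out_dir, paste0("module_", sd, ".json")))
  logf("modules", length(modules), " seed-gene module(s) extracted")

  enrichment <- NULL
  if (!is.null(collection)) {
    enrichment <- run_stage("enrich", lapply(modules, function(m) {
      hypergeometric_enrichment(m$members, collection,
                                p_cutoff = config$enrichment_p)
    }))
    for (sd in names(enrichment))
      write_enrichment(enrichment[[sd]],
                       file.path(out_dir,
                                 paste0("enrichment_", sd, ".tsv")))
    logf("enrich", "enrichment computed for ", length(enrichment),
         " module(s) at p < ", config$enrichment_p)
  }

  summary <- list(
    seed = config$seed,
    parameters = unclass(config),
    n_genes_input = nrow(series$values),
    n_genes_expressed = nrow(filtered$values),
    n_edges = igraph::ecount(net$graph),
    n_hubs = length(hubs),
    hubs = sort(hubs),
    modules = lapply(modules, function(m)
      list(seed = m$seed, n_members = length(m$members),
           members = sort(m$members),
           summary = module_summary(m))),
    n_responsive = length(responsive),
    responsive_genes = sort(responsive),
    enrichment = lapply(enrichment, function(e)
      if (nrow(e)) e[, c("term", "k", "K", "p")] else NULL)
  )
  if (!is.null(truth)) {
    planted_hubs <- truth$hubs
    recovery <- vapply(seq_along(truth$modules), function(i) {
      m <- truth$modules[[i]]
      if (!m$hub %in% names(modules)) return(NA_real_)
      mean(m$members %in% modules[[m$hub]]$members)
    }, numeric(1))
    truth_resp <- truth$responders
    called <- responsive
    summary$ground_truth <- list(
      hub_recall = mean(planted_hubs %in% hubs),
      module_member_recovery = recovery,
      de_sensitivity = if (length(truth_resp))
        mean(truth_resp %in% called) else NA,
      de_fdr = if (length(called))
        mean(!called %in% truth_resp) else 0)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  logf("done", "summary written to ", file.path(out_dir, "summary.json"))
  invisible(summary)
}
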