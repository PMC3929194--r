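#' Validated pipeline configuration
#'
#' Collects every stage parameter with the study's printed defaults
#' (tau = 0.7, beta = 7, height cutoff = 0.99). Unknown keys and
#' out-of-range values are rejected before any computation runs.
#'
#' @param ... named overrides of the defaults listed below.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    tau = 0.7,                 # hard threshold on |r|
    beta = 7,                  # soft-thresholding power
    network = "soft",          # adjacency used for TOM/modules
    height_cutoff = 0.99,
    min_module_size = 20,
    n_top_degree = 6,
    n_top_bc = 5,
    bc_network_mode = "binary",  # network BC/closeness are computed on
    weight_transform = "reciprocal",
    enrichment_method = "fisher",
    p_adjust = "BH",
    edge_cutoff = 0.1,         # edge-list export cutoff
    quantile_normalize = TRUE,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, over)
  if (cfg$tau <= 0 || cfg$tau > 1)
    stop("tau must lie in (0, 1]", call. = FALSE)
  if (cfg$beta <= 0) stop("beta must be positive", call. = FALSE)
  if (cfg$height_cutoff <= 0 || cfg$height_cutoff > 1)
    stop("height_cutoff must lie in (0, 1]", call. = FALSE)
  if (cfg$min_module_size < 1)
    stop("min_module_size must be positive", call. = FALSE)
  if (cfg$n_top_degree < 0 || cfg$n_top_bc < 0)
    stop("candidate counts must be non-negative", call. = FALSE)
  if (!cfg$network %in% c("soft", "hard"))
    stop("network must be 'soft' or 'hard'", call. = FALSE)
  if (!cfg$bc_network_mode %in% c("binary", "weighted"))
    stop("bc_network_mode must be 'binary' or 'weighted'", call. = FALSE)
  if (!cfg$enrichment_method %in% c("fisher", "ease"))
    stop("enrichment_method must be 'fisher' or 'ease'", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Run the full coexpression analysis pipeline
#'
#' preprocess -> correlation -> hard & soft adjacency -> TOM -> module
#' detection -> topology & candidate selection, plus enrichment and trait
#' validation when gene sets / a trait table are supplied. Every stage writes
#' its output under `out_dir` and the run ends with a `manifest.json`
#' recording parameters, input fingerprints and per-stage summary counts, so
#' an identical config and inputs reproduce identical outputs.
#'
#' @param expr genes x samples log2 expression matrix, or path to a TSV in
#'   the [write_expression()] layout.
#' @param out_dir output directory (created if missing).
#' @param config a [pipeline_config()].
#' @param traits optional trait data.frame (or CSV path) for validation;
#'   needs `group`, `imf_percent`, `age_months`, `housekeeping` and one
#'   column per candidate gene to be validated.
#' @param gene_sets optional named list of gene sets (or GMT path) for module
#'   enrichment.
#' @param probe_map optional probe -> gene map; triggers probe collapsing.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(expr, out_dir, config = pipeline_config(),
                         traits = NULL, gene_sets = NULL, probe_map = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop("config must come from pipeline_config()", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(expr)) expr <- read_expression(expr)
  if (is.character(traits)) traits <- read_traits(traits)
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  set.seed(config$seed)
  manifest <- list(package = "coexhub",
                   version = as.character(utils::packageVersion("coexhub")),
                   config = unclass(config),
                   input = list(n_genes = nrow(expr),
                                n_samples = ncol(expr),
                                checksum = sprintf("%.10e", sum(expr))),
                   stages = list())
  write_manifest <- function()
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      write_manifest()
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- c(list(status = "ok"), res$summary)
    res$value
  }

  expr <- run_stage("preprocess", function() {
    out <- expr
    if (!is.null(probe_map)) out <- collapse_probes(out, probe_map)
    if (config$quantile_normalize) out <- quantile_normalize(out)
    write_expression(out, file.path(out_dir, "expression.tsv"))
    list(value = out, summary = list(n_genes = nrow(out)))
  })

  r <- run_stage("correlation", function()
    list(value = correlation_matrix(expr), summary = list()))

  nets <- run_stage("network", function() {
    hard <- hard_adjacency(r, config$tau)
    soft <- soft_adjacency(r, config$beta)
    n_hard <- write_edgelist(hard, file.path(out_dir, "edges_hard.tsv"),
                             cutoff = 1)
    n_soft <- write_edgelist(soft, file.path(out_dir, "edges_soft.tsv"),
                             cutoff = config$edge_cutoff)
    list(value = list(hard = hard, soft = soft),
         summary = list(hard_edges = n_hard, soft_edges = n_soft))
  })

  cluster_adj <- if (config$network == "soft") nets$soft else nets$hard
  assign <- run_stage("modules", function() {
    tom <- topological_overlap(cluster_adj)
    dend <- hierarchical_cluster(tom)
    a <- cut_modules(dend, config$height_cutoff, config$min_module_size)
    write.table(data.frame(gene_id = names(a$colors),
                           module_color = unname(a$colors)),
                file.path(out_dir, "module_assignment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summ <- module_summaries(a, cluster_adj)
    jsonlite::write_json(
      list(modules = summ$table,
           effective_mean_degree = summ$effective_mean_degree),
      file.path(out_dir, "module_summary.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(value = a,
         summary = list(n_modules = sum(summ$table$color != "grey"),
                        n_grey = sum(a$colors == "grey")))
  })

  profiles <- run_stage("topology", function() {
    prof <- node_topology(nets$hard, mode = config$bc_network_mode,
                          weight_transform = config$weight_transform)
    prof$connectivity <- as.numeric(rowSums(nets$soft))
    prof$module_color <- unname(assign$colors[prof$gene_id])
    write.table(prof, file.path(out_dir, "topology.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    fits <- tryCatch(list(
      power_law = degree_distribution_fit(prof$degree, "power_law"),
      truncated = degree_distribution_fit(prof$degree,
                                          "truncated_power_law")),
      error = function(e) NULL)
    if (!is.null(fits))
      jsonlite::write_json(
        lapply(fits, function(f)
          list(model = f$model, exponent_r = f$exponent_r,
               alpha = f$alpha, r_squared = f$r_squared)),
        file.path(out_dir, "degree_fit.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(value = prof, summary = list(n_genes = nrow(prof)))
  })

  candidates <- run_stage("candidates", function() {
    cand <- select_candidates(profiles, config$n_top_degree, config$n_top_bc)
    write.table(cand, file.path(out_dir, "candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = cand, summary = list(n_candidates = nrow(cand)))
  })

  if (!is.null(gene_sets)) {
    run_stage("enrichment", function() {
      universe <- rownames(expr)
      mods <- unique(assign$colors[assign$colors != "grey"])
      res <- do.call(rbind, lapply(mods, function(m) {
        genes <- names(assign$colors)[assign$colors == m]
        out <- fisher_enrichment(genes,
                                 lapply(gene_sets, intersect, universe),
                                 universe,
                                 method = config$enrichment_method,
                                 p_adjust = config$p_adjust)
        cbind(module = m, out)
      }))
      write.table(res, file.path(out_dir, "enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(value = res, summary = list(n_tests = nrow(res)))
    })
  }

  if (!is.null(traits)) {
    run_stage("validation", function() {
      genes <- intersect(candidates$gene_id, names(traits))
      stats_tab <- group_stats(traits)
      reports <- lapply(genes, function(g) {
        reg <- trait_regression(traits, g)
        corr <- expression_trait_correlation(traits, g)
        list(gene = g, fold_change = fold_change(traits, g),
             expression_coefficient = reg$expression_estimate,
             expression_p = reg$expression_p,
             r = corr$r, r_p = corr$p_value)
      })
      out <- list(group_stats = stats_tab, genes = reports)
      if (length(genes) >= 2) {
        pca <- candidate_pca(traits, genes)
        out$pca <- list(var_prop = pca$var_prop,
                        cum_prop_2 = pca$cum_prop[min(2,
                                       length(pca$cum_prop))],
                        pc2_relationship = as.list(pca$pc2_relationship))
      }
      jsonlite::write_json(out, file.path(out_dir, "validation.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      list(value = out, summary = list(n_validated = length(genes)))
    })
  }

  manifest$stages[["export"]] <- list(status = "ok")
  write_graphml(cluster_adj, file.path(out_dir, "network.graphml"),
                colors = assign$colors, profiles = profiles,
                cutoff = config$edge_cutoff)
  write_manifest()
  invisible(manifest)
}
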