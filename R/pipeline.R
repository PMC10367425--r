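#' Write a consensus network as SIF and GraphML
#'
#' SIF lines are `nodeA <tab> pp <tab> nodeB`, one per undirected edge;
#' GraphML is written through igraph with `layer` and `degree` node
#' attributes.
#'
#' @param network a `consensus_network` from [build_consensus_network()].
#' @param sif_path,graphml_path output file paths (either may be `NULL`).
#' @param layers optional named character vector mapping node -> source
#'   layer for the GraphML attributes.
#' @return Invisibly, the igraph object.
#' @export
write_network <- function(network, sif_path = NULL, graphml_path = NULL,
                          layers = NULL) {
  stopifnot(inherits(network, "consensus_network"))
  if (!is.null(sif_path)) {
    lines <- if (nrow(network$edges) == 0) character(0) else
      paste(network$edges$from, "pp", network$edges$to, sep = "\t")
    writeLines(lines, sif_path)
  }
  g <- igraph::graph_from_data_frame(
    network$edges[, c("from", "to"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = network$nodes,
                          stringsAsFactors = FALSE))
  igraph::V(g)$degree <- as.integer(network$degree[igraph::V(g)$name])
  if (!is.null(layers))
    igraph::V(g)$layer <- unname(layers[igraph::V(g)$name])
  if (!is.null(network$edges$strength) && nrow(network$edges) > 0)
    igraph::E(g)$strength <- network$edges$strength
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  invisible(g)
}

#' Run configuration for the full pipeline
#'
#' Collects every tunable of the end-to-end analysis with the study's
#' defaults: detection-rate threshold 0.40, technical-CV threshold 0.25,
#' Lactobacillus-dominance cutoff 0.50, 5 screened features per layer,
#' k = 3 inflammation groups, and the bootstrap scale. The `"desk"` preset
#' runs B = 200 bootstraps x 10 restarts; `"paper"` runs 1000 x 1000.
#'
#' @param seed master seed for the run.
#' @param scale `"desk"` or `"paper"`, or override `B` / `n_restarts`
#'   directly.
#' @param detection_threshold,cv_threshold,ld_threshold,n_top,k thresholds
#'   (see Description).
#' @param B,n_restarts bootstrap resamples and hill-climbing restarts;
#'   default from `scale`.
#' @param ess imaginary sample size; `NULL` (default) estimates it on the
#'   empty DAG with [estimate_imaginary_sample_size()].
#' @param max_parents parent cap for structure search.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, scale = c("desk", "paper"),
                       detection_threshold = 0.40, cv_threshold = 0.25,
                       ld_threshold = 0.50, n_top = 5, k = 3,
                       B = NULL, n_restarts = NULL, ess = NULL,
                       max_parents = 4) {
  scale <- match.arg(scale)
  if (is.null(B)) B <- if (scale == "paper") 1000L else 200L
  if (is.null(n_restarts))
    n_restarts <- if (scale == "paper") 1000L else 10L
  structure(list(seed = as.integer(seed), scale = scale,
                 detection_threshold = detection_threshold,
                 cv_threshold = cv_threshold, ld_threshold = ld_threshold,
                 n_top = as.integer(n_top), k = as.integer(k),
                 B = as.integer(B), n_restarts = as.integer(n_restarts),
                 ess = ess, max_parents = as.integer(max_parents)),
            class = "run_config")
}

#' End-to-end multi-omics analysis run
#'
#' Orchestrates the full workflow on a cohort (by default a synthetic one
#' generated from `truth`): panel preprocessing, inflammation grouping,
#' metaproteome summarization, per-layer Kruskal-Wallis contrasts, feature
#' screening, and the bootstrapped Bayesian-network consensus. All outputs
#' are written as plain text under `out_dir` together with a YAML manifest
#' recording the seed and every parameter; re-running with the same config
#' and cohort is deterministic.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @param cohort a cohort list as produced by [generate_cohort()]; by
#'   default one is generated from `truth` with the config seed.
#' @param truth a [synthetic_truth()] used when `cohort` is `NULL`.
#' @return Invisibly, a list with the inflammation `assignment`, the
#'   per-layer statistics, the `network`, and the manifest.
#' @export
run_full_pipeline <- function(config = run_config(), out_dir,
                              cohort = NULL, truth = synthetic_truth()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 4)
  if (is.null(cohort)) cohort <- generate_cohort(truth, seed = seeds[1])

  # --- preprocessing ---------------------------------------------------
  cyto <- filter_by_detection_rate(cohort$layers$cytokine,
                                   config$detection_threshold, quiet = TRUE)
  cyto <- impute_half_min_lod(cyto)
  metab <- filter_by_detection_rate(cohort$layers$metabolite,
                                    config$detection_threshold, quiet = TRUE)
  metab <- impute_zero_replacement(metab)
  host <- filter_by_technical_cv(cohort$layers$host_protein,
                                 cohort$reference_replicates,
                                 config$cv_threshold, quiet = TRUE)

  # --- inflammation grouping -------------------------------------------
  panel <- select_curated_panel(cyto)
  assignment <- cluster_inflammation_groups(panel, k = config$k)
  write.table(assignment, file.path(out_dir, "inflammation_assignment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  groups <- setNames(as.character(assignment$group), assignment$participant)

  # --- metaproteome ----------------------------------------------------
  taxa_profile <- compute_taxa_abundance(cohort$spectral_counts)
  ld <- classify_lactobacillus_dominance(taxa_profile,
                                         threshold = config$ld_threshold)
  write.table(data.frame(participant = names(ld), ld = ld,
                         row.names = NULL),
              file.path(out_dir, "lactobacillus_dominance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  layers <- list(cytokine = cyto, immune_cell = cohort$layers$immune_cell,
                 host_protein = host, metabolite = metab,
                 taxa = cohort$layers$taxa,
                 bact_function = cohort$layers$bact_function,
                 bact_protein = cohort$layers$bact_protein)

  # --- group statistics ------------------------------------------------
  stats_by_layer <- lapply(names(layers), function(ln) {
    res <- kw_layer_test(layers[[ln]], groups)
    write.table(res, file.path(out_dir, paste0("kw_inflammation_", ln,
                                               ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })
  names(stats_by_layer) <- names(layers)

  # --- network ----------------------------------------------------------
  cc <- complete_case_filter(layers)
  names(cc) <- names(layers)
  dm <- build_network_input(cc, assignment, n_top = config$n_top,
                            seed = seeds[2])
  ess <- config$ess
  if (is.null(ess)) ess <- estimate_imaginary_sample_size(dm)
  strengths <- bootstrap_arc_strengths(dm, ess = ess, B = config$B,
                                       n_restarts = config$n_restarts,
                                       seed = seeds[3],
                                       max_parents = config$max_parents)
  write.table(as.data.frame(strengths),
              file.path(out_dir, "arc_strengths.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  network <- build_consensus_network(strengths)
  write_network(network,
                sif_path = file.path(out_dir, "consensus_network.sif"),
                graphml_path = file.path(out_dir, "consensus_network.graphml"),
                layers = dm$layers)

  manifest <- list(
    package_version = as.character(utils::packageVersion("mucosanet")),
    seed = config$seed, scale = config$scale,
    detection_threshold = config$detection_threshold,
    cv_threshold = config$cv_threshold,
    ld_threshold = config$ld_threshold,
    n_top = config$n_top, k = config$k,
    B = config$B, n_restarts = config$n_restarts,
    ess = ess, max_parents = config$max_parents,
    threshold = network$threshold,
    n_networks = network$provenance$n_networks,
    n_nodes = length(network$nodes), n_edges = nrow(network$edges))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(assignment = assignment, ld = ld,
                 stats = stats_by_layer, network = network,
                 ess = ess, manifest = manifest))
}
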