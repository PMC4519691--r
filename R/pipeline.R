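.pipeline_defaults <- list(
  seed = 1, outdir = "coexmod_run",
  # input files (all optional; missing expression triggers simulation)
  expr_tsv = NULL, design_tsv = NULL, probe_map_tsv = NULL,
  catalog_tsv = NULL, ortholog_tsv = NULL, ref_network_tsv = NULL,
  promoter_fasta = NULL, motif_tsv = NULL,
  # simulation
  sim = list(),
  # stage parameters
  beta = 8, pick_beta = FALSE, min_module_size = 30, cut_height = 0.995,
  deep_split = 2, n_perm = 200, fc_threshold = 4, p_threshold = 0.05,
  hub_top_frac = 0.2, guide_top_frac = 0.05, guide_fc = 2, top_n = 100,
  edge_min = NULL, edge_quantile = 0.05, inflation = 2, bins = 5,
  mic_max_grid = NULL, guide_gene = NULL, normalize = NULL,
  run_alternatives = TRUE, keep_edge_frac = 0.8, weight_noise_sd = 0.1
)

#' Build and validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list; unknown keys are rejected and
#' threshold ranges are validated before any computation. All randomness
#' downstream flows from the single `seed` via named per-stage substreams.
#'
#' @param config YAML path or named list overriding the defaults.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), names(.pipeline_defaults))
  if (length(unknown)) {
    stop2("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(.pipeline_defaults, config)
  if (cfg$cut_height <= 0 || cfg$cut_height > 1) {
    stop2("`cut_height` must be in (0, 1]")
  }
  if (cfg$fc_threshold < 1 || cfg$guide_fc < 1) stop2("fold thresholds must be >= 1")
  if (cfg$p_threshold <= 0 || cfg$p_threshold > 1) stop2("`p_threshold` must be in (0, 1]")
  check_fraction(cfg$hub_top_frac, "hub_top_frac", allow_zero = FALSE)
  check_fraction(cfg$guide_top_frac, "guide_top_frac", allow_zero = FALSE)
  check_fraction(cfg$edge_quantile, "edge_quantile", allow_zero = FALSE)
  if (cfg$n_perm < 1 || cfg$top_n < 1 || cfg$bins < 2) {
    stop2("`n_perm`, `top_n` must be >= 1 and `bins` >= 2")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full co-expression annotation workflow
#'
#' Executes, in order: data acquisition (file inputs or seeded
#' simulation), preprocessing (rank-invariant normalization, intensity
#' filtering, optional probe collapse, log2), network construction
#' (soft-thresholded Pearson adjacency and TOM), module detection
#' (TOM hierarchical clustering), permutation quality statistics,
#' differential-expression calling and module DEG profiles, hub-based
#' candidate selection, conserved-neighborhood annotation transfer,
#' guide-gene subnetwork, alternative-method consensus (Spearman, CLR-MI,
#' CLR-MIC networks clustered with MCL), and promoter motif scanning.
#' Every intermediate is persisted as TSV/FASTA/GraphML under `outdir`,
#' and a JSON manifest records parameters, seeds, per-stage counts and
#' md5 checksums of every output. Identical config + seed gives
#' byte-identical outputs and manifest.
#'
#' @param config a [pipeline_config()] (or list / YAML path coerced to one).
#' @return The manifest, invisibly (a list; also written to
#'   `outdir/manifest.json`).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  counts <- list()
  emit <- function(name, writer) {
    path <- file.path(cfg$outdir, name)
    writer(path)
    outputs <<- c(outputs, name)
    path
  }
  log_stage <- function(stage, ...) {
    message(sprintf("[coexmod] %s: %s", stage, sprintf(...)))
  }

  ## data ---------------------------------------------------------------
  truth <- NULL
  if (is.null(cfg$expr_tsv)) {
    sim_args <- utils::modifyList(list(seed = cfg$seed), cfg$sim)
    sc <- do.call(sim_config, sim_args)
    design <- sim_design()
    sim <- simulate_expression(sc, design)
    expr_lin <- sim$expr
    truth <- sim$truth
    pr <- simulate_promoters(truth, seed = stage_seed(cfg$seed, "promoters"))
    truth <- pr$truth
    promoters <- pr$sequences
    catalog <- make_catalog(truth)
    orthologs <- truth$ortholog_pairs
    refnet <- simulate_reference_network(
      truth, keep_edge_frac = cfg$keep_edge_frac,
      weight_noise_sd = cfg$weight_noise_sd,
      seed = stage_seed(cfg$seed, "refnet"))
    guide <- cfg$guide_gene %||% truth$guide_gene
    emit("expression_raw.tsv", function(p) write_expr_tsv(expr_lin, p))
    emit("design.tsv", function(p) write_design_tsv(design, p))
    emit("truth.txt", function(p) write_truth(truth, p))
    emit("promoters.fa", function(p) write_fasta(promoters, p))
    emit("catalog.tsv", function(p) write_catalog_tsv(catalog, p))
    emit("orthologs.tsv", function(p) write_tsv(orthologs, p))
    emit("reference_network.tsv", function(p) write_tsv(refnet, p))
  } else {
    expr_lin <- read_expr_tsv(cfg$expr_tsv, scale = "linear")
    design <- read_design_tsv(cfg$design_tsv)
    catalog <- if (!is.null(cfg$catalog_tsv)) read_catalog_tsv(cfg$catalog_tsv)
    orthologs <- if (!is.null(cfg$ortholog_tsv)) read_ortholog_tsv(cfg$ortholog_tsv)
    refnet <- if (!is.null(cfg$ref_network_tsv)) read_edges_tsv(cfg$ref_network_tsv)
    promoters <- if (!is.null(cfg$promoter_fasta)) read_fasta(cfg$promoter_fasta)
    guide <- cfg$guide_gene
  }
  counts$genes_in <- nrow(expr_lin)
  log_stage("data", "%d genes x %d samples", nrow(expr_lin), ncol(expr_lin))

  ## preprocess ----------------------------------------------------------
  ## simulated data emulates an already-summarized, normalized matrix, so
  ## normalization defaults to the raw file-input path only
  do_norm <- cfg$normalize %||% !is.null(cfg$expr_tsv)
  norm <- if (isTRUE(do_norm)) rank_invariant_normalize(expr_lin) else expr_lin
  filt <- filter_probes(norm)
  if (!is.null(cfg$probe_map_tsv)) {
    pm <- read_probe_map(cfg$probe_map_tsv)
    filt <- collapse_probes(filt, pm, probe_max_fold(filt, design))
  }
  lg <- expr_log2(filt)
  counts$genes_filtered <- nrow(lg)
  emit("expression_log2.tsv", function(p) write_expr_tsv(lg, p))
  log_stage("preprocess", "%d genes retained", nrow(lg))

  ## network -------------------------------------------------------------
  beta <- cfg$beta
  if (isTRUE(cfg$pick_beta)) {
    st <- pick_soft_threshold(lg)
    beta <- st$chosen_beta
    emit("soft_threshold.tsv", function(p) write_tsv(st$table, p))
  }
  adj <- correlation_adjacency(lg, "pearson", beta = beta)
  tom <- tom_transform(adj)
  emit("tom.tsv", function(p) write_matrix_tsv(tom, p))
  log_stage("network", "pearson adjacency, beta = %d", beta)

  ## modules -------------------------------------------------------------
  partition <- cluster_tom(tom, min_module_size = cfg$min_module_size,
                           cut_height = cfg$cut_height,
                           deep_split = cfg$deep_split)
  emit("modules.tsv", function(p) write_partition_tsv(partition, p))
  counts$n_modules <- length(setdiff(unique(partition), GREY_LABEL))
  counts$n_grey <- sum(partition == GREY_LABEL)
  log_stage("modules", "%d modules, %d grey genes",
            counts$n_modules, counts$n_grey)

  quality <- module_quality(lg, adj, partition, n_perm = cfg$n_perm,
                            seed = stage_seed(cfg$seed, "quality"))
  emit("module_quality.tsv", function(p) write_tsv(quality, p))

  ## differential expression ---------------------------------------------
  degs <- call_degs(lg, design, fc_threshold = cfg$fc_threshold,
                    p_threshold = cfg$p_threshold)
  emit("degs.tsv", function(p) write_tsv(degs, p))
  profile <- module_deg_profile(partition, degs)
  emit("module_deg_profile.tsv", function(p) write_tsv(profile, p))
  ub <- ubiquitous_degs(degs)
  counts$n_ubiquitous_up <- length(ub$up_all)
  log_stage("degs", "%d ubiquitous up, %d down",
            length(ub$up_all), length(ub$down_all))

  ## candidates ----------------------------------------------------------
  k <- degree_centrality(adj)
  focal_module <- if (length(ub$up_all)) {
    labs <- partition[intersect(ub$up_all, names(partition))]
    labs <- labs[labs != GREY_LABEL]
    if (length(labs)) names(sort(table(labs), decreasing = TRUE))[1] else NULL
  } else NULL
  candidates <- character(0)
  hubs <- character(0)
  if (!is.null(focal_module) && !is.null(catalog)) {
    scope <- names(partition)[partition == focal_module]
    hubs <- select_hubs(k, scope, cfg$hub_top_frac)
    candidates <- candidate_uncharacterized(hubs, ub$up_all, catalog)
  }
  counts$n_candidates <- length(candidates)
  emit("candidates.tsv", function(p)
    write_tsv(data.frame(gene_id = candidates), p))
  log_stage("candidates", "%d hub+ubiquitous+uncharacterized genes",
            length(candidates))

  ## annotation transfer --------------------------------------------------
  report <- NULL
  if (length(candidates) && !is.null(refnet) && !is.null(orthologs)) {
    report <- conserved_neighborhood(candidates, refnet, orthologs, adj,
                                     partition, top_n = cfg$top_n,
                                     edge_min = cfg$edge_min)
    report <- transfer_labels(report, catalog)
  }

  ## guide subnetwork -----------------------------------------------------
  if (!is.null(guide) && !is.na(guide) && guide %in% rownames(adj)) {
    gs <- guide_subnetwork(adj, guide, top_frac = cfg$guide_top_frac,
                           degs = degs, fc = cfg$guide_fc,
                           p_threshold = cfg$p_threshold)
    emit("guide_neighbors.tsv", function(p) write_tsv(gs$neighbors, p))
    emit("guide_subnetwork.graphml", function(p)
      export_graphml(rbind(
        data.frame(gene1 = gs$guide, gene2 = gs$neighbors$gene_id,
                   weight = gs$neighbors$weight),
        gs$edges),
        node_attrs = data.frame(
          gene_id = c(gs$guide, gs$neighbors$gene_id),
          module = unname(partition[c(gs$guide, gs$neighbors$gene_id)]),
          direction = c("guide", gs$neighbors$direction)),
        path = p))
    counts$n_guide_neighbors <- nrow(gs$neighbors)
  } else {
    gs <- NULL
  }

  ## alternative methods + consensus --------------------------------------
  if (isTRUE(cfg$run_alternatives)) {
    nets <- list(pearson = adj,
                 spearman = correlation_adjacency(lg, "spearman", beta = beta))
    mi <- mutual_information_matrix(lg, bins = cfg$bins)
    nets$clr_mi <- clr_scores(mi)$z
    nets$clr_mic <- clr_scores(mic_approx_matrix(lg, cfg$mic_max_grid))$z
    edge_sets <- lapply(nets, threshold_edges, quantile_frac = cfg$edge_quantile)
    partitions <- lapply(edge_sets, mcl_cluster, inflation = cfg$inflation)
    for (nm in names(edge_sets)) {
      emit(sprintf("edges_%s.tsv", nm),
           local({ d <- edge_sets[[nm]]; function(p) write_tsv(d, p) }))
      emit(sprintf("modules_%s.tsv", nm),
           local({ d <- partitions[[nm]]; function(p) write_partition_tsv(d, p) }))
    }
    focal <- if (!is.null(gs)) c(gs$guide, gs$neighbors$gene_id) else candidates
    if (length(focal) >= 2) {
      cons <- cross_method_consensus(partitions, edge_sets, focal,
                                     anchor = if (!is.null(gs)) gs$guide)
      cons_df <- do.call(rbind, lapply(names(cons$per_method), function(nm) {
        pm <- cons$per_method[[nm]]
        data.frame(method = nm, modal_module = pm$modal_module,
                   n_co_clustered = pm$n_co_clustered, n_edges = pm$n_edges)
      }))
      cons_df$co_membership_fraction <- cons$co_membership_fraction
      emit("consensus.tsv", function(p) write_tsv(cons_df, p))
      counts$co_membership_fraction <- cons$co_membership_fraction
    }
  }

  ## motifs ---------------------------------------------------------------
  if (!is.null(promoters)) {
    motifs <- if (!is.null(cfg$motif_tsv)) read_motif_tsv(cfg$motif_tsv)
      else builtin_motifs()
    occ <- iupac_scan(promoters, motifs)
    emit("motif_occurrences.tsv", function(p) write_tsv(occ, p))
    if (length(candidates)) {
      enr <- motif_enrichment(occ, candidates, names(promoters))
      emit("motif_enrichment.tsv", function(p) write_tsv(enr, p))
      if (!is.null(report)) {
        report <- annotate_candidates_with_motifs(report, occ)
      }
    }
    counts$n_motif_hits <- nrow(occ)
  }
  if (!is.null(report)) {
    emit("candidate_report.tsv", function(p)
      write_tsv(transfer_report_table(report), p))
  }

  ## manifest --------------------------------------------------------------
  checksums <- tools::md5sum(file.path(cfg$outdir, outputs))
  names(checksums) <- outputs
  manifest <- list(
    package = "coexmod",
    version = as.character(utils::packageVersion("coexmod")),
    seed = cfg$seed,
    parameters = unclass(cfg)[setdiff(names(.pipeline_defaults),
                                      c("outdir"))],
    counts = counts,
    outputs = as.list(checksums)
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  log_stage("done", "%d outputs in %s", length(outputs), cfg$outdir)
  invisible(manifest)
}

#' Run the packaged synthetic demonstration
#'
#' A complete workflow run on the default synthetic dataset (500 genes,
#' 36 samples, 5 planted modules), producing the candidate annotation
#' report and all intermediates under `outdir`.
#'
#' @param outdir output directory.
#' @param seed root seed (default 1).
#' @param n_perm permutations for module quality (default 200).
#' @return The manifest, invisibly.
#' @export
coex_demo <- function(outdir = tempfile("coexmod_demo"), seed = 1,
                      n_perm = 200) {
  run_pipeline(list(outdir = outdir, seed = seed, n_perm = n_perm))
}

#' Export a network as GraphML
#'
#' Writes a GraphML file loadable by standard viewers, with the edge
#' weight kept to six significant digits and optional node attributes
#' (module color, DEG direction class, log2 fold change).
#'
#' @param edges data.frame `gene1, gene2, weight` (may be empty).
#' @param node_attrs optional data.frame keyed by `gene_id`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
export_graphml <- function(edges, node_attrs = NULL, path) {
  nodes <- unique(c(edges$gene1, edges$gene2,
                    if (!is.null(node_attrs)) node_attrs$gene_id))
  if (!length(nodes)) warning("exporting an empty graph")
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(match(edges$gene1, nodes),
                                    match(edges$gene2, nodes)))
    igraph::E(g)$weight <- signif(edges$weight, 6)
  }
  if (!is.null(node_attrs)) {
    for (col in setdiff(names(node_attrs), "gene_id")) {
      vals <- node_attrs[[col]][match(nodes, node_attrs$gene_id)]
      g <- igraph::set_vertex_attr(g, col, value = as.character(vals))
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
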