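#' Weighted degree centrality
#'
#' `k_i = sum_{j != i} a_ij`, the connectivity of each gene in the
#' weighted network.
#'
#' @param adj symmetric adjacency matrix.
#' @return Named numeric vector of weighted degrees.
#' @export
degree_centrality <- function(adj) {
  check_symmetric(adj, 1e-8, "adjacency")
  a <- adj
  diag(a) <- 0
  rowSums(a)
}

#' Select hub genes within a module
#'
#' The `ceiling(top_frac * |scope|)` genes of highest weighted degree
#' within `scope`; ties at the cutoff go to the lexicographically smaller
#' gene id. The ceiling convention means a 1,344-gene module at
#' `top_frac = 0.2` yields 269 hubs.
#'
#' @param k named degree vector from [degree_centrality()].
#' @param scope gene ids defining the module (non-empty).
#' @param top_frac fraction in (0, 1\] (default 0.2).
#' @return Character vector of hub gene ids.
#' @export
select_hubs <- function(k, scope, top_frac = 0.2) {
  if (!length(scope)) stop2("`scope` is empty")
  if (!is.numeric(top_frac) || top_frac <= 0 || top_frac > 1) {
    stop2("`top_frac` must be in (0, 1]")
  }
  ks <- k[intersect(scope, names(k))]
  n_hub <- ceiling(top_frac * length(ks))
  ord <- order(-ks, names(ks))
  sort(names(ks)[ord][seq_len(n_hub)])
}

#' Candidate uncharacterized genes
#'
#' The candidate chain of the workflow: genes that are module hubs, are
#' up-regulated in every contrast, and lack functional characterization.
#'
#' @param hubs hub gene ids.
#' @param up_all ubiquitously up-regulated gene ids
#'   (see [ubiquitous_degs()]).
#' @param catalog a catalog data.frame (`gene_id, status, ...`).
#' @return Sorted character vector of candidate gene ids.
#' @export
candidate_uncharacterized <- function(hubs, up_all, catalog) {
  unchar <- catalog$gene_id[catalog$status == "uncharacterized"]
  sort(intersect(intersect(hubs, up_all), unchar))
}

#' Conserved cross-species network neighborhoods of candidate genes
#'
#' For each candidate with a reference-species ortholog: take the
#' ortholog's `top_n` reference neighbors ranked by total edge weight, map
#' them back through the ortholog table, and keep those present in the
#' target network. A reference edge within \{ortholog + neighbors\} is
#' *conserved* when both back-mapped endpoints exist in the target network
#' with adjacency at least `edge_min` (default: the target network's 95th
#' percentile adjacency). Candidates without an ortholog are reported as
#' untransferable, mirroring the attrition seen with real ortholog
#' databases.
#'
#' @param candidates candidate gene ids (must be in the target network).
#' @param ref reference network data.frame `gene1, gene2, weight`.
#' @param orth ortholog data.frame `gene_id, ref_id`.
#' @param target_adj target-species adjacency matrix.
#' @param partition target `module_partition` (for the neighbor module
#'   distribution).
#' @param top_n reference neighbors per ortholog (study default 100).
#' @param edge_min target-adjacency threshold defining conservation.
#' @return List of class `transfer_report`: per-candidate entries
#'   (`ortholog`, `conserved_neighbors`, reference / target conserved edge
#'   counts, neighbor module table) plus pooled counts and the
#'   untransferable candidates.
#' @export
conserved_neighborhood <- function(candidates, ref, orth, target_adj,
                                   partition, top_n = 100, edge_min = NULL) {
  missing_t <- setdiff(candidates, rownames(target_adj))
  if (length(missing_t)) {
    stop2("candidate absent from target network: ",
          paste(missing_t, collapse = ", "))
  }
  if (is.null(edge_min)) {
    edge_min <- quantile(target_adj[upper.tri(target_adj)], 0.95, names = FALSE)
  }
  fwd <- setNames(orth$ref_id, orth$gene_id)      # target -> reference
  back <- split(orth$gene_id, orth$ref_id)        # reference -> target(s)
  per <- list()
  pooled_nodes <- character(0)
  pooled_edges <- 0L
  for (g in candidates) {
    if (!g %in% names(fwd)) next
    og <- fwd[[g]]
    inc <- ref[ref$gene1 == og | ref$gene2 == og, ]
    nb <- ifelse(inc$gene1 == og, inc$gene2, inc$gene1)
    score <- tapply(inc$weight, nb, sum)           # total edge weight score
    nb <- names(score)[order(-score, names(score))]
    nb <- nb[seq_len(min(top_n, length(nb)))]
    mapped <- unique(unlist(back[nb], use.names = FALSE))
    mapped <- intersect(mapped, rownames(target_adj))
    cluster <- c(og, nb)
    sub <- ref[ref$gene1 %in% cluster & ref$gene2 %in% cluster, ]
    cons_ref <- 0L
    cons_pairs <- character(0)
    for (e in seq_len(nrow(sub))) {
      t1 <- intersect(back[[sub$gene1[e]]] %||% character(0), rownames(target_adj))
      t2 <- intersect(back[[sub$gene2[e]]] %||% character(0), rownames(target_adj))
      if (!length(t1) || !length(t2)) next
      ok <- any(target_adj[t1, t2, drop = FALSE] >= edge_min)
      if (ok) {
        cons_ref <- cons_ref + 1L
        cons_pairs <- c(cons_pairs, paste(sub$gene1[e], sub$gene2[e]))
      }
    }
    conserved_nb <- intersect(mapped, names(partition))
    per[[g]] <- list(
      gene = g, ortholog = og,
      mapped_neighbors = sort(mapped),
      conserved_neighbors = sort(conserved_nb),
      conserved_edge_count_ref = cons_ref,
      conserved_edge_count_target =
        if (length(mapped) > 1) {
          sum(target_adj[mapped, mapped][upper.tri(diag(length(mapped)))] >= edge_min)
        } else 0L,
      neighbor_modules = table(partition[conserved_nb]))
    pooled_nodes <- union(pooled_nodes, mapped)
    pooled_edges <- pooled_edges + cons_ref
  }
  structure(list(
    per_candidate = per,
    untransferable = sort(setdiff(candidates, names(fwd))),
    pooled_conserved_nodes = sort(pooled_nodes),
    pooled_conserved_edges = pooled_edges,
    edge_min = edge_min
  ), class = "transfer_report")
}

#' Transfer functional labels through conserved neighborhoods
#'
#' For each candidate, every term carried by at least one conserved
#' neighbor is scored by the hypergeometric upper tail: the probability of
#' seeing at least as many term-carrying genes among the annotated
#' conserved neighbors, given the term's frequency in the universe. Terms
#' are ranked by p ascending (ties: more carriers, then lexicographic);
#' the assigned term is the top-ranked one with `p <= alpha`, else none.
#'
#' @param report a `transfer_report` from [conserved_neighborhood()].
#' @param catalog catalog data.frame with semicolon-delimited `labels`.
#' @param universe gene universe for the enrichment (default: all catalog
#'   genes).
#' @param alpha assignment threshold (default 0.05).
#' @return The report with per-candidate `term_ranking` (data.frame
#'   `term, x, n, K, N, p`) and `assigned_term` filled in.
#' @export
transfer_labels <- function(report, catalog, universe = NULL, alpha = 0.05) {
  stopifnot(inherits(report, "transfer_report"))
  if (is.null(universe)) universe <- catalog$gene_id
  cat_u <- catalog[catalog$gene_id %in% universe, ]
  labs <- strsplit(cat_u$labels, ";", fixed = TRUE)
  term_genes <- split(rep(cat_u$gene_id, lengths(labs)),
                      trimws(unlist(labs)))
  term_genes <- term_genes[nzchar(names(term_genes))]
  N <- length(universe)
  for (g in names(report$per_candidate)) {
    nb <- intersect(report$per_candidate[[g]]$conserved_neighbors, cat_u$gene_id)
    annotated <- nb[nb %in% unlist(term_genes, use.names = FALSE)]
    n <- length(annotated)
    if (n == 0) {
      report$per_candidate[[g]]$term_ranking <-
        data.frame(term = character(0), x = integer(0), n = integer(0),
                   K = integer(0), N = integer(0), p = numeric(0))
      report$per_candidate[[g]]$assigned_term <- NA_character_
      next
    }
    terms <- unique(unlist(lapply(annotated, function(gg) {
      trimws(strsplit(cat_u$labels[cat_u$gene_id == gg], ";")[[1]])
    })))
    terms <- terms[nzchar(terms)]
    rk <- do.call(rbind, lapply(terms, function(tt) {
      K <- length(term_genes[[tt]])
      x <- sum(annotated %in% term_genes[[tt]])
      data.frame(term = tt, x = x, n = n, K = K, N = N,
                 p = phyper(x - 1, K, N - K, n, lower.tail = FALSE))
    }))
    rk <- rk[order(rk$p, -rk$x, rk$term), ]
    rownames(rk) <- NULL
    report$per_candidate[[g]]$term_ranking <- rk
    report$per_candidate[[g]]$assigned_term <-
      if (nrow(rk) && rk$p[1] <= alpha) rk$term[1] else NA_character_
  }
  report
}

#' Guide-gene first-neighbor subnetwork
#'
#' Ranks all other genes by adjacency to the guide gene, keeps the top
#' `ceiling(top_frac * (n - 1))` (the guide-gene approach: query the
#' network with one known gene, e.g. a transcription factor, and study its
#' strongest neighbors), and classifies each neighbor as up / down / none
#' from the DEG table at the secondary fold threshold (default 2) in any
#' of the given contrasts. Neighbor-neighbor edges at or above
#' `edge_export_min` are included.
#'
#' @param adj adjacency matrix.
#' @param guide guide gene id (must be present).
#' @param top_frac neighbor fraction (study default 0.05).
#' @param degs optional [call_degs()] table re-thresholded at `fc`.
#' @param contrasts optional data.frame `tissue, stage` restricting the
#'   classification; default all contrasts in `degs`.
#' @param fc secondary fold threshold for the classification (default 2).
#' @param p_threshold p cutoff for the classification.
#' @param edge_export_min adjacency threshold for neighbor-neighbor edges
#'   (default: median adjacency among neighbors).
#' @return List of class `guide_subnetwork`: `guide`, `neighbors`
#'   (data.frame `gene_id, weight, direction`), `edges`.
#' @export
guide_subnetwork <- function(adj, guide, top_frac = 0.05, degs = NULL,
                             contrasts = NULL, fc = 2, p_threshold = 0.05,
                             edge_export_min = NULL) {
  if (!guide %in% rownames(adj)) stop2("guide gene not in the network: ", guide)
  if (top_frac <= 0 || top_frac > 1) stop2("`top_frac` must be in (0, 1]")
  w <- adj[guide, setdiff(colnames(adj), guide)]
  n_keep <- ceiling(top_frac * length(w))
  ord <- order(-w, names(w))
  nb <- names(w)[ord][seq_len(n_keep)]
  direction <- rep("none", length(nb))
  if (!is.null(degs)) {
    tab <- degs
    if (!is.null(contrasts)) {
      tab <- tab[paste(tab$tissue, tab$stage) %in%
                   paste(contrasts$tissue, contrasts$stage), ]
    }
    cls <- function(g) {
      sub <- tab[tab$gene_id == g & tab$p_value <= p_threshold, ]
      if (any(sub$fold_change >= fc)) "up"
      else if (any(sub$fold_change <= 1 / fc)) "down"
      else "none"
    }
    direction <- vapply(nb, cls, character(1))
  }
  sub <- adj[nb, nb, drop = FALSE]
  if (is.null(edge_export_min)) {
    ut <- sub[upper.tri(sub)]
    edge_export_min <- if (length(ut)) median(ut) else 0
  }
  edges <- threshold_edges(sub, min_score = edge_export_min)
  structure(list(
    guide = guide,
    neighbors = data.frame(gene_id = nb, weight = unname(w[nb]),
                           direction = unname(direction)),
    edges = edges,
    edge_export_min = edge_export_min
  ), class = "guide_subnetwork")
}

#' Cross-method consensus for a focal gene set
#'
#' Given partitions and thresholded edge sets from several inference
#' methods, reports per method how many focal genes share the focal set's
#' modal module and how many edges run among focal pairs (or, when an
#' anchor gene is given, between the anchor and the other focal genes).
#' The summary is the fraction of focal pairs co-clustered in at least
#' half of the methods.
#'
#' @param partitions named list of `module_partition`s (>= 2).
#' @param networks named list of edge data.frames (`gene1, gene2, weight`),
#'   parallel to `partitions`.
#' @param focal focal gene set.
#' @param anchor optional anchor gene id.
#' @return List of class `consensus_report` with `per_method` and
#'   `co_membership_fraction`.
#' @export
cross_method_consensus <- function(partitions, networks, focal,
                                   anchor = NULL) {
  if (length(partitions) < 2) stop2("need >= 2 methods")
  stopifnot(length(partitions) == length(networks))
  methods <- names(partitions) %||% paste0("method", seq_along(partitions))
  pairs <- if (length(focal) > 1) t(combn(sort(focal), 2)) else
    matrix(character(0), 0, 2)
  co <- matrix(FALSE, nrow(pairs), length(partitions))
  per <- list()
  for (mi in seq_along(partitions)) {
    part <- partitions[[mi]]
    present <- focal[focal %in% names(part)]
    if (length(present) < length(focal)) {
      warning(sprintf("method %s: %d focal genes missing from its universe",
                      methods[mi], length(focal) - length(present)))
    }
    labs <- part[present]
    modal <- if (length(labs)) names(sort(table(labs), decreasing = TRUE))[1]
      else NA_character_
    n_modal <- sum(labs == modal)
    net <- networks[[mi]]
    if (is.null(anchor)) {
      n_edges <- sum(net$gene1 %in% focal & net$gene2 %in% focal)
    } else {
      n_edges <- sum((net$gene1 == anchor & net$gene2 %in% focal) |
                       (net$gene2 == anchor & net$gene1 %in% focal))
    }
    if (nrow(pairs)) {
      in1 <- pairs[, 1] %in% present
      in2 <- pairs[, 2] %in% present
      same <- in1 & in2
      same[same] <- part[pairs[same, 1]] == part[pairs[same, 2]] &
        part[pairs[same, 1]] != GREY_LABEL
      co[, mi] <- same
    }
    per[[methods[mi]]] <- list(modal_module = modal,
                               n_co_clustered = n_modal,
                               n_edges = n_edges)
  }
  frac <- if (nrow(pairs)) {
    mean(rowSums(co) >= ceiling(length(partitions) / 2))
  } else NA_real_
  structure(list(per_method = per, co_membership_fraction = frac,
                 anchor = anchor),
            class = "consensus_report")
}

#' Flatten a transfer report to a Table-1-shaped data.frame
#'
#' One row per candidate: ortholog (or none), conserved neighbor / edge
#' counts, assigned term, and the promoter-motif column (filled by
#' [annotate_candidates_with_motifs()]).
#'
#' @param report a `transfer_report`.
#' @return data.frame.
#' @export
transfer_report_table <- function(report) {
  rows <- lapply(report$per_candidate, function(pc) {
    data.frame(gene_id = pc$gene, ortholog = pc$ortholog,
               n_conserved_neighbors = length(pc$conserved_neighbors),
               conserved_edges_ref = pc$conserved_edge_count_ref,
               conserved_edges_target = pc$conserved_edge_count_target,
               assigned_term = pc$assigned_term %||% NA_character_,
               motifs = pc$motifs %||% "")
  })
  un <- lapply(report$untransferable, function(g) {
    data.frame(gene_id = g, ortholog = NA_character_,
               n_conserved_neighbors = 0L, conserved_edges_ref = 0L,
               conserved_edges_target = 0L, assigned_term = NA_character_,
               motifs = "")
  })
  out <- do.call(rbind, c(rows, un))
  rownames(out) <- NULL
  out
}

#' Read a two-column ortholog TSV (`gene_id`, `ref_id`)
#' @param path file path.
#' @export
read_ortholog_tsv <- function(path) {
  df <- read_tsv(path)
  names(df)[1:2] <- c("gene_id", "ref_id")
  if (anyDuplicated(df)) df <- unique(df)
  df
}

#' Read a three-column weighted edge TSV (`gene1`, `gene2`, `weight`)
#' @param path file path.
#' @export
read_edges_tsv <- function(path) {
  df <- read_tsv(path)
  names(df)[1:3] <- c("gene1", "gene2", "weight")
  df$weight <- as.numeric(df$weight)
  df
}

#' Read / write a gene catalog TSV (`gene_id status is_tf labels`)
#' @param catalog catalog data.frame.
#' @param path file path.
#' @export
write_catalog_tsv <- function(catalog, path) write_tsv(catalog, path)

#' @rdname write_catalog_tsv
#' @export
read_catalog_tsv <- function(path) {
  df <- read_tsv(path)
  df$labels[is.na(df$labels)] <- ""
  df$is_tf <- as.logical(df$is_tf)
  df
}
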