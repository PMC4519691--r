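#' Module color palette
#'
#' Deterministic label order for modules ranked by size (largest first);
#' beyond the named colors, labels continue as `module-17`, `module-18`, ...
#'
#' @param n number of labels needed.
#' @return Character vector of labels.
#' @export
module_colors <- function(n) {
  pal <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
           "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
           "cyan", "midnightblue", "lightcyan")
  if (n <= length(pal)) return(pal[seq_len(n)])
  c(pal, sprintf("module-%d", seq(length(pal) + 1L, n)))
}

#' Unassigned-module label
#' @export
GREY_LABEL <- "grey"

# rank clusters by size (desc) and relabel with the fixed palette
label_by_size <- function(assignment) {
  labs <- setdiff(unique(assignment), GREY_LABEL)
  if (!length(labs)) return(assignment)
  sizes <- table(factor(assignment[assignment != GREY_LABEL], levels = labs))
  ord <- names(sizes)[order(-as.vector(sizes), names(sizes))]
  new <- setNames(module_colors(length(ord)), ord)
  out <- assignment
  out[assignment != GREY_LABEL] <- new[assignment[assignment != GREY_LABEL]]
  out
}

#' Detect modules by hierarchical clustering of topological overlap
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`,
#' cut statically at `cut_height`; branches holding at least
#' `min_module_size` genes become modules. `deep_split` in 0..4 triggers a
#' secondary within-branch re-cut at the \{1.00, 0.95, 0.90, 0.85, 0.80\}
#' quantile of the branch's own join heights (a documented simplification
#' of the adaptive tree-cut): when the re-cut produces two or more
#' sub-branches of `min_module_size`, those replace the branch and the
#' leftover genes go to `"grey"`. Modules are ranked by size and labeled
#' from the fixed color palette, largest = `"turquoise"`.
#'
#' @param tom TOM matrix from [tom_transform()].
#' @param min_module_size smallest reportable module (study default 200;
#'   scale to the data at hand).
#' @param cut_height static tree-cut height in (0, 1\] (default 0.995).
#' @param deep_split split aggressiveness, integer 0..4 (default 2).
#' @return Named character vector gene -> module label (class
#'   `module_partition`), unassigned genes labeled `"grey"`.
#' @export
cluster_tom <- function(tom, min_module_size = 200, cut_height = 0.995,
                        deep_split = 2) {
  check_symmetric(tom, 1e-8, "TOM")
  if (cut_height <= 0 || cut_height > 1) stop2("`cut_height` must be in (0, 1]")
  if (!deep_split %in% 0:4) stop2("`deep_split` must be an integer in 0..4")
  genes <- rownames(tom)
  n <- length(genes)
  if (min_module_size > n) {
    warning("min_module_size exceeds gene count; everything is grey")
    return(structure(setNames(rep(GREY_LABEL, n), genes),
                     class = "module_partition"))
  }
  diss <- 1 - tom
  h <- hclust(as.dist(diss), method = "average")
  h$height <- cummax(h$height)     # guard tiny tie-induced inversions
  primary <- cutree(h, h = min(cut_height, max(h$height)))
  q <- c(1.00, 0.95, 0.90, 0.85, 0.80)[deep_split + 1L]

  assignment <- setNames(rep(GREY_LABEL, n), genes)
  nxt <- 0L
  for (b in unique(primary)) {
    members <- genes[primary == b]
    if (length(members) < min_module_size) next
    sub_labels <- NULL
    if (q < 1 && length(members) >= 2 * min_module_size) {
      hs <- hclust(as.dist(diss[members, members]), method = "average")
      hs$height <- cummax(hs$height)
      hcut <- quantile(hs$height, q, names = FALSE)
      sub <- cutree(hs, h = hcut * (1 + 1e-9) + 1e-12)
      sizes <- table(sub)
      big <- names(sizes)[sizes >= min_module_size]
      if (length(big) >= 2) {
        sub_labels <- ifelse(sub %in% big, paste0("tmp", nxt + as.integer(factor(sub, levels = big))), GREY_LABEL)
        nxt <- nxt + length(big)
      }
    }
    if (is.null(sub_labels)) {
      nxt <- nxt + 1L
      assignment[members] <- paste0("tmp", nxt)
    } else {
      assignment[members] <- sub_labels
    }
  }
  structure(label_by_size(assignment), class = "module_partition")
}

#' Markov clustering of a weighted network
#'
#' Classic MCL: self-loops set to each node's maximum incident weight,
#' columns normalized to a stochastic matrix, then alternating expansion
#' (matrix power), inflation (element-wise power with column
#' renormalization) and pruning of entries below `prune_below`, until the
#' maximum column-wise change drops under `1e-6` or `max_iter` is reached.
#' Clusters are connected components of the non-zero attractor structure;
#' singleton components are labeled `"grey"`. The result is invariant to
#' uniform scaling of all edge weights.
#'
#' @param w symmetric non-negative weight matrix, or a `gene1, gene2,
#'   weight` edge data.frame.
#' @param inflation inflation exponent r (default 2).
#' @param expansion expansion power (default 2).
#' @param prune_below entries below this are zeroed each iteration.
#' @param max_iter iteration cap; on non-convergence the current
#'   interpretation is returned with attribute `converged = FALSE`.
#' @return A `module_partition` with attribute `converged`.
#' @export
mcl_cluster <- function(w, inflation = 2, expansion = 2,
                        prune_below = 1e-5, max_iter = 100) {
  if (is.data.frame(w)) w <- edges_to_matrix(w)
  check_symmetric(w, 1e-8, "weight matrix")
  if (any(w < 0)) stop2("weights must be non-negative")
  genes <- rownames(w) %||% as.character(seq_len(nrow(w)))
  m <- w
  diag(m) <- 0
  loops <- apply(m, 2, max)
  diag(m) <- ifelse(loops > 0, loops, 1)
  m <- sweep(m, 2, colSums(m), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    prev <- m
    for (e in seq_len(expansion - 1L)) m <- m %*% prev  # m = prev^expansion
    m <- m^inflation
    m[m < prune_below] <- 0
    cs <- colSums(m)
    cs[cs == 0] <- 1
    m <- sweep(m, 2, cs, "/")
    if (max(abs(m - prev)) < 1e-6) { converged <- TRUE; break }
  }
  if (!converged) warning("MCL did not converge within max_iter")
  adj <- (m > 0) | (t(m) > 0)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  assignment <- setNames(paste0("tmp", comp), genes)
  sizes <- table(assignment)
  assignment[assignment %in% names(sizes)[sizes == 1]] <- GREY_LABEL
  structure(label_by_size(assignment), class = "module_partition",
            converged = converged)
}

edges_to_matrix <- function(df) {
  stopifnot(all(c("gene1", "gene2", "weight") %in% names(df)))
  genes <- sort(unique(c(df$gene1, df$gene2)))
  m <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  m[cbind(df$gene1, df$gene2)] <- df$weight
  m[cbind(df$gene2, df$gene1)] <- df$weight
  m
}

#' Permutation quality statistics for modules
#'
#' For each module, four observed statistics: mean intramodular adjacency
#' (density), mean absolute intramodular expression correlation (density),
#' the Spearman correlation between intramodular and whole-network
#' connectivity (connectivity), and mean absolute correlation with the
#' module mean profile (module membership). Each is compared against
#' `n_perm` random gene sets of the same size drawn from all network
#' genes: `Z = (obs - mean_null) / sd_null`; `Zdensity` and
#' `Zconnectivity` are the medians within each family,
#' `Zsummary = (Zdensity + Zconnectivity) / 2`, and `psummary` is the
#' median add-one-corrected one-sided empirical p-value across the four
#' statistics. `Zsummary > 10` with `psummary` near `1/(n_perm + 1)` is
#' strong evidence of a genuine module.
#'
#' @param x log2-scale [expr_mat()].
#' @param adj adjacency from [correlation_adjacency()].
#' @param partition a `module_partition` over the matrix genes.
#' @param n_perm permutations (study default 200).
#' @param seed integer seed for the null draws.
#' @return data.frame, one row per scored module; modules smaller than 3
#'   genes are skipped with a warning.
#' @export
module_quality <- function(x, adj, partition, n_perm = 200, seed = 7) {
  v <- unclass(x)
  genes <- intersect(rownames(v), rownames(adj))
  genes <- intersect(genes, names(partition))
  v <- v[genes, , drop = FALSE]
  adj <- adj[genes, genes]
  part <- partition[genes]
  k_all <- rowSums(adj)

  stat4 <- function(set) {
    a <- adj[set, set]
    off <- row(a) != col(a)
    cc <- cor(t(v[set, , drop = FALSE]))
    k_in <- rowSums(a)
    c(d1 = mean(a[off]),
      d2 = mean(abs(cc[off])),
      c1 = suppressWarnings(cor(k_in, k_all[set], method = "spearman")),
      c2 = mean(abs(cor(t(v[set, , drop = FALSE]), colMeans(v[set, , drop = FALSE])))))
  }

  mods <- setdiff(unique(part), GREY_LABEL)
  sizes <- vapply(mods, function(m) sum(part == m), integer(1))
  small <- sizes < 3
  if (any(small)) {
    warning("modules skipped (size < 3): ", paste(mods[small], collapse = ", "))
    mods <- mods[!small]; sizes <- sizes[!small]
  }
  if (!length(mods)) stop2("no scorable modules")

  set.seed(seed)
  null_by_size <- list()
  for (s in sort(unique(sizes))) {
    null_by_size[[as.character(s)]] <- t(vapply(
      seq_len(n_perm),
      function(i) stat4(sample(genes, s)),
      numeric(4)))
  }

  rows <- lapply(seq_along(mods), function(i) {
    m <- mods[i]
    obs <- stat4(names(part)[part == m])
    nulls <- null_by_size[[as.character(sizes[i])]]
    mu <- colMeans(nulls); sdev <- apply(nulls, 2, sd)
    z <- (obs - mu) / ifelse(sdev == 0, NA, sdev)
    p <- vapply(1:4, function(k) (1 + sum(nulls[, k] >= obs[k])) / (n_perm + 1),
                numeric(1))
    zd <- median(z[c("d1", "d2")]); zc <- median(z[c("c1", "c2")])
    data.frame(module = m, size = sizes[i],
               density_adj = obs["d1"], density_cor = obs["d2"],
               conn_cor = obs["c1"], membership = obs["c2"],
               Z_density_adj = z["d1"], Z_density_cor = z["d2"],
               Z_conn_cor = z["c1"], Z_membership = z["c2"],
               Zdensity = zd, Zconnectivity = zc,
               Zsummary = (zd + zc) / 2, psummary = median(p),
               n_permutations = n_perm, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Read / write a module partition as TSV (`gene_id`, `module`)
#' @param partition a `module_partition`.
#' @param path file path.
#' @export
write_partition_tsv <- function(partition, path) {
  write_tsv(data.frame(gene_id = names(partition),
                       module = unname(partition)), path)
}

#' @rdname write_partition_tsv
#' @export
read_partition_tsv <- function(path) {
  df <- read_tsv(path)
  structure(setNames(df$module, df$gene_id), class = "module_partition")
}
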