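test_that("weighted degree matches stars, zeros, and row-sum loops", {
  s <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  s[1, 2:5] <- s[2:5, 1] <- 1
  k <- degree_centrality(s)
  expect_equal(unname(k["a"]), 4)
  expect_true(all(k[c("b", "c", "d", "e")] == 1))
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(degree_centrality(z) == 0))
  a <- random_adjacency(20, 7)
  k2 <- degree_centrality(a)
  for (i in 1:20) expect_equal(unname(k2[i]), sum(a[i, -i]), tolerance = 1e-12)
})

test_that("hub selection uses the ceiling convention and lexical tie-break", {
  k <- setNames(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1), sprintf("g%02d", 1:10))
  expect_length(select_hubs(k, names(k), 0.2), 2)
  # the printed study count: 20% of a 1344-gene module is 269 hubs
  big <- setNames(seq_len(1344), sprintf("g%04d", 1:1344))
  expect_length(select_hubs(big, names(big), 0.2), 269)
  # tie at the cutoff: lexicographically smaller id wins
  kt <- setNames(c(5, 3, 3, 1), c("gA", "gC", "gB", "gD"))
  expect_setequal(select_hubs(kt, names(kt), 0.5), c("gA", "gB"))
  # full fraction returns the whole scope
  expect_setequal(select_hubs(k, names(k), 1), names(k))
  expect_error(select_hubs(k, names(k), 0), "top_frac")
  expect_error(select_hubs(k, character(0)), "empty")
})

test_that("candidate chain is plain set algebra", {
  catalog <- data.frame(gene_id = paste0("g", 1:6),
                        status = c("uncharacterized", "characterized",
                                   "uncharacterized", "characterized",
                                   "uncharacterized", "characterized"),
                        is_tf = FALSE, labels = "")
  expect_equal(candidate_uncharacterized(c("g1", "g2", "g3"),
                                         c("g1", "g2", "g4"), catalog), "g1")
  expect_length(candidate_uncharacterized(c("g1"), c("g2"), catalog), 0)
  all_char <- catalog; all_char$status <- "characterized"
  expect_length(candidate_uncharacterized(c("g1"), c("g1"), all_char), 0)
})

test_that("planted candidates are recovered exactly from synthetic truth", {
  sim <- simulate_expression(sim_config(seed = 3))
  tr <- sim$truth
  catalog <- make_catalog(tr)
  got <- candidate_uncharacterized(tr$hub_genes, tr$ubiquitous_up, catalog)
  want <- sort(intersect(intersect(tr$hub_genes, tr$ubiquitous_up),
                         tr$uncharacterized))
  expect_identical(got, want)
  expect_gt(length(want), 0)
})

test_that("conserved neighborhoods count back-mapped reference edges", {
  # target: 4 genes, fully connected with adjacency 1 among g1-g3
  adj <- matrix(0, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  adj[1:3, 1:3] <- 1; diag(adj) <- 0
  orth <- data.frame(gene_id = paste0("g", 1:3), ref_id = paste0("r", 1:3))
  ref <- data.frame(gene1 = c("r1", "r1", "r2"), gene2 = c("r2", "r3", "r3"),
                    weight = c(3, 2, 1))
  part <- structure(setNames(rep("red", 4), paste0("g", 1:4)),
                    class = "module_partition")
  rep1 <- conserved_neighborhood("g1", ref, orth, adj, part,
                                 top_n = 100, edge_min = 0.5)
  pc <- rep1$per_candidate$g1
  expect_equal(pc$ortholog, "r1")
  expect_setequal(pc$conserved_neighbors, c("g2", "g3"))
  # all three reference edges back-map onto target adjacency 1 >= 0.5
  expect_equal(pc$conserved_edge_count_ref, 3)
  # empty ortholog map -> untransferable
  rep2 <- conserved_neighborhood("g1", ref,
                                 orth[0, ], adj, part, edge_min = 0.5)
  expect_equal(rep2$untransferable, "g1")
  expect_equal(rep2$pooled_conserved_edges, 0)
  expect_error(conserved_neighborhood("missing", ref, orth, adj, part),
               "missing")
})

test_that("noise-free reference network reproduces exhaustive edge enumeration", {
  sim <- simulate_expression(sim_config(n_genes = 150, seed = 5))
  tr <- sim$truth
  net <- simulate_reference_network(tr, keep_edge_frac = 1,
                                    weight_noise_sd = 0, seed = 1)
  lg <- expr_log2(sim$expr)
  adj <- correlation_adjacency(lg, beta = 8)
  part <- structure(tr$module_of, class = "module_partition")
  cands <- intersect(tr$ortholog_pairs$gene_id,
                     intersect(tr$hub_genes, tr$ubiquitous_up))
  rep1 <- conserved_neighborhood(cands, net, tr$ortholog_pairs, adj, part,
                                 top_n = 1e6, edge_min = 0)
  for (g in names(rep1$per_candidate)) {
    og <- paste0("At_", g)
    # oracle: brute-force enumeration of reference edges in the cluster
    nb <- unique(c(net$gene2[net$gene1 == og], net$gene1[net$gene2 == og]))
    cl <- c(og, nb)
    n_edges <- sum(net$gene1 %in% cl & net$gene2 %in% cl)
    expect_equal(rep1$per_candidate[[g]]$conserved_edge_count_ref, n_edges)
  }
})

test_that("conserved edge counts are monotone in top_n and edge_min", {
  sim <- simulate_expression(sim_config(n_genes = 150, seed = 5))
  tr <- sim$truth
  net <- simulate_reference_network(tr, keep_edge_frac = 0.9,
                                    weight_noise_sd = 0.05, seed = 2)
  adj <- correlation_adjacency(expr_log2(sim$expr), beta = 8)
  part <- structure(tr$module_of, class = "module_partition")
  g <- intersect(tr$ortholog_pairs$gene_id,
                 intersect(tr$hub_genes, tr$ubiquitous_up))[1]
  e_small <- conserved_neighborhood(g, net, tr$ortholog_pairs, adj, part,
                                    top_n = 5, edge_min = 0)$pooled_conserved_edges
  e_large <- conserved_neighborhood(g, net, tr$ortholog_pairs, adj, part,
                                    top_n = 100, edge_min = 0)$pooled_conserved_edges
  expect_gte(e_large, e_small)
  e_strict <- conserved_neighborhood(g, net, tr$ortholog_pairs, adj, part,
                                     top_n = 100, edge_min = 0.5)$pooled_conserved_edges
  expect_lte(e_strict, e_large)
})

test_that("label transfer scores terms by the exact hypergeometric tail", {
  catalog <- data.frame(
    gene_id = paste0("g", 1:10),
    status = "characterized", is_tf = FALSE,
    labels = c(rep("termL", 5), rep("other", 5)))
  report <- structure(list(per_candidate = list(
    gX = list(gene = "gX", ortholog = "rX",
              conserved_neighbors = paste0("g", 1:3),
              conserved_edge_count_ref = 0, conserved_edge_count_target = 0)),
    untransferable = character(0)), class = "transfer_report")
  out <- transfer_labels(report, catalog, universe = paste0("g", 1:10))
  rk <- out$per_candidate$gX$term_ranking
  expect_equal(rk$p[rk$term == "termL"], choose(5, 3) / choose(10, 3),
               tolerance = 1e-12)
  # p ~ 0.083 misses the default 0.05 assignment cut but passes at 0.1
  expect_true(is.na(out$per_candidate$gX$assigned_term))
  out_r <- transfer_labels(report, catalog, universe = paste0("g", 1:10),
                           alpha = 0.1)
  expect_equal(out_r$per_candidate$gX$assigned_term, "termL")
  # unannotated neighbors -> no assignment
  cat2 <- catalog; cat2$labels <- ""
  out2 <- transfer_labels(report, cat2, universe = paste0("g", 1:10))
  expect_true(is.na(out2$per_candidate$gX$assigned_term))
})

test_that("transfer p-values are equivariant under gene renaming", {
  catalog <- data.frame(gene_id = paste0("g", 1:8), status = "characterized",
                        is_tf = FALSE,
                        labels = c(rep("L", 4), rep("M", 4)))
  rep1 <- structure(list(per_candidate = list(
    c1 = list(gene = "c1", ortholog = "r", conserved_neighbors = c("g1", "g2"),
              conserved_edge_count_ref = 0, conserved_edge_count_target = 0)),
    untransferable = character(0)), class = "transfer_report")
  p1 <- transfer_labels(rep1, catalog)$per_candidate$c1$term_ranking
  ren <- setNames(paste0("x", 1:8), paste0("g", 1:8))
  cat2 <- catalog; cat2$gene_id <- unname(ren[catalog$gene_id])
  rep2 <- rep1
  rep2$per_candidate$c1$conserved_neighbors <- unname(ren[c("g1", "g2")])
  p2 <- transfer_labels(rep2, cat2)$per_candidate$c1$term_ranking
  expect_equal(p1$p, p2$p, tolerance = 1e-15)
})

test_that("guide subnetworks take the ceiling top fraction and classify folds", {
  set.seed(40)
  n <- 101
  a <- random_adjacency(n, 8)
  guide <- rownames(a)[1]
  degs <- data.frame(gene_id = rownames(a), tissue = "leaf", stage = "t1",
                     fold_change = 2.5, log2fc = log2(2.5), p_value = 0.01,
                     direction = "none")
  gs <- guide_subnetwork(a, guide, top_frac = 0.05, degs = degs)
  expect_equal(nrow(gs$neighbors), 5)          # ceil(0.05 * 100)
  expect_true(all(gs$neighbors$direction == "up"))
  expect_false(guide %in% gs$neighbors$gene_id)
  # oracle: sort the guide's adjacency row
  want <- names(sort(a[guide, -1], decreasing = TRUE))[1:5]
  expect_setequal(gs$neighbors$gene_id, want)
  # full fraction returns every other gene
  gs_all <- guide_subnetwork(a, guide, top_frac = 1)
  expect_equal(nrow(gs_all$neighbors), n - 1)
  expect_error(guide_subnetwork(a, "absent"), "absent")
})

test_that("cross-method consensus counts modal co-membership and anchor edges", {
  part <- structure(setNames(rep(c("red", "blue"), each = 5),
                             paste0("g", 1:10)), class = "module_partition")
  net <- data.frame(gene1 = c("g1", "g1", "g2"), gene2 = c("g2", "g3", "g3"),
                    weight = 1)
  focal <- c("g1", "g2", "g3")
  cons <- cross_method_consensus(list(a = part, b = part),
                                 list(a = net, b = net), focal)
  expect_equal(cons$per_method$a$n_co_clustered, 3)
  expect_equal(cons$per_method$a$n_edges, 3)
  expect_equal(cons$co_membership_fraction, 1)
  # all-distinct partitions
  p2 <- structure(setNames(paste0("m", 1:10), paste0("g", 1:10)),
                  class = "module_partition")
  cons2 <- cross_method_consensus(list(a = p2, b = p2), list(a = net, b = net),
                                  focal)
  expect_equal(cons2$per_method$a$n_co_clustered, 1)
  expect_equal(cons2$co_membership_fraction, 0)
  # anchor counts only anchor-incident edges
  cons3 <- cross_method_consensus(list(a = part, b = part),
                                  list(a = net, b = net), focal, anchor = "g1")
  expect_equal(cons3$per_method$a$n_edges, 2)
  expect_error(cross_method_consensus(list(a = part), list(a = net), focal),
               ">= 2")
})

test_that("consensus tallies equal brute-force pair enumeration across methods", {
  set.seed(41)
  parts <- list(); nets <- list()
  genes <- sprintf("g%02d", 1:30)
  for (k in 1:4) {
    parts[[k]] <- structure(setNames(sample(c("red", "blue", "grey"), 30, TRUE),
                                     genes), class = "module_partition")
    idx <- t(combn(genes[1:10], 2))
    keep <- runif(nrow(idx)) < 0.3
    nets[[k]] <- data.frame(gene1 = idx[keep, 1], gene2 = idx[keep, 2],
                            weight = 1)
  }
  names(parts) <- names(nets) <- paste0("m", 1:4)
  focal <- genes[1:6]
  cons <- cross_method_consensus(parts, nets, focal)
  pairs <- t(combn(sort(focal), 2))
  co <- sapply(parts, function(p) {
    p[pairs[, 1]] == p[pairs[, 2]] & p[pairs[, 1]] != GREY_LABEL
  })
  expect_equal(cons$co_membership_fraction, mean(rowSums(co) >= 2))
  for (k in 1:4) {
    expect_equal(cons$per_method[[k]]$n_edges,
                 sum(nets[[k]]$gene1 %in% focal & nets[[k]]$gene2 %in% focal))
  }
})
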