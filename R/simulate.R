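#' Sample design for a tissue x stage x treatment expression study
#'
#' Builds a balanced factorial design: every (tissue, stage) cell has
#' `replicates` control and `replicates` stress arrays. The default
#' (3 tissues x 2 stages x 3 replicates x 2 treatments) yields 36 samples
#' split 18/18 by treatment, mirroring a multi-tissue drought microarray
#' design.
#'
#' @param tissues,stages character vectors of factor levels.
#' @param replicates replicates per (tissue, stage, treatment) cell (>= 2).
#' @return A data.frame with columns `sample_id`, `tissue`, `stage`,
#'   `treatment`, `replicate`.
#' @export
sim_design <- function(tissues = c("leaf", "root", "panicle"),
                       stages = c("tillering", "booting"),
                       replicates = 3) {
  if (replicates < 2) stop2("need >= 2 replicates per treatment arm")
  g <- expand.grid(replicate = seq_len(replicates),
                   treatment = c("control", "stress"),
                   stage = stages, tissue = tissues,
                   stringsAsFactors = FALSE)
  g <- g[, c("tissue", "stage", "treatment", "replicate")]
  g$sample_id <- sprintf("%s_%s_%s_r%d", g$tissue, g$stage,
                         substr(g$treatment, 1, 4), g$replicate)
  validate_design(g[, c("sample_id", "tissue", "stage", "treatment", "replicate")])
}

#' Configuration of the synthetic co-expression dataset
#'
#' The generator plants `n_modules` co-expressed gene modules via a
#' latent-factor model, designates hub genes with boosted factor loadings,
#' plants multiplicative drought-response effects, and labels a fraction of
#' genes as uncharacterized. Module 1 acts as the stress-responsive module:
#' it carries the ubiquitously up-regulated responders (differential in
#' every tissue/stage cell); the remaining modules carry cell-specific
#' responders. Planted responder folds are drawn log2-uniform in
#' `[2*deg_fold, 4*deg_fold]`, i.e. comfortably above the `deg_fold`
#' calling threshold, as real strongly induced stress genes are.
#'
#' @param n_genes total genes (default 500).
#' @param n_modules number of planted modules (default 5).
#' @param module_sizes integer vector of module sizes; default splits 80%
#'   of the genes equally, leaving the rest as unstructured background.
#' @param hub_frac fraction of each module designated hub genes.
#' @param within_module_cor target Pearson correlation between module
#'   genes, in (0, 1).
#' @param hub_cor_boost additive correlation-target boost for hub genes
#'   (total capped at 0.99).
#' @param noise_sd per-observation Gaussian noise SD on the log2 scale
#'   (must be > 0).
#' @param deg_fold differential-expression calling threshold (linear fold);
#'   planted responder folds lie in `[2*deg_fold, 4*deg_fold]`.
#' @param stress_shift log2 stress offset of the focal module's program
#'   (default 1): every module-1 gene is mildly induced under stress in
#'   proportion to its loading (about twofold), emulating a globally
#'   drought-responsive module; designated responders are strongly induced
#'   on top of this, and only their (>= `2*deg_fold`) folds are recorded
#'   as planted effects.
#' @param frac_uncharacterized fraction of genes lacking functional labels.
#' @param n_ubiquitous_up,n_ubiquitous_down genes of module 1 responding in
#'   every (tissue, stage) cell.
#' @param n_cell_degs cell-specific responders planted per non-focal module.
#' @param ortholog_frac fraction of genes with a reference-species ortholog.
#' @param seed integer root seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500, n_modules = 5, module_sizes = NULL,
                       hub_frac = 0.1, within_module_cor = 0.7,
                       hub_cor_boost = 0.2, noise_sd = 0.5, deg_fold = 4,
                       stress_shift = 1, frac_uncharacterized = 0.2,
                       n_ubiquitous_up = 12, n_ubiquitous_down = 1,
                       n_cell_degs = 12, ortholog_frac = 0.6, seed = 1) {
  if (is.null(module_sizes)) {
    module_sizes <- rep(floor(0.8 * n_genes / n_modules), n_modules)
  }
  if (length(module_sizes) != n_modules) {
    stop2("`module_sizes` must have length `n_modules`")
  }
  if (sum(module_sizes) > n_genes) {
    stop2("module sizes sum to more than `n_genes`")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop2("`noise_sd` must be > 0")
  if (deg_fold < 1) stop2("`deg_fold` must be >= 1")
  if (stress_shift < 0) stop2("`stress_shift` must be >= 0")
  check_fraction(hub_frac, "hub_frac")
  check_fraction(within_module_cor, "within_module_cor",
                 allow_zero = FALSE, allow_one = FALSE)
  check_fraction(frac_uncharacterized, "frac_uncharacterized")
  check_fraction(ortholog_frac, "ortholog_frac")
  if (hub_cor_boost < 0) stop2("`hub_cor_boost` must be >= 0")
  structure(list(
    n_genes = n_genes, n_modules = n_modules, module_sizes = module_sizes,
    hub_frac = hub_frac, within_module_cor = within_module_cor,
    hub_cor_boost = hub_cor_boost, noise_sd = noise_sd, deg_fold = deg_fold,
    stress_shift = stress_shift,
    frac_uncharacterized = frac_uncharacterized,
    n_ubiquitous_up = n_ubiquitous_up, n_ubiquitous_down = n_ubiquitous_down,
    n_cell_degs = n_cell_degs, ortholog_frac = ortholog_frac,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# term vocabulary attached to planted modules, cycled if n_modules > length
.module_term_pool <- c(
  "response to water deprivation", "regulation of transcription",
  "seed development", "photosynthesis", "lipid metabolic process",
  "response to abscisic acid", "proteolysis", "carbohydrate metabolic process"
)

#' Simulate a genes x samples expression matrix with planted structure
#'
#' Gene log2 expression is `baseline + loading * module_factor(cell) +
#' I(stress) * log2(planted fold) + N(0, noise_sd)`. The module factor is
#' drawn once per (module, tissue, stage) cell and shared by both treatment
#' arms, so co-expression reflects tissue/stage variation while planted
#' treatment effects stay orthogonal to it. Loadings are calibrated so the
#' expected correlation between two module genes equals
#' `within_module_cor` (hubs: `+ hub_cor_boost`); background genes are
#' independent noise, making the unassigned ("grey") label recoverable.
#'
#' @param config a [sim_config()].
#' @param design a [sim_design()] data.frame.
#' @return A list with `expr` (linear-scale [expr_mat()]) and `truth`, a
#'   `sim_truth` list recording module membership, hubs, planted effects,
#'   ortholog pairs, uncharacterized genes, the guide gene and its targets,
#'   and per-module term labels.
#' @export
simulate_expression <- function(config, design = sim_design()) {
  stopifnot(inherits(config, "sim_config"))
  design <- validate_design(design)
  set.seed(stage_seed(config$seed, "expression"))

  n <- config$n_genes
  genes <- sprintf("g%04d", seq_len(n))
  modules <- sprintf("M%d", seq_len(config$n_modules))
  module_of <- setNames(rep("none", n), genes)
  idx <- 1L
  for (m in seq_len(config$n_modules)) {
    sz <- config$module_sizes[m]
    module_of[genes[idx:(idx + sz - 1L)]] <- modules[m]
    idx <- idx + sz
  }

  hubs <- character(0)
  for (m in modules) {
    mg <- names(module_of)[module_of == m]
    n_hub <- ceiling(config$hub_frac * length(mg))
    if (n_hub > 0) hubs <- c(hubs, sort(mg[sample.int(length(mg), n_hub)]))
  }

  cells <- unique(design[, c("tissue", "stage")])
  cell_id <- function(tissue, stage) paste(tissue, stage, sep = ":")
  cell_ids <- cell_id(cells$tissue, cells$stage)
  sample_cell <- cell_id(design$tissue, design$stage)

  ## planted treatment effects -------------------------------------------
  draw_fold <- function(k) config$deg_fold * 2^runif(k, 1, 2)
  samp <- function(x, k) x[sample.int(length(x), min(k, length(x)))]
  effects <- list()
  m1 <- names(module_of)[module_of == modules[1]]
  m1_hubs <- intersect(hubs, m1)
  n_uh <- if (config$n_ubiquitous_up == 0) 0L else
    min(length(m1_hubs), max(2L, ceiling(2 * config$n_ubiquitous_up / 3)))
  ubiq_up <- c(samp(m1_hubs, n_uh),
               samp(setdiff(m1, m1_hubs),
                    max(0L, min(config$n_ubiquitous_up, length(m1)) - n_uh)))
  ubiq_down <- samp(setdiff(m1, ubiq_up), config$n_ubiquitous_down)
  for (g in ubiq_up) {
    effects[[g]] <- data.frame(gene_id = g, tissue = cells$tissue,
                               stage = cells$stage, fold = draw_fold(1))
  }
  for (g in ubiq_down) {
    effects[[g]] <- data.frame(gene_id = g, tissue = cells$tissue,
                               stage = cells$stage, fold = 1 / draw_fold(1))
  }
  if (config$n_modules > 1 && config$n_cell_degs > 0) {
    for (m in seq(2L, config$n_modules)) {
      mg <- names(module_of)[module_of == modules[m]]
      cell <- cells[1L + (m - 2L) %% nrow(cells), ]
      dg <- samp(mg, config$n_cell_degs)
      n_down <- floor(length(dg) / 4)
      fold <- draw_fold(length(dg))
      if (n_down > 0) fold[seq_len(n_down)] <- 1 / fold[seq_len(n_down)]
      effects[[length(effects) + 1L]] <-
        data.frame(gene_id = dg, tissue = cell$tissue, stage = cell$stage,
                   fold = fold)
    }
  }
  effects <- if (length(effects)) do.call(rbind, effects) else
    data.frame(gene_id = character(0), tissue = character(0),
               stage = character(0), fold = numeric(0))
  rownames(effects) <- NULL


  ## uncharacterized status and ortholog coverage, stratified over the
  ## hub+ubiquitous pool so the candidate chain always yields both
  ## transferable and untransferable candidates (mirroring real ortholog
  ## attrition), while overall fractions stay at their configured values
  cand_pool <- intersect(ubiq_up, hubs)
  rest <- setdiff(genes, cand_pool)
  orth_pool <- samp(cand_pool, ceiling(config$ortholog_frac * length(cand_pool)))
  with_orth <- c(orth_pool, rest[runif(length(rest)) < config$ortholog_frac])
  ortholog_pairs <- data.frame(gene_id = sort(with_orth),
                               ref_id = paste0("At_", sort(with_orth)))

  n_unchar <- round(config$frac_uncharacterized * n)
  u_orth <- samp(orth_pool, max(2L, round(config$frac_uncharacterized *
                                            length(orth_pool))))
  u_rest <- samp(setdiff(cand_pool, orth_pool), 1L)
  unchar <- c(u_orth, u_rest,
              samp(rest, max(0L, n_unchar - length(u_orth) - length(u_rest))))

  ## guide gene: first hub of module 2 (a transcription factor) ----------
  guide <- NA_character_
  guide_targets <- character(0)
  if (config$n_modules >= 2) {
    m2 <- names(module_of)[module_of == modules[2]]
    guide <- intersect(hubs, m2)[1]
    guide_targets <- setdiff(m2, guide)
  }

  ## expression ----------------------------------------------------------
  baseline <- rnorm(n, mean = 8, sd = 1.5)
  r <- config$within_module_cor
  r_hub <- min(r + config$hub_cor_boost, 0.99)
  loading <- ifelse(module_of == "none", 0,
                    config$noise_sd * sqrt(r / (1 - r)))
  loading[names(module_of) %in% hubs] <-
    config$noise_sd * sqrt(r_hub / (1 - r_hub))

  ## module programs over the design cells: decorrelated (QR) so that
  ## distinct modules are distinct expression programs, then unit-sd
  f0 <- matrix(rnorm(length(cell_ids) * config$n_modules),
               length(cell_ids), config$n_modules)
  if (config$n_modules > 1 && length(cell_ids) >= config$n_modules) {
    f0 <- qr.Q(qr(f0))
  }
  f0 <- apply(f0, 2, function(z) (z - mean(z)) / sd(z))
  fac <- t(f0)
  dimnames(fac) <- list(modules, cell_ids)

  ## log2 treatment-effect lookup per (gene, cell): the focal module is
  ## mildly induced as a whole (loading-proportional), strong responders
  ## are overwritten with their recorded total folds
  lfc <- matrix(0, n, length(cell_ids), dimnames = list(genes, cell_ids))
  lfc[module_of == modules[1], ] <-
    loading[module_of == modules[1]] * config$stress_shift
  if (nrow(effects)) {
    lfc[cbind(effects$gene_id, cell_id(effects$tissue, effects$stage))] <-
      log2(effects$fold)
  }
  mod_idx <- match(module_of, modules)           # NA for background
  fac_rows <- matrix(0, n, length(sample_cell))
  ok <- !is.na(mod_idx)
  fac_rows[ok, ] <- fac[mod_idx[ok], sample_cell, drop = FALSE]

  stress <- as.numeric(design$treatment == "stress")
  log2e <- baseline + loading * fac_rows +
    lfc[, sample_cell, drop = FALSE] %*% diag(stress) +
    matrix(rnorm(n * nrow(design), sd = config$noise_sd), n)
  dimnames(log2e) <- list(genes, design$sample_id)

  terms <- setNames(rep_len(.module_term_pool, config$n_modules), modules)
  truth <- structure(list(
    module_of = module_of, hub_genes = hubs, effects = effects,
    ubiquitous_up = sort(ubiq_up), ubiquitous_down = sort(ubiq_down),
    ortholog_pairs = ortholog_pairs, uncharacterized = sort(unchar),
    guide_gene = guide, guide_targets = sort(guide_targets),
    planted_motifs = data.frame(gene_id = character(0), motif = character(0),
                                position = integer(0), strand = character(0)),
    module_terms = terms, config = config
  ), class = "sim_truth")

  list(expr = expr_mat(2^log2e, "linear"), truth = truth)
}

#' Gene catalog derived from simulation ground truth
#'
#' Characterized module genes carry their module's term label; background
#' characterized genes carry a generic housekeeping label; uncharacterized
#' genes have no labels. The guide gene is flagged as a transcription
#' factor.
#'
#' @param truth a `sim_truth`.
#' @return A data.frame `gene_id, status, is_tf, labels` (semicolon-joined).
#' @export
make_catalog <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  genes <- names(truth$module_of)
  status <- ifelse(genes %in% truth$uncharacterized,
                   "uncharacterized", "characterized")
  labels <- ifelse(status == "uncharacterized", "",
                   ifelse(truth$module_of == "none", "cellular homeostasis",
                          unname(truth$module_terms[truth$module_of])))
  labels[is.na(labels)] <- ""
  data.frame(gene_id = genes, status = status,
             is_tf = genes %in% truth$guide_gene,
             labels = labels, row.names = NULL)
}

#' Simulate a cross-species reference co-function network
#'
#' Over the reference-species ids of the ortholog map, every within-module
#' ortholog pair is an eligible edge; hub-incident edges get higher base
#' weights (log-likelihood-like scores), a `keep_edge_frac` subset is
#' retained, and weights are jittered with Gaussian noise. Edges are
#' returned sorted by weight, descending.
#'
#' @param truth a `sim_truth` with at least one planted module.
#' @param keep_edge_frac fraction of eligible edges retained.
#' @param weight_noise_sd SD of the weight jitter.
#' @param seed integer seed.
#' @return A data.frame `gene1, gene2, weight` (reference-species ids).
#' @export
simulate_reference_network <- function(truth, keep_edge_frac = 0.8,
                                       weight_noise_sd = 0.1, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  check_fraction(keep_edge_frac, "keep_edge_frac")
  if (nrow(truth$ortholog_pairs) == 0) stop2("ortholog map is empty")
  if (!any(truth$module_of != "none")) stop2("truth has no planted module")
  set.seed(seed)
  orth <- setNames(truth$ortholog_pairs$ref_id, truth$ortholog_pairs$gene_id)
  out <- list()
  for (m in setdiff(unique(truth$module_of), "none")) {
    mg <- sort(intersect(names(orth), names(truth$module_of)[truth$module_of == m]))
    if (length(mg) < 2) next
    pr <- t(combn(mg, 2))
    is_hub <- matrix(pr %in% truth$hub_genes, ncol = 2)
    w <- 1 + 0.5 * rowSums(is_hub) + rnorm(nrow(pr), sd = weight_noise_sd)
    keep <- runif(nrow(pr)) <= keep_edge_frac
    if (any(keep)) {
      out[[m]] <- data.frame(gene1 = orth[pr[keep, 1]],
                             gene2 = orth[pr[keep, 2]],
                             weight = pmax(w[keep], 0.01), row.names = NULL)
    }
  }
  net <- if (length(out)) do.call(rbind, out) else
    data.frame(gene1 = character(0), gene2 = character(0), weight = numeric(0))
  net <- net[order(-net$weight), ]
  rownames(net) <- NULL
  net
}

#' Simulate promoter sequences with planted cis-elements
#'
#' One uniform-random sequence of exactly `length` nucleotides per gene.
#' Genes carrying a planted treatment effect receive embedded instances of
#' their module's motif (IUPAC consensus realized to concrete bases) at
#' recorded positions and strands; instance counts are Poisson with mean
#' `plant_rate`, floored at one. `plant_rate = 0` plants nothing.
#'
#' @param truth a `sim_truth`.
#' @param motif_lib named character vector of IUPAC consensi
#'   (default [builtin_motifs()]).
#' @param length promoter length in nt (default 1000).
#' @param plant_rate mean planted instances per designated gene.
#' @param seed integer seed.
#' @return List with `sequences` (named character vector) and `truth`
#'   (input truth with `planted_motifs` filled in).
#' @export
simulate_promoters <- function(truth, motif_lib = builtin_motifs(),
                               length = 1000, plant_rate = 2, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!length(motif_lib)) stop2("motif library is empty")
  validate_motifs(motif_lib)
  if (max(nchar(motif_lib)) > length) {
    stop2("a motif is longer than the promoter length")
  }
  set.seed(seed)
  genes <- names(truth$module_of)
  modules <- setdiff(unique(truth$module_of), "none")
  motif_of_module <- setNames(rep_len(names(motif_lib), length(modules)), modules)

  seqs <- vapply(genes, function(g) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1))

  planted <- list()
  designated <- intersect(unique(truth$effects$gene_id), genes)
  for (g in designated) {
    m <- truth$module_of[[g]]
    if (identical(m, "none") || plant_rate <= 0) next
    mname <- motif_of_module[[m]]
    consensus <- motif_lib[[mname]]
    k <- max(1L, rpois(1, plant_rate))
    L <- nchar(consensus)
    pos <- sort(sample.int(length - L + 1L, k))
    # nudge overlapping instances apart where room allows
    for (i in seq_along(pos)[-1]) {
      if (pos[i] < pos[i - 1] + L) pos[i] <- min(pos[i - 1] + L, length - L + 1L)
    }
    pos <- unique(pos)
    strand <- sample(c("+", "-"), length(pos), replace = TRUE)
    s <- seqs[[g]]
    for (i in seq_along(pos)) {
      inst <- realize_iupac(consensus)
      if (strand[i] == "-") inst <- revcomp(inst)
      substr(s, pos[i], pos[i] + L - 1L) <- inst
    }
    seqs[[g]] <- s
    planted[[g]] <- data.frame(gene_id = g, motif = mname,
                               position = pos, strand = strand)
  }
  truth$planted_motifs <- if (length(planted)) {
    pm <- do.call(rbind, planted); rownames(pm) <- NULL; pm
  } else {
    data.frame(gene_id = character(0), motif = character(0),
               position = integer(0), strand = character(0))
  }
  list(sequences = seqs, truth = truth)
}

#' Serialize / read simulation ground truth as structured text
#'
#' Sections are written as `[name]` headers followed by tab-separated rows;
#' the round trip preserves every planted element.
#'
#' @param truth a `sim_truth`.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  con <- file(path, "w"); on.exit(close(con))
  sec <- function(name, df) {
    writeLines(paste0("[", name, "]"), con)
    writeLines(paste(names(df), collapse = "\t"), con)
    if (nrow(df)) {
      writeLines(do.call(paste, c(lapply(df, as.character), sep = "\t")), con)
    }
  }
  sec("module_of", data.frame(gene_id = names(truth$module_of),
                              module = unname(truth$module_of)))
  sec("hub_genes", data.frame(gene_id = truth$hub_genes))
  sec("effects", truth$effects)
  sec("ubiquitous_up", data.frame(gene_id = truth$ubiquitous_up))
  sec("ubiquitous_down", data.frame(gene_id = truth$ubiquitous_down))
  sec("ortholog_pairs", truth$ortholog_pairs)
  sec("uncharacterized", data.frame(gene_id = truth$uncharacterized))
  sec("guide", data.frame(gene_id = truth$guide_gene))
  sec("guide_targets", data.frame(gene_id = truth$guide_targets))
  sec("planted_motifs", truth$planted_motifs)
  sec("module_terms", data.frame(module = names(truth$module_terms),
                                 term = unname(truth$module_terms)))
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  heads <- grep("^\\[", lines)
  sections <- list()
  for (i in seq_along(heads)) {
    name <- gsub("\\[|\\]", "", lines[heads[i]])
    end <- if (i < length(heads)) heads[i + 1] - 1L else length(lines)
    block <- lines[(heads[i] + 1L):end]
    cols <- strsplit(block[1], "\t")[[1]]
    rows <- block[-1]
    df <- if (length(rows)) {
      as.data.frame(do.call(rbind, strsplit(rows, "\t")),
                    stringsAsFactors = FALSE)
    } else {
      as.data.frame(matrix(character(0), 0, length(cols)))
    }
    names(df) <- cols
    sections[[name]] <- df
  }
  eff <- sections$effects
  eff$fold <- as.numeric(eff$fold)
  pm <- sections$planted_motifs
  pm$position <- as.integer(pm$position)
  structure(list(
    module_of = setNames(sections$module_of$module, sections$module_of$gene_id),
    hub_genes = sections$hub_genes$gene_id,
    effects = eff,
    ubiquitous_up = sections$ubiquitous_up$gene_id,
    ubiquitous_down = sections$ubiquitous_down$gene_id,
    ortholog_pairs = sections$ortholog_pairs,
    uncharacterized = sections$uncharacterized$gene_id,
    guide_gene = sections$guide$gene_id,
    guide_targets = sections$guide_targets$gene_id,
    planted_motifs = pm,
    module_terms = setNames(sections$module_terms$term,
                            sections$module_terms$module)
  ), class = "sim_truth")
}
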