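#' Soft-thresholded correlation adjacency
#'
#' Computes the genes x genes co-expression adjacency: unsigned,
#' `a_ij = |cor_ij|^beta`; signed, `a_ij = ((1 + cor_ij)/2)^beta`.
#' Correlations use pairwise-complete observations; pairs with fewer than
#' three complete observations get correlation 0 (with a warning), and
#' constant rows are dropped with a warning. The diagonal is set to zero by
#' convention so that row sums are connectivities.
#'
#' @param x log2-scale [expr_mat()] with >= 3 samples.
#' @param method `"pearson"` or `"spearman"`.
#' @param beta integer soft-threshold power >= 1 (the study default is 8).
#' @param signed use the signed transform (default `FALSE`, unsigned).
#' @return A symmetric adjacency matrix in \[0, 1\] with attributes
#'   `beta`, `method`, `signed`.
#' @export
correlation_adjacency <- function(x, method = c("pearson", "spearman"),
                                  beta = 8, signed = FALSE) {
  method <- match.arg(method)
  if (!is.numeric(beta) || beta < 1) stop2("`beta` must be >= 1")
  v <- unclass(x)
  if (ncol(v) < 3) stop2("need >= 3 samples")
  sds <- apply(v, 1, sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds))) {
    warning(sum(sds == 0 | is.na(sds)), " constant rows dropped")
    v <- v[sds > 0 & !is.na(sds), , drop = FALSE]
  }
  cc <- cor(t(v), method = method, use = "pairwise.complete.obs")
  if (anyNA(cc)) {
    warning("pairs with < 3 complete observations set to cor = 0")
    cc[is.na(cc)] <- 0
  }
  a <- if (signed) ((1 + cc) / 2)^beta else abs(cc)^beta
  diag(a) <- 0
  a <- (a + t(a)) / 2
  structure(a, beta = beta, method = method, signed = signed)
}

#' Scale-free topology fit across candidate soft-threshold powers
#'
#' For each power, connectivities `k_i` are computed from the unsigned (or
#' signed) adjacency, `log10(k)` is split into 10 equal-width bins, and
#' `log10(mean bin frequency)` is regressed on `log10(mean bin k)`. The
#' signed fit index is R^2, negated when the slope is positive. The chosen
#' power is the smallest one whose signed R^2 reaches `r2_cut`, otherwise
#' the power with the maximal signed R^2.
#'
#' @param x log2-scale [expr_mat()].
#' @param betas candidate powers (default 1..20).
#' @param r2_cut signed R^2 target (default 0.8).
#' @inheritParams correlation_adjacency
#' @param n_bins histogram bins for the degree distribution.
#' @return A list with `table` (per-power signed R^2, slope, mean / median /
#'   max connectivity) and `chosen_beta`.
#' @export
pick_soft_threshold <- function(x, betas = 1:20, r2_cut = 0.8,
                                method = "pearson", signed = FALSE,
                                n_bins = 10) {
  a1 <- correlation_adjacency(x, method = method, beta = 1, signed = signed)
  rows <- lapply(betas, function(b) {
    k <- rowSums(a1^b)
    if (all(k == 0)) stop2("all connectivities are zero")
    fit <- scale_free_fit(k, n_bins)
    data.frame(beta = b, r_squared = fit$r2, slope = fit$slope,
               mean_k = mean(k), median_k = median(k), max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  hit <- which(tab$r_squared >= r2_cut)
  chosen <- if (length(hit)) tab$beta[hit[1]] else tab$beta[which.max(tab$r_squared)]
  list(table = tab, chosen_beta = chosen)
}

# degree-distribution log-log regression; signed R^2 (negated for a
# positive slope, which contradicts scale-free decay)
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 2) return(list(r2 = 0, slope = 0))
  lk <- log10(k)
  br <- seq(min(lk), max(lk), length.out = n_bins + 1)
  bin <- cut(lk, br, include.lowest = TRUE)
  freq <- tapply(lk, bin, length)
  kmean <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 2) return(list(r2 = 0, slope = 0))
  fit <- lm(log10(freq[ok]) ~ log10(kmean[ok]))
  r2 <- summary(fit)$r.squared
  slope <- unname(coef(fit)[2])
  list(r2 = if (slope > 0) -r2 else r2, slope = slope)
}

#' Topological overlap transform
#'
#' The standard unsigned topological overlap measure:
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` and unit diagonal. High overlap means two genes
#' share most of their network neighborhood in addition to being directly
#' connected; `1 - TOM` is the clustering dissimilarity.
#'
#' @param adj symmetric adjacency in \[0, 1\] with zero diagonal.
#' @param tol symmetry tolerance.
#' @return Symmetric TOM matrix in \[0, 1\], diagonal 1.
#' @export
tom_transform <- function(adj, tol = 1e-10) {
  check_symmetric(adj, tol, "adjacency")
  if (any(adj < 0 | adj > 1)) stop2("adjacency values must lie in [0, 1]")
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a                       # zero diagonal kills the u = i, j terms
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  (tom + t(tom)) / 2
}

#' Mutual information matrix from equal-width binning
#'
#' Per gene pair, MI in nats from the 2-D histogram whose marginal bins are
#' equal-width over each gene's range:
#' `MI = sum p_xy * ln(p_xy / (p_x p_y))` over non-empty cells. The
#' diagonal holds each gene's marginal entropy.
#'
#' @param x an [expr_mat()] (log2 scale recommended).
#' @param bins marginal bin count (default 10).
#' @return Symmetric MI matrix (nats).
#' @export
mutual_information_matrix <- function(x, bins = 10) {
  if (bins < 2) stop2("`bins` must be >= 2")
  v <- unclass(x)
  n <- ncol(v)
  if (n < bins) warning("fewer samples than bins; MI estimates will be coarse")
  d <- t(apply(v, 1, discretize_ew, bins = bins))
  g <- nrow(v)
  mi <- matrix(0, g, g, dimnames = list(rownames(v), rownames(v)))
  marg <- lapply(seq_len(g), function(i) tabulate(d[i, ], bins) / n)
  for (i in seq_len(g)) {
    mi[i, i] <- entropy_nats(marg[[i]])
    if (i == g) break
    for (j in seq((i + 1), g)) {
      joint <- tabulate((d[i, ] - 1L) * bins + d[j, ], bins * bins) / n
      mi_ij <- mi_from_joint(matrix(joint, bins, bins, byrow = TRUE))
      mi[i, j] <- mi[j, i] <- mi_ij
    }
  }
  mi
}

discretize_ew <- function(z, bins) {
  r <- range(z)
  if (r[1] == r[2]) return(rep(1L, length(z)))
  b <- pmin(pmax(floor((z - r[1]) / (r[2] - r[1]) * bins) + 1L, 1L), bins)
  as.integer(b)
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

mi_from_joint <- function(pxy) {
  px <- rowSums(pxy); py <- colSums(pxy)
  nz <- pxy > 0
  sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
}

#' Context likelihood of relatedness scores
#'
#' Standardizes each MI value against both genes' background MI
#' distributions: `t_i(j) = (mi_ij - mean_i) / sd_i` over `j != i`, and
#' `z_ij = sqrt(max(0, t_i(j))^2 + max(0, t_j(i))^2)`. Pairs whose MI is
#' unremarkable for both genes score zero; adding a constant to every MI
#' entry leaves the scores unchanged.
#'
#' @param mi symmetric mutual-information (or MIC) matrix.
#' @return List with `mi`, the non-negative score matrix `z`, and per-gene
#'   background `mu` / `sigma`.
#' @export
clr_scores <- function(mi) {
  check_symmetric(mi, 1e-8, "MI matrix")
  g <- nrow(mi)
  if (g < 3) stop2("CLR background undefined for fewer than 3 genes")
  off <- mi
  diag(off) <- NA
  mu <- rowMeans(off, na.rm = TRUE)
  sigma <- apply(off, 1, sd, na.rm = TRUE)
  tm <- (off - mu) / ifelse(sigma == 0, Inf, sigma)   # rows standardized
  tm[is.na(tm)] <- 0
  tp <- pmax(tm, 0)
  z <- sqrt(tp^2 + t(tp)^2)
  diag(z) <- 0
  dimnames(z) <- dimnames(mi)
  list(mi = mi, z = z, mu = mu, sigma = sigma)
}

#' Approximate maximal information coefficient matrix
#'
#' Per pair, the maximum over admissible grid shapes
#' (`x_bins * y_bins <= max_grid`, both >= 2, equal-frequency axis
#' partitions only) of `MI(grid) / ln(min(x_bins, y_bins))`. Restricting
#' the search to equal-frequency partitions is a deliberate simplification
#' of the full dynamic-program grid optimization; outputs are labeled
#' approximate.
#'
#' @param x an [expr_mat()] with >= 8 samples.
#' @param max_grid cap on `x_bins * y_bins`; default `n^0.6`.
#' @return Symmetric matrix of approximate MIC values in \[0, 1\]
#'   (diagonal 1).
#' @export
mic_approx_matrix <- function(x, max_grid = NULL) {
  v <- unclass(x)
  n <- ncol(v)
  if (n < 8) stop2("need >= 8 samples for MIC")
  if (is.null(max_grid)) max_grid <- max(4, floor(n^0.6))
  if (max_grid < 4) stop2("`max_grid` must be >= 4")
  shapes <- admissible_grids(max_grid)
  # per-gene equal-frequency bin assignments for every bin count used
  bvals <- sort(unique(c(shapes)))
  binned <- lapply(bvals, function(b) t(apply(v, 1, discretize_ef, bins = b)))
  names(binned) <- as.character(bvals)
  g <- nrow(v)
  mic <- matrix(1, g, g, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(g)) {
    if (i == g) break
    for (j in seq((i + 1), g)) {
      best <- 0
      for (s in seq_len(nrow(shapes))) {
        bx <- shapes[s, 1]; by <- shapes[s, 2]
        di <- binned[[as.character(bx)]][i, ]
        dj <- binned[[as.character(by)]][j, ]
        joint <- tabulate((di - 1L) * by + dj, bx * by) / n
        val <- mi_from_joint(matrix(joint, bx, by, byrow = TRUE)) /
          log(min(bx, by))
        if (val > best) best <- val
      }
      mic[i, j] <- mic[j, i] <- min(best, 1)
    }
  }
  mic
}

admissible_grids <- function(max_grid) {
  out <- list()
  for (bx in 2:floor(max_grid / 2)) {
    for (by in 2:floor(max_grid / bx)) out[[length(out) + 1L]] <- c(bx, by)
  }
  do.call(rbind, out)
}

# equal-frequency discretization via ranks
discretize_ef <- function(z, bins) {
  r <- rank(z, ties.method = "first")
  as.integer(ceiling(r * bins / length(z)))
}

#' Threshold a symmetric score matrix into an edge list
#'
#' Keeps the top `quantile_frac` of off-diagonal pairs (default the top 1%
#' by score), or all pairs at or above an absolute `min_score` when given.
#'
#' @param m symmetric score matrix.
#' @param quantile_frac fraction of highest-scoring pairs to keep.
#' @param min_score absolute threshold overriding `quantile_frac`.
#' @return data.frame `gene1, gene2, weight`, sorted by weight descending.
#' @export
threshold_edges <- function(m, quantile_frac = 0.01, min_score = NULL) {
  check_symmetric(m, 1e-8)
  ut <- upper.tri(m)
  w <- m[ut]
  idx <- which(ut, arr.ind = TRUE)
  thr <- if (!is.null(min_score)) min_score else
    quantile(w, 1 - quantile_frac, names = FALSE)
  keep <- w >= thr & w > 0
  df <- data.frame(gene1 = rownames(m)[idx[keep, 1]],
                   gene2 = colnames(m)[idx[keep, 2]],
                   weight = w[keep])
  df <- df[order(-df$weight, df$gene1, df$gene2), ]
  rownames(df) <- NULL
  df
}

#' Read / write a symmetric gene matrix as TSV with id header row/column
#' @param m matrix with gene dimnames.
#' @param path file path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
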