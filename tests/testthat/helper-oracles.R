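# Independent oracle implementations used to cross-check the package.
# These deliberately use naive loops / closed forms, never the package's
# own code paths.

# O(n^3) topological overlap
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}

# element-wise CLR recomputation
clr_oracle <- function(mi) {
  n <- nrow(mi)
  z <- matrix(0, n, n, dimnames = dimnames(mi))
  mu <- numeric(n); sg <- numeric(n)
  for (i in seq_len(n)) {
    bg <- mi[i, -i]
    mu[i] <- mean(bg); sg[i] <- sd(bg)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ti <- if (sg[i] == 0) 0 else (mi[i, j] - mu[i]) / sg[i]
    tj <- if (sg[j] == 0) 0 else (mi[j, i] - mu[j]) / sg[j]
    z[i, j] <- sqrt(max(0, ti)^2 + max(0, tj)^2)
  }
  z
}

# naive per-pair histogram MI (nats), equal-width bins
mi_pair_oracle <- function(x, y, bins) {
  ew <- function(z) {
    r <- range(z)
    if (r[1] == r[2]) return(rep(1L, length(z)))
    pmin(pmax(floor((z - r[1]) / (r[2] - r[1]) * bins) + 1L, 1L), bins)
  }
  bx <- ew(x); by <- ew(y)
  n <- length(x)
  mi <- 0
  for (a in seq_len(bins)) for (b in seq_len(bins)) {
    pxy <- sum(bx == a & by == b) / n
    if (pxy > 0) {
      px <- sum(bx == a) / n; py <- sum(by == b) / n
      mi <- mi + pxy * log(pxy / (px * py))
    }
  }
  mi
}

# exhaustive restricted-grid MIC for one pair (equal-frequency partitions)
mic_pair_oracle <- function(x, y, max_grid) {
  ef <- function(z, b) as.integer(ceiling(rank(z, ties.method = "first") * b / length(z)))
  best <- 0
  for (bx in 2:floor(max_grid / 2)) for (by in 2:floor(max_grid / bx)) {
    dx <- ef(x, bx); dy <- ef(y, by)
    n <- length(x)
    mi <- 0
    for (a in seq_len(bx)) for (b in seq_len(by)) {
      pxy <- sum(dx == a & dy == b) / n
      if (pxy > 0) {
        mi <- mi + pxy * log(pxy / ((sum(dx == a) / n) * (sum(dy == b) / n)))
      }
    }
    best <- max(best, mi / log(min(bx, by)))
  }
  min(best, 1)
}

# regex-based IUPAC scan of one sequence, both strands
.iupac_class <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
                  S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
                  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
                  N = "[ACGTN]")
.comp_map <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
               W = "W", K = "M", M = "K", B = "V", D = "H", H = "D",
               V = "B", N = "N")
iupac_regex <- function(motif) {
  paste(.iupac_class[strsplit(toupper(motif), "")[[1]]], collapse = "")
}
regex_scan_oracle <- function(seqs, motifs) {
  out <- list()
  for (g in names(seqs)) for (mn in names(motifs)) {
    fwd <- gregexpr(paste0("(?=", iupac_regex(motifs[[mn]]), ")"),
                    seqs[[g]], perl = TRUE)[[1]]
    rcm <- paste(rev(.comp_map[strsplit(toupper(motifs[[mn]]), "")[[1]]]),
                 collapse = "")
    rev_ <- gregexpr(paste0("(?=", iupac_regex(rcm), ")"),
                     seqs[[g]], perl = TRUE)[[1]]
    add <- function(pos, st) {
      pos <- pos[pos > 0]
      if (length(pos)) data.frame(gene = g, motif = mn, position = as.integer(pos),
                                  strand = st)
    }
    out[[length(out) + 1L]] <- add(fwd, "+")
    out[[length(out) + 1L]] <- add(rev_, "-")
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(gene = character(0), motif = character(0),
                      position = integer(0), strand = character(0)))
  }
  res <- res[order(res$gene, res$motif, res$position, res$strand), ]
  rownames(res) <- NULL
  res
}

# adjusted Rand index via an independent package
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# small deterministic log2-scale expression fixture
toy_expr <- function(genes = 4, samples = 6, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(genes * samples, 8), genes, samples,
              dimnames = list(sprintf("g%02d", seq_len(genes)),
                              sprintf("s%02d", seq_len(samples))))
  expr_mat(m, "log2")
}

# symmetric random adjacency in [0,1], zero diagonal
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  dimnames(a) <- list(sprintf("g%02d", seq_len(n)), sprintf("g%02d", seq_len(n)))
  a
}
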