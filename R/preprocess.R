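#' Rank-invariant normalization against a baseline array
#'
#' Each non-baseline array is rescaled through a monotone piecewise-linear
#' mapping fitted through its rank-invariant probe set: starting from all
#' probes, probes whose rank within the current set differs between array
#' and baseline by less than `rank_tol` times the set size are kept, and
#' the selection is iterated to a fixed point (at most `max_iter` rounds).
#' The mapping interpolates array intensity -> baseline intensity through
#' the invariant points on the log2 scale (trimmed of points more than
#' 3 MAD off the consensus log-ratio, then made monotone by isotonic
#' regression) with linear tail extrapolation. The baseline array is
#' returned unchanged.
#'
#' @param x linear-scale [expr_mat()] with >= 2 columns.
#' @param baseline baseline column name or index; default is the array
#'   whose total intensity is the median across arrays.
#' @param rank_tol rank-difference threshold as a proportion of the
#'   invariant-set size (default 0.05).
#' @param max_iter fixed-point iteration cap.
#' @param min_invariant below this many invariant probes the array falls
#'   back to median scaling, with a warning.
#' @return The normalized linear-scale matrix.
#' @export
rank_invariant_normalize <- function(x, baseline = NULL, rank_tol = 0.05,
                                     max_iter = 20, min_invariant = 10) {
  if (expr_scale(x) != "linear") stop2("normalization expects linear intensities")
  if (ncol(x) < 2) stop2("need >= 2 arrays")
  v <- unclass(x)
  if (is.null(baseline)) {
    tot <- colSums(v)
    baseline <- colnames(v)[order(tot)[ceiling(ncol(v) / 2)]]
  }
  if (is.numeric(baseline)) baseline <- colnames(v)[baseline]
  if (!baseline %in% colnames(v)) stop2("baseline column not found")
  ref <- v[, baseline]
  out <- v
  for (j in colnames(v)) {
    if (j == baseline) next
    inv <- invariant_set(v[, j], ref, rank_tol, max_iter)
    if (length(inv) < min_invariant) {
      warning(sprintf(
        "array %s: only %d invariant probes; falling back to median scaling",
        j, length(inv)))
      out[, j] <- v[, j] * stats::median(ref) / stats::median(v[, j])
      next
    }
    out[, j] <- monotone_map(v[, j], v[inv, j], ref[inv])
  }
  expr_mat(out, "linear")
}

# iterate the rank-invariant probe selection to a fixed point
invariant_set <- function(a, b, rank_tol, max_iter) {
  keep <- seq_along(a)
  for (it in seq_len(max_iter)) {
    ra <- rank(a[keep], ties.method = "average")
    rb <- rank(b[keep], ties.method = "average")
    new <- keep[abs(ra - rb) < rank_tol * length(keep)]
    if (length(new) == length(keep)) return(new)
    if (length(new) == 0) return(new)
    keep <- new
  }
  keep
}

# monotone piecewise-linear map fitted through the invariant points on
# the log2 scale. Points whose log-ratio deviates from the consensus by
# more than 3 MAD are trimmed first: a gene can be rank-consistent yet
# sit far off the technical-bias curve (e.g. a strongly induced gene that
# is top-ranked in both arrays), and such points must not bend the map.
# Tails extrapolate with the slope of the outer 2% (>= 5) of points,
# falling back to slope 1 in log space (pure scaling).
monotone_map <- function(x, xs, ys) {
  eps <- min(c(xs[xs > 0], ys[ys > 0], 1)) / 2
  lx <- log2(pmax(xs, eps)); ly <- log2(pmax(ys, eps))
  r <- ly - lx
  dev <- abs(r - median(r))
  keep <- dev <= 3 * stats::mad(r) + 1e-8
  lx <- lx[keep]; ly <- ly[keep]
  o <- order(lx)
  lx <- lx[o]; ly <- ly[o]
  ag <- vapply(split(ly, lx), mean, numeric(1))
  lx <- as.numeric(names(ag)); ly <- unname(ag)
  if (length(lx) == 1) return(x * 2^(ly - lx))
  ly <- stats::isoreg(lx, ly)$yf
  z <- log2(pmax(x, eps))
  y <- stats::approx(lx, ly, xout = z, rule = 2)$y
  n <- length(lx)
  k <- min(n, max(5L, ceiling(0.02 * n)))
  tail_slope <- function(ix) {
    if (length(unique(lx[ix])) < 2) return(1)
    sl <- unname(coef(lm(ly[ix] ~ lx[ix]))[2])
    if (!is.finite(sl) || sl <= 0) 1 else sl
  }
  lo <- z < lx[1]; hi <- z > lx[n]
  y[lo] <- ly[1] + tail_slope(seq_len(k)) * (z[lo] - lx[1])
  y[hi] <- ly[n] + tail_slope(seq(n - k + 1L, n)) * (z[hi] - lx[n])
  out <- 2^y
  out[x == 0] <- 0
  out
}

#' Filter low or absent probes
#'
#' Keeps probes with intensity above `min_intensity` in at least
#' `frac_expressed` of the samples and, additionally, called present in at
#' least `frac_present` of the samples. Presence comes from the optional
#' `present_calls` matrix (`P`/`M`/`A` or 1/0); when it is absent the
#' surrogate presence criterion is intensity above `min_intensity` in at
#' least `frac_present` of the samples.
#'
#' @param x linear-scale [expr_mat()].
#' @param min_intensity intensity floor (default 20).
#' @param frac_expressed required fraction of samples above the floor.
#' @param present_calls optional probe x sample presence matrix.
#' @param frac_present required fraction of present calls.
#' @return The filtered matrix.
#' @export
filter_probes <- function(x, min_intensity = 20, frac_expressed = 0.5,
                          present_calls = NULL, frac_present = 0.2) {
  check_fraction(frac_expressed, "frac_expressed")
  check_fraction(frac_present, "frac_present")
  if (min_intensity < 0) stop2("`min_intensity` must be >= 0")
  v <- unclass(x)
  expressed <- rowMeans(v > min_intensity) >= frac_expressed
  if (is.null(present_calls)) {
    present <- rowMeans(v > min_intensity) >= frac_present
  } else {
    pc <- present_calls[rownames(v), colnames(v), drop = FALSE]
    pv <- if (is.character(pc)) pc == "P" else pc == 1
    present <- rowMeans(pv) >= frac_present
  }
  keep <- expressed & present
  if (!any(keep)) {
    stop2(sprintf("all %d probes removed by filtering (floor %g)",
                  nrow(v), min_intensity))
  }
  expr_mat(v[keep, , drop = FALSE], expr_scale(x))
}

#' Maximum per-probe fold change across all (tissue, stage) contrasts
#'
#' For the probe-collapse rule: per probe, the maximum over contrasts of
#' `max(FC, 1/FC)` where FC is the stress/control ratio of linear means.
#'
#' @param x an [expr_mat()] (any scale; linear view is used).
#' @param design a [sim_design()]-shaped data.frame.
#' @return Named numeric vector of max fold changes.
#' @export
probe_max_fold <- function(x, design) {
  design <- validate_design(design)
  v <- expr_linear_values(x)
  cells <- unique(design[, c("tissue", "stage")])
  best <- rep(1, nrow(v)); names(best) <- rownames(v)
  for (i in seq_len(nrow(cells))) {
    in_cell <- design$tissue == cells$tissue[i] & design$stage == cells$stage[i]
    s <- design$sample_id[in_cell & design$treatment == "stress"]
    ctl <- design$sample_id[in_cell & design$treatment == "control"]
    if (length(s) < 1 || length(ctl) < 1) next
    fc <- rowMeans(v[, s, drop = FALSE]) / pmax(rowMeans(v[, ctl, drop = FALSE]), .Machine$double.eps)
    best <- pmax(best, fc, 1 / pmax(fc, .Machine$double.eps))
  }
  best
}

#' Collapse probes to unique genes
#'
#' Probes without a mapping, and probes mapping to more than one gene, are
#' dropped. For genes measured by several probes the probe with the highest
#' max-across-contrasts fold change wins; ties go to the lexicographically
#' smallest probe id. Output rows are gene ids.
#'
#' @param x an [expr_mat()] with probe row ids.
#' @param probe_map data.frame `probe_id, gene_id` (many-to-one allowed;
#'   a probe listed with two genes is discarded).
#' @param max_fold named per-probe fold-change vector from
#'   [probe_max_fold()].
#' @return Gene-level matrix.
#' @export
collapse_probes <- function(x, probe_map, max_fold) {
  if (is.null(probe_map) || nrow(probe_map) == 0) stop2("probe map is empty")
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_map)))
  if (any(!nzchar(probe_map$gene_id))) stop2("probe map contains empty gene ids")
  multi <- unique(probe_map$probe_id[duplicated(probe_map$probe_id)])
  pm <- probe_map[!probe_map$probe_id %in% multi, ]
  pm <- pm[pm$probe_id %in% rownames(x), ]
  if (nrow(pm) == 0) stop2("no mapped probes present in the matrix")
  fc <- max_fold[pm$probe_id]
  # order so the winning probe (highest FC, then smallest id) comes first
  pm <- pm[order(pm$gene_id, -fc, pm$probe_id), ]
  win <- pm[!duplicated(pm$gene_id), ]
  out <- unclass(x)[win$probe_id, , drop = FALSE]
  rownames(out) <- win$gene_id
  expr_mat(out[order(rownames(out)), , drop = FALSE], expr_scale(x))
}

#' Read a two-column probe map TSV (`probe_id`, `gene_id`)
#' @param path file path.
#' @export
read_probe_map <- function(path) {
  pm <- read_tsv(path)
  names(pm)[1:2] <- c("probe_id", "gene_id")
  pm
}
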