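#' Call differentially expressed genes per (tissue, stage) contrast
#'
#' Per gene and (tissue, stage) cell, the fold change is the ratio of
#' linear-scale means, stress over control, and the p-value comes from a
#' Welch two-sample t-test on the log2 values. A gene is `up` when
#' `fold_change >= fc_threshold` and `p <= p_threshold`, `down` when
#' `fold_change <= 1/fc_threshold` and `p <= p_threshold`, otherwise
#' `none`. Contrasts with fewer than two replicates in either arm are
#' skipped with a warning. With degenerate (zero-variance) arms the
#' p-value is 0 when the means differ and 1 otherwise.
#'
#' @param x an [expr_mat()]; the linear view is used for fold changes and
#'   the log2 view for testing.
#' @param design a [sim_design()]-shaped data.frame.
#' @param fc_threshold linear fold-change cutoff (study default 4).
#' @param p_threshold p-value cutoff (default 0.05). No multiple-testing
#'   correction is applied by default, matching raw-p usage; set
#'   `adjust = "BH"` for Benjamini-Hochberg within each contrast.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame `gene_id, tissue, stage, fold_change, log2fc,
#'   p_value, direction`.
#' @export
call_degs <- function(x, design, fc_threshold = 4, p_threshold = 0.05,
                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  design <- validate_design(design)
  if (fc_threshold < 1) stop2("`fc_threshold` must be >= 1")
  lin <- expr_linear_values(x)
  lg <- if (expr_scale(x) == "log2") unclass(x) else log2(pmax(lin, .Machine$double.eps))
  cells <- unique(design[, c("tissue", "stage")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    in_cell <- design$tissue == cells$tissue[i] & design$stage == cells$stage[i]
    s <- design$sample_id[in_cell & design$treatment == "stress"]
    ctl <- design$sample_id[in_cell & design$treatment == "control"]
    if (length(s) < 2 || length(ctl) < 2) {
      warning(sprintf("contrast %s/%s skipped: < 2 replicates in an arm",
                      cells$tissue[i], cells$stage[i]))
      next
    }
    fc <- rowMeans(lin[, s, drop = FALSE]) /
      pmax(rowMeans(lin[, ctl, drop = FALSE]), .Machine$double.eps)
    p <- apply(lg, 1, function(row) welch_p(row[s], row[ctl]))
    if (adjust == "BH") p <- p.adjust(p, "BH")
    dir <- ifelse(fc >= fc_threshold & p <= p_threshold, "up",
                  ifelse(fc <= 1 / fc_threshold & p <= p_threshold, "down",
                         "none"))
    out[[i]] <- data.frame(gene_id = rownames(lin),
                           tissue = cells$tissue[i], stage = cells$stage[i],
                           fold_change = unname(fc), log2fc = unname(log2(fc)),
                           p_value = unname(p), direction = unname(dir),
                           row.names = NULL)
  }
  if (!length(out)) stop2("no testable contrasts in the design")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

welch_p <- function(a, b) {
  if (sd(a) == 0 && sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  tryCatch(t.test(a, b)$p.value,
           error = function(e) if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
}

#' Genes differential in every listed contrast
#'
#' The ubiquitous responders: `up_all` holds genes called `up` in every
#' contrast of `contrasts`, `down_all` analogously; the two sets are
#' disjoint by construction.
#'
#' @param table a [call_degs()] table.
#' @param contrasts data.frame with columns `tissue, stage`; default all
#'   contrasts present in `table`.
#' @return List with character vectors `up_all` and `down_all`.
#' @export
ubiquitous_degs <- function(table, contrasts = NULL) {
  if (is.null(contrasts)) contrasts <- unique(table[, c("tissue", "stage")])
  if (nrow(contrasts) == 0) stop2("empty contrast list")
  key <- paste(table$tissue, table$stage)
  want <- paste(contrasts$tissue, contrasts$stage)
  if (!all(want %in% key)) stop2("contrasts not all present in the DEG table")
  tab <- table[key %in% want, ]
  all_dir <- function(d) {
    hits <- tapply(tab$direction == d, tab$gene_id, sum)
    sort(names(hits)[hits == length(want)])
  }
  list(up_all = all_dir("up"), down_all = all_dir("down"))
}

#' Percentage of differential genes per module and contrast
#'
#' The module characterization underlying drought-responsive module
#' selection: for each (module, contrast), the percentages of module genes
#' called up and down. The `"grey"` pseudo-module is included and flagged.
#'
#' @param partition a `module_partition`.
#' @param table a [call_degs()] table.
#' @return data.frame `module, tissue, stage, size, percent_up,
#'   percent_down, is_unassigned`.
#' @export
module_deg_profile <- function(partition, table) {
  common <- intersect(names(partition), unique(table$gene_id))
  if (length(common) < length(partition)) {
    warning("partition and DEG table gene universes differ; using overlap")
  }
  part <- partition[common]
  tab <- table[table$gene_id %in% common, ]
  cells <- unique(tab[, c("tissue", "stage")])
  out <- list()
  for (m in unique(part)) {
    mg <- names(part)[part == m]
    if (!length(mg)) next
    for (i in seq_len(nrow(cells))) {
      sub <- tab[tab$gene_id %in% mg & tab$tissue == cells$tissue[i] &
                   tab$stage == cells$stage[i], ]
      out[[length(out) + 1L]] <- data.frame(
        module = m, tissue = cells$tissue[i], stage = cells$stage[i],
        size = length(mg),
        percent_up = 100 * sum(sub$direction == "up") / length(mg),
        percent_down = 100 * sum(sub$direction == "down") / length(mg),
        is_unassigned = m == GREY_LABEL)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
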