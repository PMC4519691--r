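#' Expression matrix container
#'
#' A thin wrapper around a numeric genes x samples matrix that carries an
#' explicit scale flag (`"linear"` intensities or `"log2"`), so that the
#' log-transform is applied exactly once along the pipeline.
#'
#' @param values numeric matrix, rows = genes (or probes), columns = samples.
#'   Must have row and column names.
#' @param scale `"linear"` or `"log2"`. Linear values must be non-negative.
#' @return A numeric matrix of class `expr_mat` with attribute `expr_scale`.
#' @examples
#' m <- matrix(2^rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' x <- expr_mat(m, "linear")
#' expr_scale(x)
#' @export
expr_mat <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop2("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop2("expression matrix needs row (gene) and column (sample) names")
  }
  if (anyDuplicated(rownames(values))) stop2("duplicate row ids")
  if (scale == "linear" && any(values < 0, na.rm = TRUE)) {
    stop2("linear-scale intensities must be non-negative")
  }
  structure(values, expr_scale = scale, class = c("expr_mat", class(values)))
}

#' @rdname expr_mat
#' @param x an `expr_mat`.
#' @export
expr_scale <- function(x) attr(x, "expr_scale") %||% "linear"

#' Log2-transform an expression matrix (once)
#'
#' @param x an `expr_mat` on linear scale.
#' @param offset pseudo-count added before the log to guard zeros.
#' @return The matrix on log2 scale; applying [expr_log2()] to an already
#'   log2 matrix is an error, so the transform cannot silently stack.
#' @export
expr_log2 <- function(x, offset = 1) {
  if (expr_scale(x) != "linear") stop2("matrix is already on log2 scale")
  expr_mat(log2(unclass(x) + offset), "log2")
}

#' @rdname expr_log2
#' @export
expr_unlog <- function(x, offset = 1) {
  if (expr_scale(x) != "log2") stop2("matrix is not on log2 scale")
  expr_mat(pmax(2^unclass(x) - offset, 0), "linear")
}

# linear-scale view regardless of stored scale (no offset games for log2
# data generated directly on that scale: offset = 0 used by callers that
# know the matrix was never offset)
expr_linear_values <- function(x, offset = 1) {
  if (expr_scale(x) == "linear") unclass(x) else pmax(2^unclass(x) - offset, 0)
}

#' Read / write expression matrices as TSV
#'
#' The layout is one header row of sample ids, first column `gene_id`,
#' remaining columns numeric.
#'
#' @param x an `expr_mat`.
#' @param path file path.
#' @param scale scale flag to attach when reading.
#' @return `write_expr_tsv` returns the path; `read_expr_tsv` an `expr_mat`.
#' @export
write_expr_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), unclass(x), check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_expr_tsv
#' @export
read_expr_tsv <- function(path, scale = c("linear", "log2")) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expr_mat(m, match.arg(scale))
}

#' Read / write a sample design table
#'
#' Columns: `sample_id`, `tissue`, `stage`, `treatment` (control/stress),
#' `replicate`.
#'
#' @param design a design data.frame.
#' @param path file path.
#' @export
write_design_tsv <- function(design, path) write_tsv(design, path)

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  d <- read_tsv(path)
  validate_design(d)
}

validate_design <- function(design) {
  need <- c("sample_id", "tissue", "stage", "treatment", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop2("design is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id)) stop2("duplicate sample ids in design")
  if (!all(design$treatment %in% c("control", "stress"))) {
    stop2("treatment must be 'control' or 'stress'")
  }
  design
}
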