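`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Derive a per-stage random seed from one root seed
#'
#' All stochastic stages of the pipeline draw their seed from a single root
#' seed combined with the stage name, so that adding or reordering stages
#' does not shift the random stream of the others.
#'
#' @param seed integer root seed.
#' @param stage character stage name.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) + 1000003 * h) %% .Machine$integer.max)
}

check_fraction <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x < 0 || x > 1 ||
      (!allow_zero && x == 0) || (!allow_one && x == 1)) {
    stop2(sprintf("`%s` must be a fraction in [%s, %s]", name,
                  if (allow_zero) "0" else "(0", if (allow_one) "1]" else "1)"))
  }
  invisible(x)
}

check_symmetric <- function(m, tol = 1e-12, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop2(what, " must be a square matrix")
  }
  if (max(abs(m - t(m))) > tol) {
    stop2(what, " is not symmetric within tolerance ", format(tol))
  }
  invisible(m)
}

# write a data.frame as tab-separated text, no quoting, no row names
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE, ...)
}
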