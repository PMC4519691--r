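# IUPAC degenerate alphabet as base bitmasks (A=1, C=2, G=4, T=8)
.iupac_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L, R = 5L, Y = 10L, S = 6L,
                 W = 9L, K = 12L, M = 3L, B = 14L, D = 13L, H = 11L,
                 V = 7L, N = 15L)
.base_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 0L)
.iupac_comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
                 H = "D", V = "B", N = "N")

#' Built-in cis-element consensus library
#'
#' A small set of published plant promoter elements by name: the
#' ABA-responsive element core (ABRE), the MYB recognition core, the
#' W-box bound by WRKY factors, and the CACT tetranucleotide. These are
#' data, not method: supply your own library for real analyses.
#'
#' @return Named character vector of IUPAC consensi.
#' @export
builtin_motifs <- function() {
  c(ABRELATERD1 = "ACGTG", `MYB-core` = "CNGTTR",
    `WRKY71-box` = "TGAC", CACTFTPPCA1 = "YACT")
}

validate_motifs <- function(motifs) {
  if (!length(motifs) || is.null(names(motifs)) || any(!nzchar(motifs))) {
    stop2("motifs must be a non-empty named character vector")
  }
  for (nm in names(motifs)) {
    ch <- strsplit(toupper(motifs[[nm]]), "")[[1]]
    bad <- which(!ch %in% names(.iupac_bits))
    if (length(bad)) {
      stop2(sprintf("motif %s: invalid IUPAC letter '%s' at position %d",
                    nm, ch[bad[1]], bad[1]))
    }
  }
  invisible(motifs)
}

#' Reverse complement of an IUPAC string
#' @param s a DNA / IUPAC string.
#' @export
revcomp <- function(s) {
  ch <- rev(strsplit(toupper(s), "")[[1]])
  paste(.iupac_comp[ch], collapse = "")
}

# realize a degenerate consensus into one concrete instance
realize_iupac <- function(consensus) {
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(toupper(consensus), "")[[1]]
  paste(vapply(ch, function(c1) {
    allowed <- bases[bitwAnd(.iupac_bits[[c1]], .base_bits[bases]) > 0]
    if (length(allowed) == 1) allowed else sample(allowed, 1)
  }, character(1)), collapse = "")
}

#' Scan promoter sequences for IUPAC consensus motifs
#'
#' Reports every (possibly overlapping) window matching each motif, on
#' both strands by default. Matching is by bitwise intersection of IUPAC
#' base sets, so `R` matches `A` or `G`; an `N` in the *sequence* matches
#' nothing unless the motif position is itself `N`. Reverse-strand hits
#' are found by matching the motif's reverse complement on the forward
#' sequence; their position is the leftmost forward coordinate and the
#' strand is `-`.
#'
#' @param promoters named character vector of sequences over
#'   \{A, C, G, T, N\} (e.g. from [read_fasta()]).
#' @param motifs named character vector of IUPAC consensi.
#' @param both_strands scan the reverse strand too (default `TRUE`).
#' @param collapse_palindromes drop the `-` hit when a palindromic motif
#'   hits the same window on both strands (default `FALSE`).
#' @return data.frame `gene, motif, position, strand` (1-based positions).
#' @export
iupac_scan <- function(promoters, motifs, both_strands = TRUE,
                       collapse_palindromes = FALSE) {
  validate_motifs(motifs)
  if (is.null(names(promoters))) stop2("promoter sequences must be named")
  out <- list()
  for (g in names(promoters)) {
    seq_bits <- seq_to_bits(promoters[[g]])
    for (mn in names(motifs)) {
      pats <- list(`+` = motifs[[mn]])
      if (both_strands) pats[["-"]] <- revcomp(motifs[[mn]])
      hits <- list()
      for (st in names(pats)) {
        pos <- bit_match(seq_bits, pats[[st]])
        if (length(pos)) {
          hits[[st]] <- data.frame(gene = g, motif = mn, position = pos,
                                   strand = st)
        }
      }
      h <- do.call(rbind, hits)
      if (!is.null(h) && collapse_palindromes) {
        h <- h[!(duplicated(h$position) & h$strand == "-"), ]
      }
      out[[length(out) + 1L]] <- h
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene = character(0), motif = character(0),
                      position = integer(0), strand = character(0))
  }
  res <- res[order(res$gene, res$motif, res$position, res$strand), ]
  rownames(res) <- NULL
  res
}

seq_to_bits <- function(s) {
  ch <- strsplit(toupper(s), "")[[1]]
  bad <- which(!ch %in% names(.base_bits))
  if (length(bad)) {
    stop2(sprintf("invalid sequence letter '%s' at position %d",
                  ch[bad[1]], bad[1]))
  }
  unname(.base_bits[ch])
}

# positions where every motif letter's base set intersects the sequence
# base; a sequence N (bits 0) only matches a motif N (treated specially)
bit_match <- function(seq_bits, pattern) {
  ch <- strsplit(toupper(pattern), "")[[1]]
  pb <- unname(.iupac_bits[ch])
  L <- length(pb)
  n <- length(seq_bits)
  if (n < L) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  for (k in seq_len(L)) {
    sb <- seq_bits[k:(n - L + k)]
    hit <- bitwAnd(sb, pb[k]) > 0
    if (ch[k] == "N") hit <- hit | sb == 0L   # motif N also covers sequence N
    ok <- ok & hit
  }
  which(ok)
}

#' Motif enrichment in a gene set by presence / absence
#'
#' Per motif, a 2x2 table of genes with at least one hit versus none,
#' in-set versus background, tested by the one-sided hypergeometric
#' (enrichment); q-values are Benjamini-Hochberg across motifs.
#'
#' @param occ occurrence table from [iupac_scan()].
#' @param geneset genes of interest (subset of `background`).
#' @param background background gene universe.
#' @return data.frame `motif, x, n, K, N, odds_ratio, p, q` sorted by p.
#' @export
motif_enrichment <- function(occ, geneset, background) {
  if (!length(geneset)) stop2("`geneset` is empty")
  if (!all(geneset %in% background)) stop2("`geneset` must be within `background`")
  motifs <- sort(unique(occ$motif))
  n <- length(geneset); N <- length(background)
  rows <- lapply(motifs, function(mn) {
    carriers <- unique(occ$gene[occ$motif == mn])
    K <- sum(background %in% carriers)
    x <- sum(geneset %in% carriers)
    or <- (x * (N - K - n + x)) / max((K - x) * (n - x), .Machine$double.eps)
    data.frame(motif = mn, x = x, n = n, K = K, N = N,
               odds_ratio = or,
               p = phyper(x - 1, K, N - K, n, lower.tail = FALSE))
  })
  res <- do.call(rbind, rows)
  res$q <- p.adjust(res$p, "BH")
  res <- res[order(res$p, res$motif), ]
  rownames(res) <- NULL
  res
}

#' Fill the candidate report's promoter-motif column
#'
#' @param report a `transfer_report`.
#' @param occ occurrence table from [iupac_scan()].
#' @param motifs_of_interest motif names to report.
#' @param candidates optional extra candidate ids (for untransferable
#'   genes already listed in the report).
#' @return The report with a `motifs` string (semicolon-joined) per
#'   candidate; candidates without a scanned promoter are flagged with an
#'   empty column.
#' @export
annotate_candidates_with_motifs <- function(report, occ,
                                            motifs_of_interest = NULL) {
  stopifnot(inherits(report, "transfer_report"))
  if (is.null(motifs_of_interest)) motifs_of_interest <- unique(occ$motif)
  for (g in names(report$per_candidate)) {
    if (!g %in% occ$gene) {
      report$per_candidate[[g]]$motifs <- ""
      report$per_candidate[[g]]$promoter_missing <- TRUE
      next
    }
    hit <- sort(unique(occ$motif[occ$gene == g &
                                   occ$motif %in% motifs_of_interest]))
    report$per_candidate[[g]]$motifs <- paste(hit, collapse = ";")
  }
  report
}

#' Read / write promoter FASTA
#'
#' Thin wrappers over Biostrings; record ids are gene ids.
#'
#' @param sequences named character vector.
#' @param path file path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read a motif TSV (`name`, `iupac_consensus`, optional `source`)
#' @param path file path.
#' @export
read_motif_tsv <- function(path) {
  df <- read_tsv(path)
  m <- setNames(toupper(df[[2]]), df[[1]])
  validate_motifs(m)
  m
}
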