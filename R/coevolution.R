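# Perturbation-based co-evolution statistic between alignment columns.
#
# For an A-column i and B-column j the score sums, over the 20 residue
# conditions a observed at i, the Kullback-Leibler shift that conditioning
# on {column i = a} induces in the column-j symbol distribution:
#
#   CMI(i, j) = sum_a w(a) * sum_b p(b | j, rows with i = a)
#                          * log[ p(b | j, rows with i = a) / p(b | j, all) ]
#
# With w(a) = f_i(a) (the "weighted" mode, default) and no gaps at column i
# this collapses to the mutual information of the smoothed joint symbol
# table, which gives an exact independent oracle. Each term is a KL
# divergence, so every entry is non-negative in either mode.

.tab21 <- function(v) tabulate(v + 1L, 21L)

#' Smoothed symbol frequencies of one alignment column
#'
#' Counts the 21 symbols (gap + 20 residues) at `col`, optionally over a
#' row subset, adds `pseudocount` to every symbol and renormalizes.
#'
#' @param enc an `encoded_alignment`.
#' @param col column index.
#' @param subset row indices, or `NULL` for all rows.
#' @param pseudocount added to each of the 21 symbol counts (default 1/21).
#' @return Numeric vector of length 21 summing to 1, named by symbol.
#' @export
column_frequencies <- function(enc, col, subset = NULL, pseudocount = 1 / 21) {
  stopifnot(inherits(enc, "encoded_alignment"))
  m <- unclass(enc)
  if (!is_count(col) || col > ncol(m))
    stop_ppiface("column %s out of range 1..%d", format(col), ncol(m))
  v <- if (is.null(subset)) m[, col] else m[subset, col]
  if (length(v) == 0L) stop_ppiface("empty row subset")
  counts <- .tab21(v) + pseudocount
  f <- counts / sum(counts)
  names(f) <- names(sort(aa_code_table()))
  f
}

#' Co-evolution matrix between protein-A and protein-B columns
#'
#' Computes the perturbation score above for every pair of an A-column
#' (`1..boundary`) and a B-column (`boundary+1..width`). Gap is never used
#' as a condition but is counted as a 21st outcome symbol. Conditions whose
#' row subset is empty contribute nothing. The matrix is M x N and not
#' symmetric by construction.
#'
#' @param enc an `encoded_alignment` with at least 2 rows.
#' @param boundary number of protein-A columns; defaults to the `boundary`
#'   attribute for concatenated alignments.
#' @param weighting `"weighted"` (condition weight = conditioning-residue
#'   frequency; equals smoothed mutual information, default) or
#'   `"unweighted"` (plain sum over conditions).
#' @param pseudocount per-symbol Laplace pseudocount (default 1/21).
#' @param base logarithm base (default natural log).
#' @return A `coevolution_matrix`: numeric matrix with attributes `mode`
#'   (`"inter"`), `weighting`, `pseudocount`, `base`.
#' @export
cmi_matrix <- function(enc, boundary = attr(enc, "boundary"),
                       weighting = c("weighted", "unweighted"),
                       pseudocount = 1 / 21, base = exp(1)) {
  stopifnot(inherits(enc, "encoded_alignment"))
  weighting <- match.arg(weighting)
  m <- unclass(enc)
  n <- nrow(m)
  if (n < 2L) stop_ppiface("need at least 2 sequences, got %d", n)
  if (is.null(boundary) || !is_count(boundary) || boundary >= ncol(m))
    stop_ppiface("boundary must split columns into two non-empty blocks")
  lenA <- as.integer(boundary)
  encB <- m[, (lenA + 1L):ncol(m), drop = FALSE]
  N <- ncol(encB)
  bg <- vapply(seq_len(N), function(j) .tab21(encB[, j]), integer(21))
  q <- (bg + pseudocount) / (n + 21 * pseudocount)        # 21 x N background
  res <- matrix(0, lenA, N)
  allgapA <- logical(lenA)
  for (ci in seq_len(lenA)) {
    colv <- m[, ci]
    counts <- .tab21(colv)
    if (sum(counts[-1L]) == 0L) { allgapA[ci] <- TRUE; next }
    for (a in which(counts[-1L] > 0L)) {
      rows <- which(colv == a)
      na <- length(rows)
      sub <- encB[rows, , drop = FALSE]
      cond <- vapply(seq_len(N), function(j) .tab21(sub[, j]), integer(21))
      p <- (cond + pseudocount) / (na + 21 * pseudocount)
      term <- p * log(p / q)
      term[p == 0] <- 0                                    # 0 log 0 = 0
      w <- if (weighting == "weighted") na / n else 1
      res[ci, ] <- res[ci, ] + w * colSums(term)
    }
  }
  if (base != exp(1)) res <- res / log(base)
  if (any(allgapA)) {
    warning(sprintf("all-gap A column(s) %s: scores set to 0",
                    paste(which(allgapA), collapse = ",")), call. = FALSE)
  }
  allgapB <- colSums(bg[-1L, , drop = FALSE]) == 0L
  if (any(allgapB)) {
    res[, allgapB] <- 0
    warning(sprintf("all-gap B column(s) %s: scores set to 0",
                    paste(which(allgapB), collapse = ",")), call. = FALSE)
  }
  structure(res, class = c("coevolution_matrix", "matrix", "array"),
            mode_label = "inter", weighting = weighting,
            pseudocount = pseudocount, base = base)
}

#' Intra-protein co-evolution matrix
#'
#' Equivalent to concatenating a single-protein alignment with itself and
#' running [cmi_matrix()]; returns the square A-vs-A block. Diagonal
#' entries are self-pairs, never candidate contacts; downstream intra
#' network construction ignores them via the sequence-separation filter.
#'
#' @inheritParams cmi_matrix
#' @return A square `coevolution_matrix` with mode `"intra"`.
#' @export
intra_cmi <- function(enc, weighting = c("weighted", "unweighted"),
                      pseudocount = 1 / 21, base = exp(1)) {
  stopifnot(inherits(enc, "encoded_alignment"))
  weighting <- match.arg(weighting)
  m <- unclass(enc)
  self <- cbind(m, m)
  attr(self, "code_table") <- attr(enc, "code_table")
  attr(self, "ids") <- attr(enc, "ids")
  class(self) <- c("encoded_alignment", class(self))
  out <- cmi_matrix(self, boundary = ncol(m), weighting = weighting,
                    pseudocount = pseudocount, base = base)
  attr(out, "mode_label") <- "intra"
  out
}

#' Write a co-evolution matrix as TSV
#'
#' Two files: a wide matrix with 1-based residue indices, and optionally a
#' long format (i, j, score).
#'
#' @param cmi a `coevolution_matrix` (or plain matrix).
#' @param path output path for the wide matrix.
#' @param long_path optional path for the long format.
#' @return `path`, invisibly.
#' @export
write_cmi_tsv <- function(cmi, path, long_path = NULL) {
  m <- unclass(cmi)
  df <- data.frame(i = seq_len(nrow(m)), m, check.names = FALSE)
  colnames(df) <- c("i", seq_len(ncol(m)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(long_path)) {
    long <- data.frame(i = rep(seq_len(nrow(m)), times = ncol(m)),
                       j = rep(seq_len(ncol(m)), each = nrow(m)),
                       score = as.vector(m))
    write.table(long, long_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
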