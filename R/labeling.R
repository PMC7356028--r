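# Structure-derived residue-pair labels: heavy-atom contact seeds, then
# flank expansion under a distance cap.

#' Read two chains from a PDB file
#'
#' Minimal fixed-column ATOM-record parser (no pre-installed R package
#' provides one). Hydrogens are dropped; alternate locations other than
#' "A" are skipped; insertion codes are not supported and residue numbers
#' must be strictly increasing within a chain.
#'
#' @param path PDB file.
#' @param chain_a,chain_b chain identifiers.
#' @return A `structure_pair`: list with `chainA`, `chainB`, each a
#'   data.frame with columns `resno`, `resname`, `atom`, `element`,
#'   `x`, `y`, `z`.
#' @export
read_structure_pair <- function(path, chain_a, chain_b) {
  if (!file.exists(path)) stop_ppiface("PDB file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[startsWith(lines, "ATOM")]
  if (length(lines) == 0L) stop_ppiface("no ATOM records in %s", path)
  fld <- function(from, to) trimws(substr(lines, from, to))
  atoms <- data.frame(
    atom = fld(13, 16),
    altloc = fld(17, 17),
    resname = fld(18, 20),
    chain = fld(22, 22),
    resno = suppressWarnings(as.integer(fld(23, 26))),
    x = as.numeric(fld(31, 38)),
    y = as.numeric(fld(39, 46)),
    z = as.numeric(fld(47, 54)),
    element = fld(77, 78),
    stringsAsFactors = FALSE
  )
  atoms <- atoms[atoms$altloc %in% c("", "A"), ]
  noel <- atoms$element == ""
  atoms$element[noel] <- substr(gsub("[0-9]", "", atoms$atom[noel]), 1, 1)
  atoms <- atoms[atoms$element != "H", ]
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop_ppiface("non-finite coordinates in %s", path)
  pick <- function(ch) {
    sub <- atoms[atoms$chain == ch, setdiff(names(atoms), c("altloc", "chain"))]
    if (nrow(sub) == 0L) stop_ppiface("chain '%s' not found in %s", ch, path)
    resno <- unique(sub$resno)
    if (any(diff(resno) <= 0))
      stop_ppiface("chain '%s': residue numbers not strictly increasing", ch)
    sub
  }
  structure(list(chainA = pick(chain_a), chainB = pick(chain_b)),
            class = "structure_pair")
}

#' Construct a structure pair from atom tables
#'
#' @param chainA,chainB data.frames with columns `resno`, `resname`,
#'   `atom`, `element`, `x`, `y`, `z` (heavy atoms only).
#' @return A `structure_pair`.
#' @export
structure_pair <- function(chainA, chainB) {
  chk <- function(df, lab) {
    need <- c("resno", "resname", "atom", "element", "x", "y", "z")
    if (!all(need %in% names(df)))
      stop_ppiface("chain %s: missing columns %s", lab,
                   paste(setdiff(need, names(df)), collapse = ","))
    if (nrow(df) == 0L) stop_ppiface("chain %s has no atoms", lab)
    if (any(diff(unique(df$resno)) <= 0))
      stop_ppiface("chain %s: residue numbers not strictly increasing", lab)
    df
  }
  structure(list(chainA = chk(chainA, "A"), chainB = chk(chainB, "B")),
            class = "structure_pair")
}

#' Residue-pair label set
#'
#' @param M,N chain lengths (pair grid dimensions).
#' @param pairs data.frame with columns `i`, `j` and optionally
#'   `provenance` (`"seed"` or `"expanded"`).
#' @return A `pair_label_set`.
#' @export
pair_label_set <- function(M, N, pairs) {
  if (is.null(pairs$provenance)) pairs$provenance <- rep("seed", nrow(pairs))
  pairs <- unique(pairs[, c("i", "j", "provenance")])
  if (nrow(pairs) &&
      (any(pairs$i < 1L | pairs$i > M) || any(pairs$j < 1L | pairs$j > N)))
    stop_ppiface("label pair outside the %dx%d grid", M, N)
  dup <- duplicated(pairs[, c("i", "j")])
  pairs <- pairs[!dup, ]
  pairs <- pairs[order(pairs$i, pairs$j), ]
  rownames(pairs) <- NULL
  structure(list(M = as.integer(M), N = as.integer(N), pairs = pairs),
            class = "pair_label_set")
}

#' @export
print.pair_label_set <- function(x, ...) {
  cat(sprintf("<pair_label_set> %dx%d grid, %d positives\n",
              x$M, x$N, nrow(x$pairs)))
  invisible(x)
}

# Minimum heavy-atom distance for every residue pair, via one atom-level
# distance matrix aggregated with data.table.
.min_dist_table <- function(ca, cb) {
  A <- as.matrix(ca[, c("x", "y", "z")])
  B <- as.matrix(cb[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  dt <- data.table::data.table(
    i = rep(ca$resno, times = nrow(cb)),
    j = rep(cb$resno, each = nrow(ca)),
    d2 = as.vector(d2)
  )
  dt[, list(dmin = sqrt(min(d2))), by = c("i", "j")]
}

#' Seed interface pairs from heavy-atom contacts
#'
#' A pair (i, j) is a seed iff some heavy-atom distance between residue i
#' of chain A and residue j of chain B is below `heavy_atom_cutoff`.
#'
#' @param s a `structure_pair`.
#' @param heavy_atom_cutoff distance cutoff in Angstrom (default 5.0,
#'   strict `<`).
#' @param M,N grid dimensions; default the maximum residue number present
#'   in each chain.
#' @return A `pair_label_set` with provenance `"seed"`.
#' @export
seed_interface_pairs <- function(s, heavy_atom_cutoff = 5.0,
                                 M = max(s$chainA$resno),
                                 N = max(s$chainB$resno)) {
  stopifnot(inherits(s, "structure_pair"))
  md <- .min_dist_table(s$chainA, s$chainB)
  hits <- md[md$dmin < heavy_atom_cutoff, ]
  pair_label_set(M, N, data.frame(i = hits$i, j = hits$j,
                                  provenance = "seed"))
}

# Representative-atom coordinates per residue: C-beta, falling back to
# C-alpha (glycine), or the first heavy atom.
.rep_coords <- function(chain, mode = c("CB", "CA", "nearest")) {
  mode <- match.arg(mode)
  resnos <- unique(chain$resno)
  out <- matrix(NA_real_, max(resnos), 3L)
  for (r in resnos) {
    at <- chain[chain$resno == r, ]
    row <- switch(mode,
      CB = if (any(at$atom == "CB")) at[at$atom == "CB", ][1L, ]
           else if (any(at$atom == "CA")) at[at$atom == "CA", ][1L, ]
           else at[1L, ],
      CA = if (any(at$atom == "CA")) at[at$atom == "CA", ][1L, ] else at[1L, ],
      nearest = at[1L, ])
    out[r, ] <- c(row$x, row$y, row$z)
  }
  out
}

#' Expand seed labels over flanking residues under a distance cap
#'
#' For each seed (i, j), every (i', j') with `|i' - i| <= flank` and
#' `|j' - j| <= flank` (clipped to the grid) is added when the
#' representative-atom distance (C-beta, C-alpha fallback; configurable)
#' is at most `cap`. Residues missing from the structure are never added.
#'
#' @param seeds a `pair_label_set` of seed pairs.
#' @param s the `structure_pair` the seeds came from.
#' @param flank flank width in residues (default 2).
#' @param cap distance cap in Angstrom (default 10.0, inclusive).
#' @param rep_atom representative atom rule: `"CB"` (default), `"CA"`, or
#'   `"nearest"` (minimum heavy-atom distance).
#' @return A `pair_label_set`; pairs also present in `seeds` keep
#'   provenance `"seed"`, the rest are `"expanded"`.
#' @export
expand_labels <- function(seeds, s, flank = 2L, cap = 10.0,
                          rep_atom = c("CB", "CA", "nearest")) {
  stopifnot(inherits(seeds, "pair_label_set"), inherits(s, "structure_pair"))
  rep_atom <- match.arg(rep_atom)
  M <- seeds$M; N <- seeds$N
  if (rep_atom == "nearest") {
    md <- .min_dist_table(s$chainA, s$chainB)
    dmat <- matrix(NA_real_, M, N)
    dmat[cbind(md$i, md$j)] <- md$dmin
  } else {
    ra <- .rep_coords(s$chainA, rep_atom)
    rb <- .rep_coords(s$chainB, rep_atom)
    ra <- ra[seq_len(min(nrow(ra), M)), , drop = FALSE]
    rb <- rb[seq_len(min(nrow(rb), N)), , drop = FALSE]
    dmat <- matrix(NA_real_, M, N)
    d2 <- outer(rowSums(ra^2), rowSums(rb^2), "+") - 2 * ra %*% t(rb)
    d2[!is.na(d2) & d2 < 0] <- 0
    dmat[seq_len(nrow(ra)), seq_len(nrow(rb))] <- sqrt(d2)
  }
  keep_i <- integer(0); keep_j <- integer(0)
  for (k in seq_len(nrow(seeds$pairs))) {
    i0 <- seeds$pairs$i[k]; j0 <- seeds$pairs$j[k]
    ii <- max(1L, i0 - flank):min(M, i0 + flank)
    jj <- max(1L, j0 - flank):min(N, j0 + flank)
    g <- expand.grid(i = ii, j = jj)
    ok <- !is.na(dmat[cbind(g$i, g$j)]) & dmat[cbind(g$i, g$j)] <= cap
    keep_i <- c(keep_i, g$i[ok]); keep_j <- c(keep_j, g$j[ok])
  }
  pairs <- unique(data.frame(i = keep_i, j = keep_j))
  seed_key <- paste(seeds$pairs$i, seeds$pairs$j)
  pairs$provenance <- ifelse(paste(pairs$i, pairs$j) %in% seed_key,
                             "seed", "expanded")
  pair_label_set(M, N, pairs)
}

#' Complement of the positive labels on the pair grid
#'
#' @param labels a `pair_label_set`.
#' @return data.frame of all (i, j) not labeled positive;
#'   `nrow(negatives) + nrow(positives) = M * N`.
#' @export
negatives <- function(labels) {
  stopifnot(inherits(labels, "pair_label_set"))
  g <- expand.grid(i = seq_len(labels$M), j = seq_len(labels$N))
  pos <- paste(labels$pairs$i, labels$pairs$j)
  g[!(paste(g$i, g$j) %in% pos), ]
}

#' Positives as a binary matrix
#' @param labels a `pair_label_set`.
#' @return M x N 0/1 matrix.
#' @export
label_matrix <- function(labels) {
  m <- matrix(0L, labels$M, labels$N)
  if (nrow(labels$pairs)) m[cbind(labels$pairs$i, labels$pairs$j)] <- 1L
  m
}

#' Write labels as TSV (i, j, label, provenance)
#' @param labels a `pair_label_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(labels, path) {
  df <- data.frame(i = labels$pairs$i, j = labels$pairs$j, label = 1L,
                   provenance = labels$pairs$provenance)
  header <- sprintf("# M=%d N=%d", labels$M, labels$N)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read labels written by [write_labels_tsv()]
#' @param path TSV path.
#' @return A `pair_label_set`.
#' @export
read_labels_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("# M=(\\d+) N=(\\d+)", header))[[1L]]
  if (length(m) != 3L) stop_ppiface("missing '# M=.. N=..' header in %s", path)
  df <- read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  pair_label_set(as.integer(m[2L]), as.integer(m[3L]), df)
}
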