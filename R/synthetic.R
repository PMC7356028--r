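# Synthetic fixtures: toy complexes with a planted interface, per-residue
# annotations, and concatenated alignments with planted covariation.
#
# Geometry is idealized: residues are pseudo-atom triplets (N, CA, CB) on
# straight chains 3.8 A apart; chain B runs parallel at 30 A except at
# planted contacts, which are brought to 4.5 A of their partner. With that
# spacing exactly the planted pairs satisfy the 5 A heavy-atom seed
# criterion (nearest non-planted approach is ~5.3 A).

#' Specification for one synthetic complex
#'
#' Defaults state the standard test world used throughout the package:
#' chains of 30 and 25 residues, 4 planted contacts, covariation coupling
#' 0.9, alignment depth 500.
#'
#' @param M,N chain lengths.
#' @param n_interface number of planted contact pairs
#'   (`<= min(M, N)`, placed on distinct residues of both chains).
#' @param coupling probability that a coupled column pair co-varies in a
#'   given sequence.
#' @param n_sequences alignment depth.
#' @param seed integer seed; all generators are deterministic given it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(M = 30L, N = 25L, n_interface = 4L,
                           coupling = 0.9, n_sequences = 500L, seed = 1L) {
  if (!is_count(M) || !is_count(N) || !is_count(n_interface) ||
      !is_count(n_sequences))
    stop_ppiface("M, N, n_interface, n_sequences must be positive integers")
  if (n_interface > min(M, N))
    stop_ppiface("n_interface (%d) exceeds min(M, N) = %d",
                 n_interface, min(M, N))
  if (coupling < 0 || coupling > 1) stop_ppiface("coupling must be in [0, 1]")
  structure(list(M = as.integer(M), N = as.integer(N),
                 n_interface = as.integer(n_interface),
                 coupling = coupling, n_sequences = as.integer(n_sequences),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.chain_atoms <- function(seq_letters, ca) {
  n <- length(seq_letters)
  three <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
             G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
             M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
             S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")
  rows <- lapply(seq_len(n), function(i) {
    base <- ca[i, ]
    at <- data.frame(
      resno = i, resname = three[[seq_letters[i]]],
      atom = c("N", "CA", "CB"), element = c("N", "C", "C"),
      x = base[1L] + c(-0.5, 0, 0),
      y = base[2L] + c(0.4, 0, 0),
      z = base[3L] + c(0, 0, 1.5))
    if (seq_letters[i] == "G") at <- at[at$atom != "CB", ]
    at
  })
  do.call(rbind, rows)
}

#' Generate a toy complex with a planted interface
#'
#' Returns idealized coordinates for two chains in which exactly
#' `n_interface` residue pairs fall under the 5 Angstrom heavy-atom seed
#' criterion, plus per-residue annotations (RSA strictly positive on the
#' surface, exactly 0 on a designated buried subset disjoint from the
#' interface; secondary structure assigned in runs) and the ground-truth
#' label set.
#'
#' @param spec a `synthetic_spec`.
#' @return List with `structure` (`structure_pair`), `seqA`, `seqB`,
#'   `annA`, `annB` (`residue_annotations`), `truth` (`pair_label_set` of
#'   the planted seeds), `planted` (data.frame i, j), `buriedA`, `buriedB`.
#' @export
gen_complex <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  M <- spec$M; N <- spec$N; k <- spec$n_interface
  with_seed(spec$seed, {
    pi_ <- sort(sample(M, k))
    pj <- sample(N, k)
    seqA <- sample(AA_LETTERS, M, replace = TRUE)
    seqB <- sample(AA_LETTERS, N, replace = TRUE)
    caA <- cbind(3.8 * seq_len(M), 0, 0)
    caB <- cbind(3.8 * seq_len(N), 30, 0)
    # y = 4.5 puts planted CA pairs inside the 5 A heavy-atom criterion
    # while the nearest non-planted atom pair stays at ~5.3 A
    for (t in seq_len(k)) caB[pj[t], ] <- c(3.8 * pi_[t], 4.5, 0)
    s <- structure_pair(.chain_atoms(seqA, caA), .chain_atoms(seqB, caB))
    surface_rsa <- function(L, planted) {
      rsa <- runif(L, 0.05, 1)
      pool <- setdiff(seq_len(L), planted)
      n_buried <- min(length(pool), max(1L, round(0.2 * L)))
      buried <- sort(sample(pool, n_buried))
      rsa[buried] <- 0
      list(rsa = rsa, buried = buried)
    }
    ra <- surface_rsa(M, pi_)
    rb <- surface_rsa(N, pj)
    ssp_runs <- function(L) {
      out <- character(0)
      while (length(out) < L)
        out <- c(out, rep(sample(SSP_CLASSES, 1L),
                          sample(3:8, 1L)))
      out[seq_len(L)]
    }
    annA <- residue_annotations(ra$rsa, ssp_runs(M), aa = seqA)
    annB <- residue_annotations(rb$rsa, ssp_runs(N), aa = seqB)
    truth <- pair_label_set(M, N, data.frame(i = pi_, j = pj,
                                             provenance = "seed"))
    list(structure = s,
         seqA = paste(seqA, collapse = ""),
         seqB = paste(seqB, collapse = ""),
         annA = annA, annB = annB, truth = truth,
         planted = data.frame(i = pi_, j = pj),
         buriedA = ra$buried, buriedB = rb$buried)
  })
}

#' Generate a concatenated alignment with planted covariation
#'
#' Background columns are i.i.d. uniform over the 20 residues. For each
#' planted pair (i, j), a fixed random bijection of the alphabet is chosen;
#' with probability `coupling` a sequence's residue at B-column j is
#' replaced by the bijective image of its residue at A-column i. The
#' bijection model gives closed-form expected mutual information, which the
#' co-evolution tests exploit.
#'
#' @param spec a `synthetic_spec`.
#' @param truth `pair_label_set` (or data.frame i, j) of coupled pairs;
#'   defaults to the planted pairs of [gen_complex()] run on `spec`.
#' @return A `concat_alignment` of `n_sequences` rows and `M + N` columns,
#'   species ids `sp0001...`.
#' @export
gen_coupled_msa <- function(spec, truth = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(truth)) truth <- gen_complex(spec)$truth
  pairs <- if (inherits(truth, "pair_label_set")) truth$pairs else truth
  M <- spec$M; N <- spec$N; n <- spec$n_sequences
  if (nrow(pairs) && (max(pairs$i) > M || max(pairs$j) > N))
    stop_ppiface("truth pairs outside the %dx%d grid", M, N)
  with_seed(derive_seed(spec$seed, 7919L), {
    codes <- matrix(sample.int(20L, n * (M + N), replace = TRUE), n, M + N)
    for (t in seq_len(nrow(pairs))) {
      perm <- sample.int(20L)
      mask <- runif(n) < spec$coupling
      jcol <- M + pairs$j[t]
      codes[mask, jcol] <- perm[codes[mask, pairs$i[t]]]
    }
    seqs <- apply(codes, 1L, function(r) paste(AA_LETTERS[r], collapse = ""))
    ids <- sprintf("sp%04d", seq_len(n))
    aln <- new_alignment(ids, seqs, name = "synthetic_concat")
    aln$lenA <- M; aln$lenB <- N; aln$boundary <- M
    class(aln) <- c("concat_alignment", class(aln))
    aln
  })
}

#' Split a concatenated alignment into its two protein alignments
#'
#' @param concat a `concat_alignment`.
#' @return List of two `aa_alignment`s sharing the species ids.
#' @export
split_concat <- function(concat) {
  stopifnot(inherits(concat, "concat_alignment"))
  b <- concat$boundary
  list(A = new_alignment(concat$ids, substr(concat$seqs, 1L, b),
                         name = paste0(concat$name, "_A")),
       B = new_alignment(concat$ids, substr(concat$seqs, b + 1L, concat$width),
                         name = paste0(concat$name, "_B")))
}

#' Write a structure pair as a minimal PDB file
#'
#' Chains are written as "A" and "B" with fixed-width ATOM records, enough
#' for [read_structure_pair()] and standard viewers.
#'
#' @param s a `structure_pair`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "structure_pair"))
  fmt <- function(df, chain, serial0) {
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial0 + seq_len(nrow(df)),
            ifelse(nchar(df$atom) < 4, paste0(" ", df$atom), df$atom),
            df$resname, chain, df$resno, df$x, df$y, df$z, df$element)
  }
  lines <- c(fmt(s$chainA, "A", 0L),
             "TER",
             fmt(s$chainB, "B", nrow(s$chainA)),
             "TER", "END")
  writeLines(lines, path)
  invisible(path)
}
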