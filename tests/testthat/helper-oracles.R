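# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately use different code paths (joint tables, quadruple
# loops, exhaustive scans) from the implementation they check.

# Random alignment with optional gaps, as an aa_alignment.
random_alignment <- function(n_rows, width, gap_frac = 0, seed = 1,
                             alphabet = AA_LETTERS) {
  set.seed(seed)
  seqs <- replicate(n_rows, {
    s <- sample(alphabet, width, replace = TRUE)
    if (gap_frac > 0) {
      g <- runif(width) < gap_frac
      s[g] <- "-"
    }
    paste(s, collapse = "")
  })
  new_alignment(sprintf("sp%03d", seq_len(n_rows)), seqs)
}

# Perturbation score recomputed from the 21x21 joint symbol table of
# columns (i, j): one tabulation of the joint counts, then direct sums.
# Independent of the per-condition row subsetting the implementation uses.
mi_joint_oracle <- function(enc, i, j, pseudocount = 0,
                            weighted = TRUE) {
  m <- unclass(enc)
  n <- nrow(m)
  joint <- matrix(0, 21, 21)                     # rows = symbol at i
  for (r in seq_len(n))
    joint[m[r, i] + 1L, m[r, j] + 1L] <- joint[m[r, i] + 1L, m[r, j] + 1L] + 1
  col_counts <- colSums(joint)                   # symbol counts at j
  q <- (col_counts + pseudocount) / (n + 21 * pseudocount)
  total <- 0
  for (a in 2:21) {                              # conditions: non-gap at i
    na <- sum(joint[a, ])
    if (na == 0) next
    p <- (joint[a, ] + pseudocount) / (na + 21 * pseudocount)
    kl <- 0
    for (b in 1:21) if (p[b] > 0) kl <- kl + p[b] * log(p[b] / q[b])
    total <- total + (if (weighted) na / n else 1) * kl
  }
  total
}

# Classic mutual information of two gap-free columns (no smoothing).
mi_classic <- function(enc, i, j) {
  m <- unclass(enc)
  n <- nrow(m)
  tab <- table(m[, i], m[, j]) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  s <- 0
  for (a in rownames(tab)) for (b in colnames(tab)) {
    p <- tab[a, b]
    if (p > 0) s <- s + p * log(p / (pa[a] * pb[b]))
  }
  unname(s)
}

# Quadruple-loop zero-padded cross-correlation.
conv_brute <- function(m, w) {
  k <- nrow(w); half <- (k - 1) / 2
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    acc <- 0
    for (di in -half:half) for (dj in -half:half) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m))
        acc <- acc + w[di + half + 1, dj + half + 1] * m[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# Exhaustive heavy-atom interface scan over all residue/atom pairs.
seed_pairs_brute <- function(s, cutoff = 5.0) {
  res <- list()
  for (i in unique(s$chainA$resno)) {
    ai <- s$chainA[s$chainA$resno == i, ]
    for (j in unique(s$chainB$resno)) {
      bj <- s$chainB[s$chainB$resno == j, ]
      dmin <- Inf
      for (r in seq_len(nrow(ai))) for (q in seq_len(nrow(bj)))
        dmin <- min(dmin, sqrt(sum((c(ai$x[r], ai$y[r], ai$z[r]) -
                                    c(bj$x[q], bj$y[q], bj$z[q]))^2)))
      if (dmin < cutoff) res[[length(res) + 1L]] <- c(i, j)
    }
  }
  if (length(res) == 0L) return(data.frame(i = integer(0), j = integer(0)))
  df <- as.data.frame(do.call(rbind, res))
  names(df) <- c("i", "j")
  df[order(df$i, df$j), ]
}

# Representative-atom coordinate of one residue (CB, else CA, else first).
rep_atom_brute <- function(chain, r) {
  at <- chain[chain$resno == r, ]
  if (nrow(at) == 0L) return(NULL)
  row <- if (any(at$atom == "CB")) at[at$atom == "CB", ][1, ]
         else if (any(at$atom == "CA")) at[at$atom == "CA", ][1, ]
         else at[1, ]
  c(row$x, row$y, row$z)
}

# Exhaustive flank-grid expansion scan.
expand_brute <- function(seeds, s, flank = 2, cap = 10) {
  M <- seeds$M; N <- seeds$N
  res <- list()
  for (k in seq_len(nrow(seeds$pairs))) {
    i0 <- seeds$pairs$i[k]; j0 <- seeds$pairs$j[k]
    for (i in max(1, i0 - flank):min(M, i0 + flank))
      for (j in max(1, j0 - flank):min(N, j0 + flank)) {
        ra <- rep_atom_brute(s$chainA, i); rb <- rep_atom_brute(s$chainB, j)
        if (is.null(ra) || is.null(rb)) next
        if (sqrt(sum((ra - rb)^2)) <= cap)
          res[[length(res) + 1L]] <- c(i, j)
      }
  }
  if (length(res) == 0L) return(data.frame(i = integer(0), j = integer(0)))
  df <- unique(as.data.frame(do.call(rbind, res)))
  names(df) <- c("i", "j")
  df <- df[order(df$i, df$j), ]
  rownames(df) <- NULL
  df
}

# Separable training table: positives shifted by `shift` on the first
# `n_signal` features — the planted-separation fixture.
make_separable_table <- function(n_pos = 100, ratio = 5, shift = 3,
                                 n_signal = 6, seed = 1,
                                 feats = feature_names(TRUE)) {
  set.seed(seed)
  n_neg <- n_pos * ratio
  p <- length(feats)
  x <- matrix(rnorm((n_pos + n_neg) * p), ncol = p)
  x[seq_len(n_pos), seq_len(n_signal)] <- x[seq_len(n_pos),
                                            seq_len(n_signal)] + shift
  colnames(x) <- feats
  df <- data.frame(complex_id = "fixture", i = 1L, j = 1L, x,
                   label = c(rep(1L, n_pos), rep(0L, n_neg)))
  attr(df, "features") <- feats
  df
}

# Full synthetic complex with features and expanded labels, for
# classifier-level tests. Sizes kept small so a leave-one-out run over a
# handful of complexes stays inside the suite's time budget.
make_synthetic_case <- function(seed, M = 14, N = 12, n_interface = 3,
                                n_sequences = 120, coupling = 0.9) {
  spec <- synthetic_spec(M = M, N = N, n_interface = n_interface,
                         coupling = coupling, n_sequences = n_sequences,
                         seed = seed)
  cx <- gen_complex(spec)
  msa <- gen_coupled_msa(spec, cx$truth)
  cmi <- cmi_matrix(encode_alignment(msa))
  base <- build_base_stack(cx$seqA, cx$seqB, cmi, cx$annA, cx$annB)
  stack <- derive_env_stack(base, make_kernel(3, 0.10))
  labels <- expand_labels(seed_interface_pairs(cx$structure), cx$structure)
  list(spec = spec, cx = cx, stack = stack, labels = labels)
}

# Tiny grid for quick classifier fits in tests (scaled-down; the default
# grid is exercised once in the CLI smoke test via --grid small).
small_grid <- function() {
  data.frame(num_trees = 100L, max_depth = c(0L, 10L),
             max_features = "sqrt", min_node = 1L,
             stringsAsFactors = FALSE)
}
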