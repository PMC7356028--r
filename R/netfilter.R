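# Network post-filter: intra-protein co-evolution networks, buried-residue
# removal, unitary-kernel cluster scoring and stretch mapping. Each stage
# only removes pairs, so the pipeline is monotone.

#' Intra-protein contact network from an intra co-evolution matrix
#'
#' Candidate pairs are unordered (i, i') with sequence separation
#' `|i - i'| >= min_sep`; the pair score is the mean of the two matrix
#' entries (the intra matrix is symmetric up to smoothing effects). Edges
#' are the top fraction of candidates by score. Two interpretations of
#' "top fraction" are provided: `"count"` (default) keeps the top
#' `ceiling(top_frac * n_candidates)` pairs; `"value"` keeps pairs whose
#' score exceeds `min + (1 - top_frac) * range` of the candidate scores.
#'
#' @param cmi square intra `coevolution_matrix` (or plain matrix).
#' @param min_sep minimum sequence separation (default 5).
#' @param top_frac fraction of candidates kept (default 0.05).
#' @param mode `"count"` or `"value"` (see above).
#' @return An `intra_network`: list with `edges` (data.frame i, j, score),
#'   `nodes` (edge-incident residues), `L`, `n_candidates`, and
#'   `n_total_pairs` (= choose(L, 2), before separation filtering).
#' @export
intra_network <- function(cmi, min_sep = 5L, top_frac = 0.05,
                          mode = c("count", "value")) {
  mode <- match.arg(mode)
  m <- unclass(cmi)
  if (nrow(m) != ncol(m)) stop_ppiface("intra matrix must be square")
  L <- nrow(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  idx <- idx[idx[, 2L] - idx[, 1L] >= min_sep, , drop = FALSE]
  if (nrow(idx) == 0L) {
    warning("no candidate pairs at this separation; empty network",
            call. = FALSE)
    return(structure(list(edges = data.frame(i = integer(0), j = integer(0),
                                             score = numeric(0)),
                          nodes = integer(0), L = L, n_candidates = 0L,
                          n_total_pairs = choose(L, 2)),
                     class = "intra_network"))
  }
  score <- (m[idx] + m[idx[, c(2L, 1L), drop = FALSE]]) / 2
  keep <- switch(mode,
    count = {
      k <- ceiling(top_frac * nrow(idx))
      order(-score, idx[, 1L], idx[, 2L])[seq_len(k)]
    },
    value = {
      thr <- min(score) + (1 - top_frac) * (max(score) - min(score))
      which(score > thr)
    })
  edges <- data.frame(i = idx[keep, 1L], j = idx[keep, 2L],
                      score = score[keep])
  edges <- edges[order(-edges$score, edges$i, edges$j), ]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$i, edges$j))),
                 L = L, n_candidates = nrow(idx),
                 n_total_pairs = choose(L, 2)),
            class = "intra_network")
}

#' @export
print.intra_network <- function(x, ...) {
  cat(sprintf("<intra_network> L=%d, %d/%d candidate pairs kept, %d nodes\n",
              x$L, nrow(x$edges), x$n_candidates, length(x$nodes)))
  invisible(x)
}

#' Convert networks to igraph objects
#'
#' @param x an `intra_network`, or a binary M x N inter matrix.
#' @param ... unused.
#' @return An igraph graph (bipartite for matrices). Requires the
#'   suggested igraph package.
#' @export
as_igraph <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop_ppiface("the igraph package is required for graph export")
  if (inherits(x, "intra_network")) {
    igraph::graph_from_data_frame(
      data.frame(from = paste0("r", x$edges$i), to = paste0("r", x$edges$j),
                 weight = x$edges$score), directed = FALSE)
  } else {
    idx <- which(x == 1L, arr.ind = TRUE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = paste0("A", idx[, 1L]), to = paste0("B", idx[, 2L])),
      directed = FALSE)
    igraph::V(g)$type <- startsWith(igraph::V(g)$name, "B")
    g
  }
}

#' Residual inter-protein network
#'
#' Removes nodes, not edges: row i of the binary prediction matrix is
#' zeroed when residue i of protein A is buried (RSA = 0) or participates
#' in a top intra-protein co-evolution pair; likewise columns for protein
#' B. Idempotent, and never adds a 1-cell.
#'
#' @param pred binary M x N prediction matrix.
#' @param rsaA,rsaB per-residue RSA vectors.
#' @param nodesA,nodesB intra-network node sets ([intra_network()]
#'   `$nodes`), or `intra_network` objects.
#' @return Binary M x N matrix.
#' @export
residual_network <- function(pred, rsaA, rsaB,
                             nodesA = integer(0), nodesB = integer(0)) {
  if (inherits(nodesA, "intra_network")) nodesA <- nodesA$nodes
  if (inherits(nodesB, "intra_network")) nodesB <- nodesB$nodes
  M <- nrow(pred); N <- ncol(pred)
  if (length(rsaA) != M || length(rsaB) != N)
    stop_ppiface("RSA vector lengths (%d, %d) do not match matrix %dx%d",
                 length(rsaA), length(rsaB), M, N)
  out <- pred
  dropA <- unique(c(which(rsaA == 0), nodesA))
  dropB <- unique(c(which(rsaB == 0), nodesB))
  if (length(dropA)) out[dropA[dropA <= M], ] <- 0L
  if (length(dropB)) out[, dropB[dropB <= N]] <- 0L
  out
}

#' Score predicted pairs by unitary-kernel window sums
#'
#' Convolves an all-ones kernel of the given size over the binary
#' prediction matrix (zero-padded), so each cell's score counts the 1s in
#' its neighborhood (maximum 9 for 3x3, 25 for 5x5). Predicted-positive
#' cells whose score strictly exceeds the cutoff are retained: isolated
#' positives are discarded, clusters survive.
#'
#' @param pred binary M x N matrix.
#' @param kernel_size 3 or 5 — match the environment-feature kernel.
#' @param cutoff retention threshold (strict `>`); defaults to 2 for 3x3
#'   and 6 for 5x5 (about 25% window occupancy).
#' @param prob optional probability matrix; adds a `probability` column.
#' @return A `scored_pairs` data.frame (i, j, score[, probability]) with
#'   attributes `kernel_size`, `cutoff`, `score_matrix`.
#' @export
convolution_score <- function(pred, kernel_size = 5L, cutoff = NULL,
                              prob = NULL) {
  if (!(kernel_size %in% c(3L, 5L)))
    stop_ppiface("kernel_size must be 3 or 5 (got %s)", format(kernel_size))
  if (is.null(cutoff)) cutoff <- if (kernel_size == 3L) 2 else 6
  unit <- matrix(1, kernel_size, kernel_size)
  score <- convolve_same(pred, unit)
  keep <- which(pred == 1L & score > cutoff, arr.ind = TRUE)
  out <- data.frame(i = keep[, 1L], j = keep[, 2L], score = score[keep])
  if (!is.null(prob)) out$probability <- prob[keep]
  out <- out[order(out$i, out$j), ]
  rownames(out) <- NULL
  structure(out, kernel_size = as.integer(kernel_size), cutoff = cutoff,
            score_matrix = score, class = c("scored_pairs", "data.frame"))
}

# Indices lying in a run of >= run_length consecutive values.
.run_members <- function(values, run_length) {
  u <- sort(unique(values))
  if (length(u) == 0L) return(integer(0))
  grp <- cumsum(c(1L, diff(u) != 1L))
  len <- ave(u, grp, FUN = length)
  u[len >= run_length]
}

#' Keep pairs lying in contiguous stretches on both chains
#'
#' Interface hotspots span several consecutive residues; a retained pair
#' survives only if the retained set covers at least `run_length`
#' consecutive A-residues including its i, and likewise for j on B.
#'
#' @param pairs a `scored_pairs` data.frame (or any data.frame with i, j).
#' @param run_length required stretch length (default 3).
#' @return Filtered `scored_pairs` (attributes preserved).
#' @export
stretch_filter <- function(pairs, run_length = 3L) {
  okA <- .run_members(pairs$i, run_length)
  okB <- .run_members(pairs$j, run_length)
  out <- pairs[pairs$i %in% okA & pairs$j %in% okB, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("kernel_size", "cutoff", "score_matrix"))
    attr(out, a) <- attr(pairs, a)
  class(out) <- class(pairs)
  out
}

#' Run the full post-filter on a prediction matrix
#'
#' Residual network (buried residues + intra-network nodes), unitary-kernel
#' scoring, then the stretch filter. Returns all intermediate stages so the
#' monotone reduction is auditable.
#'
#' @param pred binary M x N prediction matrix.
#' @param rsaA,rsaB per-residue RSA vectors.
#' @param intraA,intraB `intra_network` objects (or node vectors).
#' @param kernel_size 3 or 5.
#' @param prob optional probability matrix.
#' @param run_length stretch length (default 3).
#' @return List with `residual` (matrix), `scored` (`scored_pairs`),
#'   `final` (`scored_pairs` after the stretch filter).
#' @export
netfilter <- function(pred, rsaA, rsaB, intraA = integer(0),
                      intraB = integer(0), kernel_size = 5L, prob = NULL,
                      run_length = 3L) {
  residual <- residual_network(pred, rsaA, rsaB, intraA, intraB)
  scored <- convolution_score(residual, kernel_size = kernel_size,
                              prob = prob)
  final <- stretch_filter(scored, run_length = run_length)
  list(residual = residual, scored = scored, final = final)
}
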