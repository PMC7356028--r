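test_that("intra_network enumerates separation-filtered candidates", {
  m <- matrix(runif(100), 10, 10); m <- (m + t(m)) / 2
  net <- intra_network(m, min_sep = 5, top_frac = 1)   # keep everything
  want <- do.call(rbind, lapply(1:10, function(i) {
    js <- seq_len(10)[seq_len(10) >= i + 5]
    if (length(js)) cbind(i, js)
  }))
  expect_equal(nrow(net$edges), nrow(want))
  expect_setequal(paste(net$edges$i, net$edges$j), paste(want[, 1], want[, 2]))
  expect_equal(net$n_total_pairs, choose(10, 2))

  # top-fraction count: ceiling(0.05 * candidates)
  net5 <- intra_network(m, min_sep = 5, top_frac = 0.05)
  expect_equal(nrow(net5$edges), ceiling(0.05 * net$n_candidates))
  expect_setequal(net5$nodes, unique(c(net5$edges$i, net5$edges$j)))
  # edges are the highest-scoring candidates
  expect_gte(min(net5$edges$score),
             sort(net$edges$score, decreasing = TRUE)[nrow(net5$edges)])

  # chain lengths from the worked examples: 56 -> 1540, 69 -> 2346
  expect_equal(intra_network(matrix(0, 56, 56))$n_total_pairs, 1540)
  expect_equal(intra_network(matrix(0, 69, 69))$n_total_pairs, 2346)

  expect_warning(tiny <- intra_network(matrix(1, 3, 3), min_sep = 5),
                 "empty")
  expect_equal(nrow(tiny$edges), 0L)
})

test_that("value mode thresholds on the score range", {
  m <- matrix(0, 12, 12)
  m[1, 8] <- m[8, 1] <- 10      # one dominant pair
  m[2, 9] <- m[9, 2] <- 1
  net <- intra_network(m, min_sep = 5, top_frac = 0.05, mode = "value")
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$i, 1L); expect_equal(net$edges$j, 8L)
})

test_that("residual_network removes buried and intra nodes only", {
  set.seed(2)
  pred <- matrix(rbinom(40, 1, 0.4), 5, 8)
  rsaA <- runif(5, 0.1, 1); rsaB <- runif(8, 0.1, 1)
  expect_identical(residual_network(pred, rsaA, rsaB), pred)   # identity case
  expect_true(all(residual_network(pred, rep(0, 5), rsaB) == 0))

  nodesA <- c(2L, 4L); nodesB <- 7L
  rsaA[1] <- 0
  got <- residual_network(pred, rsaA, rsaB, nodesA, nodesB)
  # edge-list oracle: drop edges incident to eliminated nodes
  keep <- which(pred == 1L, arr.ind = TRUE)
  keep <- keep[!(keep[, 1] %in% c(1L, nodesA)) & !(keep[, 2] %in% nodesB), ,
               drop = FALSE]
  want <- matrix(0L, 5, 8); want[keep] <- 1L
  expect_equal(got, want)
  expect_true(all(got <= pred))
  expect_equal(residual_network(got, rsaA, rsaB, nodesA, nodesB), got) # idempotent
})

test_that("convolution_score retains clustered cells above the cutoff", {
  ones <- matrix(1L, 9, 9)
  s3 <- convolution_score(ones, 3)
  expect_equal(max(attr(s3, "score_matrix")), 9)     # full 3x3 window
  s5 <- convolution_score(ones, 5)
  expect_equal(max(attr(s5, "score_matrix")), 25)    # full 5x5 window

  lone <- matrix(0L, 7, 7); lone[4, 4] <- 1L
  expect_equal(nrow(convolution_score(lone, 3)), 0L) # score 1 <= 2 dropped

  # strictness at the cutoff: in a 3-run only the center scores 3 (> 2);
  # the ends score exactly 2 and are dropped
  cross <- matrix(0L, 7, 7); cross[4, 3:5] <- 1L
  kept <- convolution_score(cross, 3)
  expect_equal(kept$score, 3)
  expect_equal(nrow(kept), 1L)
  expect_equal(c(kept$i, kept$j), c(4L, 4L))

  expect_error(convolution_score(ones, 7), "kernel_size")
})

test_that("window scores match the brute-force oracle on random matrices", {
  set.seed(31)
  for (rep_ in 1:3) {
    pred <- matrix(rbinom(108, 1, 0.35), 12, 9)
    for (ks in c(3L, 5L)) {
      got <- convolution_score(pred, ks)
      unit <- matrix(1, ks, ks)
      want_scores <- conv_brute(pred, unit)
      cutoff <- if (ks == 3L) 2 else 6
      want <- which(pred == 1L & want_scores > cutoff, arr.ind = TRUE)
      want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
      expect_equal(cbind(got$i, got$j), unname(want), ignore_attr = TRUE)
      expect_equal(got$score, want_scores[want])
    }
    # cutoff 0 retains exactly the 1-cells
    all_kept <- convolution_score(pred, 3, cutoff = 0)
    expect_equal(nrow(all_kept), sum(pred))
  }
})

test_that("stretch_filter requires 3-runs on both chains", {
  run <- data.frame(i = c(5, 6, 7), j = c(9, 10, 11), score = 3)
  expect_equal(nrow(stretch_filter(run)), 3L)
  lone <- data.frame(i = c(5, 6, 7, 20), j = c(9, 10, 11, 2), score = 3)
  expect_equal(nrow(stretch_filter(lone)), 3L)       # isolated pair dropped
  expect_equal(nrow(stretch_filter(run[1:2, ])), 0L)

  # brute-force run-scan oracle on random pair sets
  set.seed(7)
  for (rep_ in 1:5) {
    pairs <- unique(data.frame(i = sample(1:15, 25, TRUE),
                               j = sample(1:12, 25, TRUE)))
    pairs$score <- 1
    got <- stretch_filter(pairs, run_length = 3)
    in_run <- function(v, x) {
      u <- sort(unique(v))
      any(vapply(x + (-2:0), function(st)
        all((st:(st + 2)) %in% u), logical(1)))
    }
    want <- pairs[vapply(seq_len(nrow(pairs)), function(r)
      in_run(pairs$i, pairs$i[r]) && in_run(pairs$j, pairs$j[r]),
      logical(1)), ]
    expect_setequal(paste(got$i, got$j), paste(want$i, want$j))
  }
})

test_that("the post-filter pipeline only ever removes pairs", {
  set.seed(19)
  for (run in 1:10) {
    M <- sample(10:20, 1); N <- sample(10:20, 1)
    pred <- matrix(rbinom(M * N, 1, runif(1, 0.2, 0.6)), M, N)
    rsaA <- runif(M); rsaA[sample(M, 2)] <- 0
    rsaB <- runif(N)
    nodesA <- sample(M, sample(0:3, 1))
    nodesB <- sample(N, sample(0:3, 1))
    res <- netfilter(pred, rsaA, rsaB, nodesA, nodesB,
                     kernel_size = sample(c(3L, 5L), 1))
    expect_gte(sum(pred), sum(res$residual))
    expect_gte(sum(res$residual), nrow(res$scored))
    expect_gte(nrow(res$scored), nrow(res$final))
  }
})

test_that("networks export to igraph", {
  m <- matrix(runif(64), 8); m <- (m + t(m)) / 2
  net <- intra_network(m, min_sep = 3, top_frac = 0.2)
  g <- as_igraph(net)
  expect_equal(igraph::ecount(g), nrow(net$edges))
  pred <- matrix(0L, 4, 5); pred[cbind(c(1, 2), c(3, 3))] <- 1L
  bg <- as_igraph(pred)
  expect_true(igraph::is_bipartite(bg))
  expect_equal(igraph::ecount(bg), 2)
})
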