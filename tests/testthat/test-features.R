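test_that("default property tables are symmetric, complete and distinct", {
  tabs <- default_property_tables()
  expect_setequal(names(tabs), c("CCM", "HCM", "SCM", "CP", "CPE", "CPB"))
  for (nm in names(tabs)) {
    tb <- tabs[[nm]]
    expect_identical(dim(tb), c(20L, 20L))
    expect_identical(rownames(tb), AA_LETTERS)
    expect_equal(tb, t(tb), info = nm)
  }
  # contact-potential stand-ins must not be affine images of each other
  # (min-max scaling would otherwise collapse them)
  sc <- lapply(tabs[c("CP", "CPE", "CPB")], minmax_scale)
  expect_gt(max(abs(sc$CP - sc$CPE)), 0.01)
  expect_gt(max(abs(sc$CP - sc$CPB)), 0.01)
})

test_that("read_property_table round-trips and validates", {
  tb <- default_property_tables()$HCM
  f <- tempfile(fileext = ".tsv")
  write.table(tb, f, sep = "\t", quote = FALSE)
  expect_equal(read_property_table(f), tb)
  bad <- tb; bad[1, 2] <- bad[1, 2] + 1
  write.table(bad, f, sep = "\t", quote = FALSE)
  expect_error(read_property_table(f), "symmetric")
})

test_that("pairwise_from_table matches a looped lookup oracle", {
  tb <- default_property_tables()$CCM
  expect_equal(pairwise_from_table("A", "C", tb),
               matrix(tb["A", "C"], 1, 1, dimnames = list("A", "C")))

  set.seed(5)
  sA <- paste(sample(AA_LETTERS, 5, TRUE), collapse = "")
  sB <- paste(sample(AA_LETTERS, 7, TRUE), collapse = "")
  got <- pairwise_from_table(sA, sB, tb)
  a <- strsplit(sA, "")[[1]]; b <- strsplit(sB, "")[[1]]
  for (i in 1:5) for (j in 1:7)
    expect_equal(unname(got[i, j]), unname(tb[a[i], b[j]]))

  # table symmetry implies transpose on argument swap
  expect_equal(unname(pairwise_from_table(sB, sA, tb)), unname(t(got)))
})

test_that("rsa_pair is the outer product (rank-1)", {
  expect_equal(rsa_pair(c(1, 0.5), 0.2), matrix(c(0.2, 0.1), 2, 1))
  m <- rsa_pair(c(0, 0.8, 0.3), c(0.5, 0.9))
  expect_true(all(m[1, ] == 0))                     # buried annihilates row
  # every 2x2 minor vanishes
  expect_equal(m[2, 1] * m[3, 2] - m[2, 2] * m[3, 1], 0)
  expect_error(rsa_pair(c(-0.1, 0.5), 0.2), "negative")
})

test_that("ssp_pair looks up unordered class pairs", {
  ranks <- default_ssp_ranks()
  expect_length(ranks, 6)
  expect_equal(sort(unname(ranks)), (1:6) / 6)

  m <- ssp_pair(c("H", "E", "C"), c("C", "H"), ranks)
  expect_equal(unname(m[1, 2]), unname(ranks[["H-H"]]))
  expect_equal(unname(m[1, 1]), unname(ranks[["C-H"]]))
  expect_equal(unname(m[2, 1]), unname(ranks[["C-E"]]))

  allH <- ssp_pair(rep("H", 4), rep("H", 3), ranks)
  expect_true(all(allH == ranks[["H-H"]]))
  expect_lte(length(unique(as.vector(
    ssp_pair(sample(c("H", "E", "C"), 30, TRUE),
             sample(c("H", "E", "C"), 20, TRUE), ranks)))), 6)
  expect_error(ssp_pair("X", "H", ranks), "unknown")
})

test_that("learn_ssp_ranks ranks combos by occurrence deterministically", {
  sspA <- c("H", "H", "C", "E")
  sspB <- c("C", "H", "E")
  pos <- data.frame(i = c(1, 1, 2, 3, 3, 4), j = c(1, 1, 1, 2, 3, 3))
  r <- learn_ssp_ranks(sspA, sspB, pos)
  expect_length(r, 6)
  expect_setequal(names(r), c("H-H", "E-H", "C-H", "E-E", "C-E", "C-C"))
  expect_equal(sort(unname(r)), (1:6) / 6)
  # C-H occurs 3x (most frequent) -> top rank
  expect_equal(unname(r[["C-H"]]), 1)
  expect_identical(r, learn_ssp_ranks(sspA, sspB, pos))
})

test_that("minmax_scale maps to [0,1] with fixed degenerate convention", {
  expect_equal(minmax_scale(matrix(c(1, 5, 3, 7), 2)),
               matrix(c(0, 2 / 3, 1 / 3, 1), 2))
  expect_equal(minmax_scale(matrix(4, 2, 2)), matrix(0, 2, 2))
  m <- matrix(rnorm(12), 3)
  expect_equal(minmax_scale(minmax_scale(m)), minmax_scale(m))
  expect_equal(which.max(minmax_scale(m)), which.max(m))
})

test_that("annotations round-trip through TSV and map 8-class codes", {
  ann <- residue_annotations(c(0, 0.4, 1), c("G", "B", "S"), aa = c("A", "C", "D"))
  expect_equal(ann$ssp, c("H", "E", "C"))
  f <- tempfile(fileext = ".tsv")
  write_annotations(ann, f)
  back <- read_annotations(f)
  expect_equal(back$rsa, ann$rsa)
  expect_equal(back$ssp, ann$ssp)
  expect_error(residue_annotations(c(0.5, 1.2), c("H", "H")), "0, 1")
  expect_error(residue_annotations(0.5, "Z"), "unknown")
})

test_that("build_base_stack assembles 9 scaled matrices consistently", {
  set.seed(9)
  M <- 3L; N <- 4L
  seqA <- paste(sample(AA_LETTERS, M, TRUE), collapse = "")
  seqB <- paste(sample(AA_LETTERS, N, TRUE), collapse = "")
  cmi <- matrix(runif(M * N), M, N)
  annA <- residue_annotations(runif(M), sample(c("H", "E", "C"), M, TRUE))
  annB <- residue_annotations(runif(N), sample(c("H", "E", "C"), N, TRUE))
  stack <- build_base_stack(seqA, seqB, cmi, annA, annB)
  expect_s3_class(stack, "feature_stack")
  expect_identical(names(stack), feature_names())
  for (f in names(stack)) {
    expect_identical(dim(stack[[f]]), c(M, N))
    expect_true(all(stack[[f]] >= 0 & stack[[f]] <= 1), info = f)
  }
  # recomposition oracle: RSA slot equals scaling the outer product directly
  expect_equal(stack$RSA, minmax_scale(rsa_pair(annA$rsa, annB$rsa)))
  expect_error(build_base_stack(seqA, seqB, cmi[, -1], annA, annB), "cmi")
  expect_error(build_base_stack(seqA, seqB, cmi, annB, annB), "annA")
})

test_that("feature stacks round-trip through long-format TSV", {
  case <- make_synthetic_case(31, M = 8, N = 7, n_sequences = 40)
  f <- tempfile(fileext = ".tsv")
  write_feature_stack(case$stack, f)
  back <- read_feature_stack(f)
  expect_identical(names(back), names(case$stack))
  for (nm in names(back))
    expect_equal(back[[nm]], case$stack[[nm]], tolerance = 1e-9)
  expect_equal(attr(back, "kernel")$size, 3L)
})
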