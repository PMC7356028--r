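# Base pairwise feature matrices: physicochemical compatibility, solvent
# accessibility, secondary structure, contact potentials.

# Kyte-Doolittle hydropathy
.KD_HYDROPATHY <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
                    H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
                    P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7,
                    V = 4.2, W = -0.9, Y = -1.3)

# Formal charge class at physiological pH
.CHARGE <- c(A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 1, I = 0,
             K = 1, L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0,
             T = 0, V = 0, W = 0, Y = 0)

# Residue volumes (A^3), Zamyatnin-style consensus values
.VOLUME <- c(A = 88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9,
             G = 60.1, H = 153.2, I = 166.7, K = 168.6, L = 166.7,
             M = 162.9, N = 114.1, P = 112.7, Q = 143.8, R = 173.4,
             S = 89.0, T = 116.1, V = 140.0, W = 227.8, Y = 193.6)

#' Default 20x20 pairwise property tables
#'
#' The published compatibility and contact-potential tables are not
#' redistributed here; instead this generator derives symmetric stand-ins
#' from standard scalar residue scales, and [read_property_table()] lets
#' users drop in the literature tables as plain 20x20 TSV files. The
#' derivations:
#' \itemize{
#'   \item CCM (charge): `-q(a) * q(b)` — opposite charges score highest.
#'   \item HCM (hydropathy): `-|h(a) - h(b)|` with Kyte-Doolittle `h` —
#'     like-with-like is compatible.
#'   \item SCM (size): `-|v(a) - v(b)|` with residue volume `v`.
#'   \item CP / CPE / CPB (contact potentials, synthetic stand-ins):
#'     additive, multiplicative and min-combined functions of normalized
#'     hydropathy, mimicking the hydrophobic-driven structure of
#'     knowledge-based contact energies for all, exposed and buried
#'     residues. Mutually non-affine so they stay distinct after scaling.
#' }
#' All tables are symmetric and complete over the 20 standard residues;
#' downstream min-max scaling makes their absolute scale immaterial.
#'
#' @return Named list of six 20x20 matrices: CCM, HCM, SCM, CP, CPE, CPB.
#' @export
default_property_tables <- function() {
  h <- .KD_HYDROPATHY[AA_LETTERS]
  q <- .CHARGE[AA_LETTERS]
  v <- .VOLUME[AA_LETTERS]
  hn <- (h - min(h)) / (max(h) - min(h))
  dimn <- list(AA_LETTERS, AA_LETTERS)
  mk <- function(m) { dimnames(m) <- dimn; m }
  list(
    CCM = mk(-outer(q, q)),
    HCM = mk(-abs(outer(h, h, "-"))),
    SCM = mk(-abs(outer(v, v, "-"))),
    CP  = mk(-outer(hn, hn, "+")),
    CPE = mk(-outer(hn, hn, "*")),
    CPB = mk(-outer(hn, hn, pmin))
  )
}

#' Read a 20x20 property table from TSV
#'
#' Expected format: tab-separated, first column and header row are the 20
#' residue letters. The table must be complete and symmetric.
#'
#' @param path TSV path.
#' @return 20x20 numeric matrix with residue-letter dimnames.
#' @export
read_property_table <- function(path) {
  df <- read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (!all(AA_LETTERS %in% rownames(m)) || !all(AA_LETTERS %in% colnames(m)))
    stop_ppiface("property table %s does not cover the 20 standard residues",
                 path)
  m <- m[AA_LETTERS, AA_LETTERS]
  if (max(abs(m - t(m))) > 1e-8)
    stop_ppiface("property table %s is not symmetric", path)
  m
}

#' All-vs-all matrix from a 20x20 property table
#'
#' @param seqA,seqB gap-free sequences (strings) over the standard residues.
#' @param table symmetric 20x20 matrix with residue-letter dimnames.
#' @return M x N matrix with `out[i, j] = table[seqA[i], seqB[j]]`.
#' @export
pairwise_from_table <- function(seqA, seqB, table) {
  a <- strsplit(seqA, "", fixed = TRUE)[[1L]]
  b <- strsplit(seqB, "", fixed = TRUE)[[1L]]
  missA <- !(a %in% rownames(table))
  if (any(missA))
    stop_ppiface("residue '%s' at A position %d missing from table",
                 a[which(missA)[1L]], which(missA)[1L])
  missB <- !(b %in% colnames(table))
  if (any(missB))
    stop_ppiface("residue '%s' at B position %d missing from table",
                 b[which(missB)[1L]], which(missB)[1L])
  table[a, b, drop = FALSE]
}

#' Pairwise solvent-accessibility product
#'
#' @param rsaA,rsaB per-residue relative solvent accessibility in `[0, 1]`.
#' @return Outer product matrix; a buried residue (RSA 0) zeroes its whole
#'   row or column.
#' @export
rsa_pair <- function(rsaA, rsaB) {
  if (any(rsaA < 0) || any(rsaB < 0)) stop_ppiface("negative RSA value")
  if (any(rsaA > 1) || any(rsaB > 1)) stop_ppiface("RSA value above 1")
  outer(rsaA, rsaB)
}

#' Default secondary-structure pair ranks
#'
#' Naive multiplication of class codes would rank helix-helix pairs lowest,
#' so the 6 unordered class pairs get occurrence-based ranks instead. The
#' default ordering (least to most frequent at interfaces) is a documented
#' stand-in — loop-rich contacts most common, sheet-sheet least — used when
#' no training labels are available; [learn_ssp_ranks()] replaces it with
#' ranks learned from data.
#'
#' @return Named numeric vector over the 6 keys `"H-H"`, `"E-H"`, `"C-H"`,
#'   `"E-E"`, `"C-E"`, `"C-C"`, values `1/6 .. 1`.
#' @export
default_ssp_ranks <- function() {
  order_least_to_most <- c("E-E", "E-H", "H-H", "C-E", "C-H", "C-C")
  setNames(seq_along(order_least_to_most) / 6, order_least_to_most)
}

#' Learn secondary-structure pair ranks from labeled pairs
#'
#' Counts the 6 unordered class combinations among positive residue pairs
#' and ranks them by occurrence (most frequent = 1.0, scaled by 1/6).
#' Ties are broken by the fixed combo order, so the result is deterministic.
#'
#' @param sspA,sspB per-residue classes (`"H"`, `"E"`, `"C"`) of the two
#'   proteins of one or more complexes (lists of vectors, or vectors for a
#'   single complex).
#' @param positives data.frame(s) with columns `i`, `j` of positive pairs.
#' @return Named numeric vector like [default_ssp_ranks()].
#' @export
learn_ssp_ranks <- function(sspA, sspB, positives) {
  if (!is.list(sspA) || is.data.frame(sspA)) {
    sspA <- list(sspA); sspB <- list(sspB); positives <- list(positives)
  }
  keys <- .ssp_combo_keys()
  counts <- setNames(numeric(6), keys)
  for (k in seq_along(sspA)) {
    pos <- positives[[k]]
    if (nrow(pos) == 0L) next
    kk <- .ssp_key(sspA[[k]][pos$i], sspB[[k]][pos$j])
    tab <- table(kk)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  ord <- order(counts, match(names(counts), keys))    # ascending occurrence
  setNames(seq_len(6) / 6, names(counts)[ord])
}

#' Pairwise secondary-structure rank matrix
#'
#' @param sspA,sspB per-residue classes (`"H"`, `"E"`, `"C"`).
#' @param ranks rank table from [default_ssp_ranks()] or
#'   [learn_ssp_ranks()].
#' @return M x N matrix of the unordered-pair rank values (at most 6
#'   distinct values).
#' @export
ssp_pair <- function(sspA, sspB, ranks = default_ssp_ranks()) {
  bad <- setdiff(unique(c(sspA, sspB)), SSP_CLASSES)
  if (length(bad))
    stop_ppiface("unknown secondary-structure class: %s",
                 paste(bad, collapse = ","))
  keys <- outer(sspA, sspB, .ssp_key)
  miss <- setdiff(unique(as.vector(keys)), names(ranks))
  if (length(miss))
    stop_ppiface("rank table missing combination(s): %s",
                 paste(miss, collapse = ","))
  matrix(ranks[keys], nrow = length(sspA))
}

#' Min-max scale a matrix to [0, 1]
#'
#' `(x - min) / (max - min)`; a constant matrix maps to all zeros (fixed
#' convention for the degenerate case). Scaling is idempotent and
#' preserves argmax/argmin positions.
#'
#' @param m numeric matrix.
#' @return Matrix of the same shape with entries in `[0, 1]`.
#' @export
minmax_scale <- function(m) {
  r <- range(m)
  if (!all(is.finite(r))) stop_ppiface("non-finite values in matrix")
  if (r[1L] == r[2L]) return(matrix(0, nrow(m), ncol(m)))
  (m - r[1L]) / (r[2L] - r[1L])
}

#' Read a per-residue annotation table
#'
#' Tab-separated columns: `index` (1-based), `aa`, `rsa` (0-1), `ssp`
#' (H/E/C; G,I map to H; B to E; and C,S,T,L,`-` to C, covering common
#' predictor outputs).
#'
#' @param path TSV path.
#' @return List with `rsa`, `ssp`, `aa`, `length` (class
#'   `residue_annotations`).
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("index", "aa", "rsa", "ssp")
  if (!all(need %in% names(df)))
    stop_ppiface("annotation file %s must have columns %s", path,
                 paste(need, collapse = ", "))
  df <- df[order(df$index), ]
  if (!identical(as.integer(df$index), seq_len(nrow(df))))
    stop_ppiface("annotation indices in %s are not contiguous 1..n", path)
  residue_annotations(df$rsa, df$ssp, aa = df$aa)
}

#' Construct per-residue annotations
#'
#' @param rsa numeric vector in `[0, 1]`.
#' @param ssp character vector of classes; common 8-class codes are mapped
#'   to the 3 classes H/E/C.
#' @param aa optional residue letters.
#' @return A `residue_annotations` object.
#' @export
residue_annotations <- function(rsa, ssp, aa = NULL) {
  ssp <- toupper(as.character(ssp))
  map <- c(H = "H", G = "H", I = "H", E = "E", B = "E",
           C = "C", S = "C", T = "C", L = "C", "-" = "C")
  unknown <- setdiff(unique(ssp), names(map))
  if (length(unknown))
    stop_ppiface("unknown secondary-structure code(s): %s",
                 paste(unknown, collapse = ","))
  ssp <- unname(map[ssp])
  if (length(rsa) != length(ssp))
    stop_ppiface("rsa and ssp lengths differ (%d vs %d)",
                 length(rsa), length(ssp))
  if (any(!is.finite(rsa)) || any(rsa < 0) || any(rsa > 1))
    stop_ppiface("rsa values must lie in [0, 1]")
  structure(list(rsa = as.numeric(rsa), ssp = ssp, aa = aa,
                 length = length(rsa)),
            class = "residue_annotations")
}

#' Write annotations as TSV
#' @param ann a `residue_annotations` object.
#' @param path output path.
#' @param aa residue letters if not stored in `ann`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path, aa = ann$aa) {
  df <- data.frame(index = seq_len(ann$length),
                   aa = aa %||% rep("X", ann$length),
                   rsa = ann$rsa, ssp = ann$ssp)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble the nine base feature matrices
#'
#' Builds the canonical 9-matrix stack (CMI, CCM, HCM, SCM, RSA, SSP, CP,
#' CPE, CPB), each min-max scaled to `[0, 1]` per matrix.
#'
#' @param seqA,seqB gap-free sequences of proteins A and B.
#' @param cmi M x N co-evolution matrix ([cmi_matrix()]).
#' @param annA,annB `residue_annotations` for A and B.
#' @param tables list of 20x20 tables (names CCM, HCM, SCM, CP, CPE, CPB);
#'   default [default_property_tables()].
#' @param ranks secondary-structure rank table.
#' @return A `feature_stack`: named list of nine M x N matrices with
#'   attributes `M`, `N`.
#' @export
build_base_stack <- function(seqA, seqB, cmi, annA, annB,
                             tables = default_property_tables(),
                             ranks = default_ssp_ranks()) {
  M <- nchar(seqA); N <- nchar(seqB)
  if (!identical(dim(unclass(cmi)), c(M, N)))
    stop_ppiface("cmi matrix is %dx%d but sequences imply %dx%d",
                 nrow(cmi), ncol(cmi), M, N)
  if (annA$length != M)
    stop_ppiface("annA has %d residues, seqA has %d", annA$length, M)
  if (annB$length != N)
    stop_ppiface("annB has %d residues, seqB has %d", annB$length, N)
  miss <- setdiff(c("CCM", "HCM", "SCM", "CP", "CPE", "CPB"), names(tables))
  if (length(miss))
    stop_ppiface("property tables missing: %s", paste(miss, collapse = ","))
  raw <- list(
    CMI = matrix(as.numeric(unclass(cmi)), M, N),
    CCM = pairwise_from_table(seqA, seqB, tables$CCM),
    HCM = pairwise_from_table(seqA, seqB, tables$HCM),
    SCM = pairwise_from_table(seqA, seqB, tables$SCM),
    RSA = rsa_pair(annA$rsa, annB$rsa),
    SSP = ssp_pair(annA$ssp, annB$ssp, ranks),
    CP  = pairwise_from_table(seqA, seqB, tables$CP),
    CPE = pairwise_from_table(seqA, seqB, tables$CPE),
    CPB = pairwise_from_table(seqA, seqB, tables$CPB)
  )
  stack <- lapply(raw, function(m) unname(minmax_scale(m)))
  structure(stack, M = M, N = N, class = "feature_stack")
}

#' Serialize a feature stack as long-format TSV
#'
#' Columns: i, j, feature, value.
#'
#' @param stack a `feature_stack`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_stack <- function(stack, path) {
  M <- attr(stack, "M"); N <- attr(stack, "N")
  long <- do.call(rbind, lapply(names(stack), function(f) {
    data.frame(i = rep(seq_len(M), times = N),
               j = rep(seq_len(N), each = M),
               feature = f, value = as.vector(stack[[f]]))
  }))
  kern <- attr(stack, "kernel")
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(kern))
    writeLines(jsonlite::toJSON(kern, auto_unbox = TRUE),
               paste0(path, ".kernel.json"))
  invisible(path)
}

#' Read a long-format feature stack TSV
#'
#' @param path TSV written by [write_feature_stack()].
#' @return A `feature_stack`.
#' @export
read_feature_stack <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  M <- max(df$i); N <- max(df$j)
  feats <- unique(df$feature)
  stack <- lapply(feats, function(f) {
    sub <- df[df$feature == f, ]
    m <- matrix(NA_real_, M, N)
    m[cbind(sub$i, sub$j)] <- sub$value
    m
  })
  names(stack) <- feats
  kf <- paste0(path, ".kernel.json")
  out <- structure(stack, M = M, N = N, class = "feature_stack")
  if (file.exists(kf))
    attr(out, "kernel") <- jsonlite::fromJSON(readLines(kf, warn = FALSE))
  out
}
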