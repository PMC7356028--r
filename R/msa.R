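# Alignment input, validation, species matching, concatenation and
# numeric encoding.

#' Construct a validated alignment object
#'
#' An alignment is a set of equal-length amino-acid sequences (rows) with
#' unique identifiers. Gap characters `-` and `.` are normalized to `-`;
#' letters are uppercased. Only the 20 standard one-letter residue codes
#' plus the gap symbol are allowed.
#'
#' @param ids character vector of row identifiers (FASTA headers).
#' @param seqs character vector of aligned sequences, same length as `ids`.
#' @param name optional alignment label used in messages.
#' @return An object of class `aa_alignment`: a list with elements
#'   `ids`, `seqs`, `width`, `name`.
#' @export
new_alignment <- function(ids, seqs, name = "alignment") {
  if (length(ids) != length(seqs))
    stop_ppiface("ids and seqs lengths differ (%d vs %d)",
                 length(ids), length(seqs))
  if (length(seqs) == 0L) stop_ppiface("alignment '%s' is empty", name)
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  w <- nchar(seqs)
  if (length(unique(w)) != 1L)
    stop_ppiface("ragged alignment '%s': row lengths %s", name,
                 paste(unique(w), collapse = ", "))
  ok <- paste0("^[", paste(AA_LETTERS, collapse = ""), "-]*$")
  bad <- !grepl(ok, seqs)
  if (any(bad))
    stop_ppiface("alignment '%s': record '%s' contains non-standard letters",
                 name, ids[which(bad)[1L]])
  dup <- duplicated(ids)
  if (any(dup)) {
    warning(sprintf("alignment '%s': duplicate ids (%s); keeping first occurrence",
                    name, paste(unique(ids[dup]), collapse = ", ")),
            call. = FALSE)
    ids <- ids[!dup]
    seqs <- seqs[!dup]
  }
  structure(list(ids = ids, seqs = seqs, width = w[1L], name = name),
            class = "aa_alignment")
}

#' Read an aligned FASTA file
#'
#' @param path path to an aligned FASTA file.
#' @param name optional label; defaults to the file name.
#' @return An `aa_alignment`.
#' @export
read_alignment <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop_ppiface("alignment file not found: %s", path)
  x <- Biostrings::readBStringSet(path)
  new_alignment(names(x), as.character(x), name = name)
}

#' Write an alignment as FASTA
#'
#' @param aln an `aa_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  x <- Biostrings::BStringSet(setNames(aln$seqs, aln$ids))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("<aa_alignment '%s'> %d rows x %d columns\n",
              x$name, length(x$ids), x$width))
  invisible(x)
}

#' Remove rows with low identity to a reference row
#'
#' Pairwise identity is computed over the non-gap columns of the reference:
#' matches at those columns divided by their count. The reference row is
#' always retained and row order is preserved.
#'
#' @param aln an `aa_alignment`.
#' @param reference_row index of the reference row (default 1).
#' @param min_identity minimum identity fraction (default 0.25).
#' @return Filtered `aa_alignment`.
#' @export
filter_low_identity <- function(aln, reference_row = 1L, min_identity = 0.25) {
  stopifnot(inherits(aln, "aa_alignment"))
  n <- length(aln$ids)
  if (!is_count(reference_row) || reference_row > n)
    stop_ppiface("reference_row %s out of range 1..%d",
                 format(reference_row), n)
  chars <- strsplit(aln$seqs, "", fixed = TRUE)
  ref <- chars[[reference_row]]
  idx <- which(ref != GAP_CHAR)
  if (length(idx) == 0L)
    stop_ppiface("reference row is all gaps")
  ident <- vapply(chars, function(s) mean(s[idx] == ref[idx]), numeric(1))
  keep <- ident >= min_identity
  keep[reference_row] <- TRUE
  if (sum(keep) == 1L && n > 1L)
    warning("all non-reference rows fell below the identity threshold; returning reference only",
            call. = FALSE)
  new_alignment(aln$ids[keep], aln$seqs[keep], name = aln$name)
}

#' Parse species keys from alignment row identifiers
#'
#' The species token is extracted with a single-capture-group regular
#' expression applied to each id. The default takes the first
#' whitespace-delimited word, which suits headers written as
#' `species_name optional description`.
#'
#' @param aln an `aa_alignment`.
#' @param species_regex regex with one capture group.
#' @return Character vector of species keys, one per row.
#' @export
species_keys <- function(aln, species_regex = "^(\\S+)") {
  m <- regmatches(aln$ids, regexec(species_regex, aln$ids))
  vapply(m, function(g) if (length(g) >= 2L) g[2L] else NA_character_,
         character(1))
}

#' Concatenate two alignments by shared species
#'
#' Rows are matched on a species key parsed from the headers; only species
#' present in both alignments are kept (intersection, in the order of
#' alignment A). Each output row is the protein-A row followed by the
#' protein-B row for the same species, so columns `1..lenA` come from A and
#' `lenA+1..lenA+lenB` from B.
#'
#' @param alnA,alnB `aa_alignment` objects.
#' @param species_regex passed to [species_keys()].
#' @return A `concat_alignment` (also an `aa_alignment`) with extra fields
#'   `lenA`, `lenB` and `boundary` (= `lenA`, the count of A columns).
#' @export
concatenate_by_species <- function(alnA, alnB, species_regex = "^(\\S+)") {
  stopifnot(inherits(alnA, "aa_alignment"), inherits(alnB, "aa_alignment"))
  spA <- species_keys(alnA, species_regex)
  spB <- species_keys(alnB, species_regex)
  common <- intersect(spA, spB)
  common <- common[!is.na(common)]
  if (length(common) == 0L) stop_ppiface("no shared species between alignments")
  ia <- match(common, spA)
  ib <- match(common, spB)
  out <- new_alignment(common,
                       paste0(alnA$seqs[ia], alnB$seqs[ib]),
                       name = paste0(alnA$name, "+", alnB$name))
  out$lenA <- alnA$width
  out$lenB <- alnB$width
  out$boundary <- alnA$width
  class(out) <- c("concat_alignment", class(out))
  out
}

#' Encode an alignment as an integer matrix
#'
#' Uses the fixed code table of [aa_code_table()]: gap = 0, residues 1..20
#' alphabetically. The co-evolution statistic is invariant to the choice of
#' bijection.
#'
#' @param aln an `aa_alignment` (or `concat_alignment`).
#' @return An `encoded_alignment`: integer matrix (rows = sequences,
#'   columns = alignment columns) with attributes `ids`, `code_table`, and,
#'   for concatenated input, `boundary`.
#' @export
encode_alignment <- function(aln) {
  stopifnot(inherits(aln, "aa_alignment"))
  code <- aa_code_table()
  chars <- strsplit(aln$seqs, "", fixed = TRUE)
  m <- do.call(rbind, lapply(chars, function(s) unname(code[s])))
  storage.mode(m) <- "integer"
  attr(m, "ids") <- aln$ids
  attr(m, "code_table") <- code
  if (inherits(aln, "concat_alignment")) attr(m, "boundary") <- aln$boundary
  attr(m, "name") <- aln$name
  class(m) <- c("encoded_alignment", class(m))
  m
}

#' Decode an encoded alignment back to letters
#'
#' @param enc an `encoded_alignment`.
#' @return An `aa_alignment`; `decode_alignment(encode_alignment(x))`
#'   reproduces `x` row for row.
#' @export
decode_alignment <- function(enc) {
  stopifnot(inherits(enc, "encoded_alignment"))
  code <- attr(enc, "code_table")
  letters21 <- names(code)[order(code)]
  m <- unclass(enc)
  seqs <- apply(m, 1L, function(r) paste(letters21[r + 1L], collapse = ""))
  new_alignment(attr(enc, "ids"), seqs,
                name = attr(enc, "name") %||% "alignment")
}
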