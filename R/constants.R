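# Shared vocabulary: amino-acid alphabet, numeric codes, feature names.

#' The 20 standard amino-acid one-letter codes, alphabetical
#'
#' Order fixes the numeric encoding used throughout the package
#' (gap = 0, residues = 1..20 in this order).
#' @export
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname AA_LETTERS
#' @export
GAP_CHAR <- "-"

#' Numeric code table for alignment encoding
#'
#' Gap maps to 0, the 20 standard residues to 1..20 in alphabetical order
#' of one-letter code. Any bijection is equivalent for the co-evolution
#' statistic (it is invariant to symbol relabeling); a fixed table makes
#' encode/decode a deterministic round trip.
#'
#' @return Named integer vector of length 21.
#' @export
aa_code_table <- function() {
  setNames(0:20, c(GAP_CHAR, AA_LETTERS))
}

#' Canonical feature names
#'
#' The nine base pairwise features: co-evolution (CMI), charge (CCM),
#' hydropathy (HCM) and size (SCM) compatibility, solvent-accessibility
#' product (RSA), secondary-structure rank (SSP), and three contact
#' potentials (CP, CPE exposed, CPB buried). Environment counterparts are
#' prefixed with "E".
#'
#' @param environment if `TRUE`, return all 18 names (9 base + 9
#'   environment); otherwise the 9 base names.
#' @return Character vector of feature names in canonical order.
#' @export
feature_names <- function(environment = FALSE) {
  base <- c("CMI", "CCM", "HCM", "SCM", "RSA", "SSP", "CP", "CPE", "CPB")
  if (environment) c(base, paste0("E", base)) else base
}

# Secondary-structure classes: H = helix (alpha), E = sheet (beta),
# C = coil/loop (l).
SSP_CLASSES <- c("H", "E", "C")

.ssp_combo_keys <- function() {
  combos <- c("H-H", "E-H", "C-H", "E-E", "C-E", "C-C")
  combos
}

.ssp_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "-"), paste(b, a, sep = "-"))
}
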