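# Amino-acid property table driving simulated effect sizes and the
# property-correlation analyses.
#
# Default table sources:
#   * mw_g_mol: free amino acid molecular weight (g/mol).
#   * volume_A3: residue volume in cubic angstroms (Zamyatnin, 1972,
#     Prog. Biophys. Mol. Biol. 24:107-123).
#   * hydrophobicity_ph7: normalized side-chain hydrophobicity index at
#     pH 7 (Monera et al., 1995, J. Pept. Sci. 1:319-329; Phe = 100,
#     Gly = 0).

AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

#' Load an amino-acid property table
#'
#' Reads a TSV with columns `code`, `name`, `mw_g_mol`, `volume_A3` and
#' `hydrophobicity_ph7`, and validates it: exactly the 20 canonical amino
#' acids, unique one-letter codes, positive molecular weights and volumes.
#'
#' @param path Path to a TSV file. Defaults to the table shipped with the
#'   package (see source citations in the package vignette).
#' @return A `data.frame` of class `aa_properties` with one row per amino
#'   acid, ordered by one-letter code.
#' @export
load_aa_properties <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_properties.tsv", package = "trnacharge",
                        mustWork = TRUE)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  required <- c("code", "name", "mw_g_mol", "volume_A3", "hydrophobicity_ph7")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stopf("property table is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tab$code)) {
    stopf("duplicate amino-acid code(s): %s",
          paste(unique(tab$code[duplicated(tab$code)]), collapse = ", "))
  }
  if (nrow(tab) != 20 || !setequal(tab$code, AA_CODES)) {
    stopf("property table must contain exactly the 20 canonical amino acids")
  }
  if (any(tab$mw_g_mol <= 0) || any(tab$volume_A3 <= 0)) {
    stopf("molecular weights and side-chain volumes must be positive")
  }
  tab <- tab[match(AA_CODES, tab$code), , drop = FALSE]
  rownames(tab) <- tab$code
  class(tab) <- c("aa_properties", "data.frame")
  tab
}

#' Default amino-acid property table
#'
#' @return The validated table shipped with the package.
#' @export
aa_properties <- function() load_aa_properties()
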