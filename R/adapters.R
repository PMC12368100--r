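# Adapter sets for charged/uncharged capture.
#
# The 3' adapters carry unique sequences so that charged and uncharged
# molecules can in principle be told apart by alignment, but their first
# three nucleotides are constrained to "GGC" so that the six-nucleotide
# classifier window (CCA + GGC) is identical across isodecoders and across
# both 3' adapters. The 5' adapter comes in two chemistries: an all-RNA
# version ("legacy_rna_5p", associated with elevated pore blocking for Asn-
# and Cys-charged tRNAs) and a DNA/RNA hybrid ("hybrid_5p") with five
# ribonucleotides at its 3' terminus. Sequences are represented as plain
# characters; T and U are preserved as given and compared as distinct.
#
# The shipped default adapter sequences are synthetic placeholders obeying
# the GGC constraint, not the oligonucleotides used in any published
# protocol.

#' Construct and validate an adapter set
#'
#' @param charged_3p 3' adapter ligated to aminoacylated tRNA.
#' @param uncharged_3p 3' adapter ligated to deacylated tRNA.
#' @param universal_5p Universal 5' adapter (plain characters; may mix T/U to
#'   represent a DNA/RNA hybrid).
#' @return A list of class `adapter_set`.
#' @export
adapter_set <- function(charged_3p, uncharged_3p, universal_5p) {
  for (s in list(charged_3p, uncharged_3p, universal_5p)) {
    if (!is.character(s) || length(s) != 1 || nchar(s) == 0) {
      stopf("adapter sequences must be non-empty character scalars")
    }
  }
  if (identical(charged_3p, uncharged_3p)) {
    stopf("charged and uncharged 3' adapters must differ")
  }
  if (substr(charged_3p, 1, 3) != "GGC" || substr(uncharged_3p, 1, 3) != "GGC") {
    stopf("both 3' adapters must begin with 'GGC' so the classifier window (CCAGGC) is library-invariant")
  }
  structure(list(charged_3p = charged_3p,
                 uncharged_3p = uncharged_3p,
                 universal_5p = universal_5p),
            class = "adapter_set")
}

#' Default adapter set
#'
#' @param mode `"hybrid_5p"` (DNA/RNA hybrid 5' adapter, default) or
#'   `"legacy_rna_5p"` (all-RNA 5' adapter).
#' @return An `adapter_set`.
#' @export
default_adapters <- function(mode = c("hybrid_5p", "legacy_rna_5p")) {
  mode <- match.arg(mode)
  u5 <- switch(mode,
    legacy_rna_5p = "GCUAUGCGAUCUCGGAACCAUCAG",
    hybrid_5p     = "GCTATGCGATCTCGGAACCAUCAG")  # DNA body, 5 ribo nt at 3' end
  adapter_set(
    charged_3p   = "GGCUUAGCAAUCCGGAUCGUACGA",
    uncharged_3p = "GGCAAUCGGAUUCCUAGGCAUUCG",
    universal_5p = u5)
}
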