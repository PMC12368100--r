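# Extended reference construction.
#
# Layout: 5' adapter + tRNA body + CCA (+ optional inserted T) + 3' adapter.
# Coordinates are 0-based, half-open throughout. The "anchor" is the index of
# the first base 3' of the CCA tail: the first 3' adapter base in standard
# mode, or the inserted T in pairwise mode. The charge site is the bond
# between index anchor-1 (the CCA's final A) and the anchor; per-position
# effects are indexed by signed offset from the anchor (offset 0 = anchor).
# The dwell probe sits at offset +9 (motor-protein contact).

# Canonical anticodon per amino acid used for default isodecoder names.
AA_ANTICODON <- c(A = "AGC", R = "ACG", N = "GUU", D = "GUC", C = "GCA",
                  Q = "UUG", E = "UUC", G = "GCC", H = "GUG", I = "AAU",
                  L = "CAA", K = "CUU", M = "CAU", F = "GAA", P = "UGG",
                  S = "AGA", T = "AGU", W = "CCA", Y = "GUA", V = "AAC")

#' Construct a tRNA isodecoder record
#'
#' @param name Isodecoder label, e.g. `"Gly-GCC"`.
#' @param body Mature tRNA sequence excluding the 3'-terminal CCA
#'   (alphabet A/C/G/U).
#' @return A list of class `trna_isodecoder`.
#' @export
trna_isodecoder <- function(name, body) {
  if (!is.character(body) || length(body) != 1 || nchar(body) == 0) {
    stopf("isodecoder body must be a non-empty sequence")
  }
  if (grepl("[^ACGU]", body)) {
    stopf("isodecoder body must use the alphabet {A,C,G,U}")
  }
  structure(list(name = name, body = body), class = "trna_isodecoder")
}

#' Generate a panel of synthetic tRNA isodecoder bodies
#'
#' Deterministically generates random tRNA-like bodies (uniform A/C/G/U,
#' fixed length, not ending in CCA), one per amino acid, named by the
#' three-letter amino-acid code and its canonical anticodon (e.g.
#' `"Gly-GCC"`). These stand in for mature tRNA sequences in simulations;
#' only the invariant CCA + adapter context matters for the classifier
#' window, so the bodies carry no cloverleaf structure.
#'
#' @param aa_table Amino-acid property table (defines the panel membership).
#' @param length Body length in nucleotides (default 73).
#' @param seed Integer seed.
#' @return Named list of `trna_isodecoder` objects, keyed by one-letter code.
#' @export
synthetic_isodecoders <- function(aa_table = aa_properties(), length = 73,
                                  seed = 101) {
  codes <- aa_table$code
  out <- vector("list", length(codes))
  names(out) <- codes
  for (i in seq_along(codes)) {
    code <- codes[i]
    body <- with_local_seed(derive_seed(seed, i), {
      repeat {
        b <- paste(sample(c("A", "C", "G", "U"), length, replace = TRUE),
                   collapse = "")
        if (substr(b, length - 2, length) != "CCA") break
      }
      b
    })
    out[[code]] <- trna_isodecoder(
      name = paste0(AA_THREE[[code]], "-", AA_ANTICODON[[code]]),
      body = body)
  }
  out
}

#' Build an extended reference for an adapter-ligated tRNA
#'
#' Concatenates 5' adapter + body + CCA (+ inserted `T` in pairwise mode) +
#' the requested 3' adapter, and records the anchor coordinate. In standard
#' mode the six-mer at `[anchor-3, anchor+3)` is `CCAGGC`; in pairwise mode
#' the four-mer at `[anchor-3, anchor+1)` is `CCAT` with the anchor pointing
#' at the inserted T.
#'
#' @param isodecoder A `trna_isodecoder`.
#' @param adapters An `adapter_set`.
#' @param which_3p `"charged"` or `"uncharged"`: which unique 3' adapter to
#'   append.
#' @param mode `"standard"` or `"pairwise_insert_t"`.
#' @return A list of class `extended_reference` with fields `name`,
#'   `sequence`, `anchor` (0-based), `mode`, `which_3p`,
#'   `dwell_probe_offset` (+9) and `n5` (5' adapter length).
#' @export
build_extended_reference <- function(isodecoder, adapters,
                                     which_3p = c("charged", "uncharged"),
                                     mode = c("standard", "pairwise_insert_t")) {
  which_3p <- match.arg(which_3p)
  mode <- match.arg(mode)
  if (!inherits(isodecoder, "trna_isodecoder")) {
    isodecoder <- trna_isodecoder(isodecoder$name, isodecoder$body)
  }
  if (!inherits(adapters, "adapter_set")) {
    adapters <- adapter_set(adapters$charged_3p, adapters$uncharged_3p,
                            adapters$universal_5p)
  }
  body <- isodecoder$body
  nb <- nchar(body)
  if (substr(body, nb - 2, nb) == "CCA") {
    warnf("isodecoder '%s' body already ends in CCA; possible double-CCA construct",
          isodecoder$name)
  }
  a3 <- switch(which_3p, charged = adapters$charged_3p,
               uncharged = adapters$uncharged_3p)
  insert <- if (mode == "pairwise_insert_t") "T" else ""
  seq <- paste0(adapters$universal_5p, body, "CCA", insert, a3)
  anchor <- nchar(adapters$universal_5p) + nb + 3L  # 0-based
  ref <- structure(list(
    name = paste0(isodecoder$name, "_", which_3p),
    sequence = seq,
    anchor = as.integer(anchor),
    mode = mode,
    which_3p = which_3p,
    dwell_probe_offset = 9L,
    n5 = nchar(adapters$universal_5p)
  ), class = "extended_reference")
  validate_extended_reference(ref)
  ref
}

validate_extended_reference <- function(ref) {
  # substr() is 1-based; ref$anchor is 0-based.
  a <- ref$anchor
  if (substr(ref$sequence, a - 2, a) != "CCA") {
    stopf("reference '%s': sequence[anchor-3, anchor) must be 'CCA'", ref$name)
  }
  win <- substr(ref$sequence, a - 2, a + 3)
  if (ref$mode == "standard" && win != "CCAGGC") {
    stopf("reference '%s': standard-mode window must be 'CCAGGC', got '%s'",
          ref$name, win)
  }
  if (ref$mode == "pairwise_insert_t" &&
      substr(ref$sequence, a - 2, a + 1) != "CCAT") {
    stopf("reference '%s': pairwise-mode motif must be 'CCAT'", ref$name)
  }
  if (a + 9 >= nchar(ref$sequence)) {
    stopf("reference '%s': 3' adapter too short to cover the +9 dwell probe",
          ref$name)
  }
  invisible(ref)
}

#' Reference window sequence around the anchor
#'
#' @param ref An `extended_reference`.
#' @param from,to Signed offsets from the anchor (0-based, inclusive).
#' @return Character scalar.
#' @export
reference_window <- function(ref, from = -3, to = 2) {
  substr(ref$sequence, ref$anchor + from + 1, ref$anchor + to + 1)
}

#' Write extended references to FASTA
#'
#' Anchor coordinates and mode are stored in the FASTA description so that
#' `read_reference_fasta()` round-trips the full object.
#'
#' @param refs List of `extended_reference` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(refs, path) {
  if (inherits(refs, "extended_reference")) refs <- list(refs)
  nms <- vapply(refs, `[[`, "", "name")
  if (anyDuplicated(nms)) stopf("duplicate reference names: %s",
                                paste(unique(nms[duplicated(nms)]), collapse = ", "))
  seqs <- Biostrings::BStringSet(vapply(refs, `[[`, "", "sequence"))
  names(seqs) <- vapply(refs, function(r) {
    sprintf("%s anchor=%d mode=%s which=%s n5=%d", r$name, r$anchor, r$mode,
            r$which_3p %||% "charged", r$n5 %||% 0L)
  }, "")
  Biostrings::writeXStringSet(seqs, filepath = path, width = 80)
  invisible(path)
}

#' Read extended references from FASTA
#'
#' @param path FASTA path.
#' @return Named list of `extended_reference` objects. An empty file yields
#'   an empty list with a warning.
#' @export
read_reference_fasta <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (file.size(path) == 0) {
    warnf("empty FASTA file: %s", path)
    return(list())
  }
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  parse_field <- function(h, key, default = NA_character_) {
    m <- regmatches(h, regexec(paste0(key, "=([^ ]+)"), h))[[1]]
    if (length(m) == 2) m[2] else default
  }
  refs <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    h <- headers[i]
    nm <- sub(" .*$", "", h)
    anchor <- suppressWarnings(as.integer(parse_field(h, "anchor")))
    if (is.na(anchor)) stopf("reference '%s' lacks an anchor= field", nm)
    ref <- structure(list(
      name = nm,
      sequence = as.character(seqs[[i]]),
      anchor = anchor,
      mode = parse_field(h, "mode", "standard"),
      which_3p = parse_field(h, "which", "charged"),
      dwell_probe_offset = 9L,
      n5 = suppressWarnings(as.integer(parse_field(h, "n5", "0")))
    ), class = "extended_reference")
    validate_extended_reference(ref)
    refs[[i]] <- ref
  }
  nms <- vapply(refs, `[[`, "", "name")
  if (anyDuplicated(nms)) stopf("duplicate reference names in FASTA: %s",
                                paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(refs) <- nms
  refs
}
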