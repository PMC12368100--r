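# Seeded k-mer current-level model.
#
# Expected pore current for a k-mer is a deterministic pseudo-random function
# of the k-mer and an integer seed, mapped into a plausible picoampere range.
# No attempt is made to mimic a real pore table: downstream operations only
# depend on relative distortions of the baseline, not on its exact shape.

#' Construct a k-mer current-level model
#'
#' @param k K-mer order (default 9, centered on the reported position).
#' @param noise_sd Within-position current standard deviation, pA.
#' @param sample_rate Samples per second (default 4000).
#' @param mean_speed Mean translocation speed, nt/s (default 130).
#' @param dwell_log_sd Log-scale SD of the log-normal dwell distribution.
#' @param seed Integer seed of the level function.
#' @param range Length-2 numeric, pA range of expected levels.
#' @return A list of class `level_model`.
#' @export
level_model <- function(k = 9, noise_sd = 2.5, sample_rate = 4000,
                        mean_speed = 130, dwell_log_sd = 0.35,
                        seed = 1234, range = c(60, 120)) {
  stopifnot(k >= 1, noise_sd > 0, sample_rate > 0, mean_speed > 0,
            dwell_log_sd >= 0, length(range) == 2, range[2] > range[1])
  structure(list(k = as.integer(k), noise_sd = noise_sd,
                 sample_rate = sample_rate, mean_speed = mean_speed,
                 dwell_log_sd = dwell_log_sd, seed = as.integer(seed),
                 range = range),
            class = "level_model")
}

#' Expected current level of k-mers
#'
#' Deterministic given the model seed; U and T are treated identically
#' (the pore reads the ribose-agnostic base identity).
#'
#' @param model A `level_model`.
#' @param kmers Character vector of k-mers.
#' @return Numeric vector of expected levels (pA).
#' @export
kmer_level <- function(model, kmers) {
  if (any(nchar(kmers) != model$k)) stopf("all k-mers must have length %d", model$k)
  digits <- chartr("ACGTUN", "012330", toupper(kmers))
  if (any(grepl("[^0-3]", digits))) stopf("k-mers must use the alphabet {A,C,G,T,U}")
  val <- vapply(digits, function(d) strtoi(d, base = 4L), 0, USE.NAMES = FALSE)
  u <- ((val * 2654435761 + as.double(model$seed) * 97531) %% 2147483647) / 2147483647
  model$range[1] + diff(model$range) * u
}

#' Per-position expected levels along a reference
#'
#' The k-mer reported at position i is centered on i (edges padded with 'A').
#'
#' @param model A `level_model`.
#' @param sequence Reference sequence (character scalar).
#' @return Numeric vector, one expected level per reference position.
#' @export
position_levels <- function(model, sequence) {
  n <- nchar(sequence)
  half <- (model$k - 1L) %/% 2L
  pad <- strrep("A", half)
  padded <- paste0(pad, sequence, strrep("A", model$k - 1L - half))
  kmers <- substring(padded, seq_len(n), seq_len(n) + model$k - 1L)
  kmer_level(model, kmers)
}
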