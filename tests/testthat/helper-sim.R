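# Shared fixtures, built in code.

# A small construct: 12 nt body, adapters long enough to cover the +9 probe.
tiny_adapters <- function() {
  adapter_set(charged_3p = "GGCUUAGCAAUCCG",
              uncharged_3p = "GGCAAUCGGAUUCC",
              universal_5p = "GCTATGCGAUCAG")
}

tiny_ref <- function(which_3p = "charged", mode = "standard",
                     body = "AUGCUUGGAACG") {
  build_extended_reference(trna_isodecoder("Gly-GCC", body),
                           tiny_adapters(), which_3p, mode)
}

# n simulated reads on one reference with explicit truth.
sim_reads <- function(ref, n, charged = FALSE, aa = NA_character_,
                      seed = 1, signal = "summary",
                      preset = "bio-default", model = level_model(),
                      effects = NULL) {
  if (is.null(effects)) {
    effects <- effect_profiles(preset, ref_length = nchar(ref$sequence))
  }
  truth <- list(isodecoder = "Gly-GCC", charged = charged, aa = aa)
  lapply(seq_len(n), function(i) {
    simulate_read(ref, truth, model, effects, seed = derive_seed(seed, i),
                  signal = signal, read_id = sprintf("tr%s_%05d", seed, i))
  })
}

# Minimal chunk stubs for split/weight arithmetic tests.
stub_chunks <- function(n, prefix = "s") {
  lapply(seq_len(n), function(i) {
    structure(list(read_id = paste0(prefix, i), anchor = 10L,
                   context_seq = "CCAGGC",
                   features = c(f1 = 0, f2 = 0), samples = NULL, label = NA),
              class = "signal_chunk")
  })
}

# A model stub emitting a fixed probability for any window chunk.
stub_model <- function(prob) {
  structure(list(intercept = stats::qlogis(prob),
                 coef = c(f1 = 0, f2 = 0),
                 config = classifier_config("window"),
                 seed = 1L, n_train = 0L),
            class = "charging_classifier")
}
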