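# Canned end-to-end experiments. These encode the package's standard
# evaluation designs so that tests, scripts and users run the same
# procedures:
#   * charging_experiment(): ground-truth charged + deacylated libraries,
#     80/20 read-level split, charging model, ML>199 calls, confusion
#     metrics on the held-out reads;
#   * pairwise_experiment(): 20 amino-acid panels on one shared synthetic
#     tRNA body (inserted-T references), all ordered pairwise models;
#   * panel_experiment(): per-amino-acid signal summaries (dwell at +9,
#     current difference at the charge site) against an uncharged control.

#' Emulate basecalls for every read of a simulated library
#'
#' @param lib A `sim_library`.
#' @param ... Passed to [emulate_basecalls()].
#' @param seed Master seed (per-read substreams are derived from it).
#' @return `data.frame` with `read_id`, `basecall`.
#' @export
emulate_library_basecalls <- function(lib, seed = 1, ...) {
  ref_names <- vapply(lib$refs, `[[`, "", "name")
  bc <- vapply(seq_along(lib$reads), function(i) {
    read <- lib$reads[[i]]
    ref <- lib$refs[[match(read$ref_name, ref_names)]]
    emulate_basecalls(read, ref, seed = derive_seed(seed, i), ...)
  }, "")
  data.frame(read_id = vapply(lib$reads, `[[`, "", "read_id"),
             basecall = bc, stringsAsFactors = FALSE)
}

#' Ground-truth charging classification experiment
#'
#' Simulates a fully charged and a fully deacylated library (the two
#' ground-truth library designs), splits reads 80/20, trains the charging
#' classifier on the training split and evaluates ML>cutoff calls on the
#' held-out reads.
#'
#' @param n_per_class Reads per library.
#' @param seed Master integer seed.
#' @param preset Effect preset (default `"bio-default"`).
#' @param split Training fraction.
#' @param cutoff ML call cutoff (default 199).
#' @param config Classifier configuration.
#' @param isodecoders Isodecoder panel (default: 20-amino-acid synthetic
#'   panel, cognate charging).
#' @param signal Signal retention mode.
#' @return List with `eval` (held-out `eval_report`), `F1`,
#'   `fp_rate_pct` (percent of truly uncharged held-out reads with score
#'   >= cutoff+1), `model`, `scores`, `truth`.
#' @export
charging_experiment <- function(n_per_class = 2000, seed = 1,
                                preset = "bio-default", split = 0.8,
                                cutoff = 199, config = classifier_config(),
                                isodecoders = NULL, signal = "summary") {
  spec_c <- library_spec(isodecoders = isodecoders, charged_fraction = 1,
                         n_reads = n_per_class, condition = "charged",
                         seed = derive_seed(seed, 1))
  spec_u <- library_spec(isodecoders = isodecoders, charged_fraction = 0,
                         n_reads = n_per_class, condition = "deacylated",
                         seed = derive_seed(seed, 2))
  lib_c <- simulate_library(spec_c, preset = preset, signal = signal)
  lib_u <- simulate_library(spec_u, preset = preset, signal = signal)
  ch_c <- extract_library_chunks(lib_c)
  ch_u <- extract_library_chunks(lib_u)
  ds <- make_training_dataset(ch_c, ch_u, split = split,
                              seed = derive_seed(seed, 3))
  model <- train_charging_model(ds$train, config, seed = derive_seed(seed, 4))
  scores <- score_reads(model, ds$test$chunks)
  calls <- classify_charging(scores, cutoff = cutoff)
  truth <- data.frame(read_id = scores$read_id,
                      charged = ds$test$labels == 1L,
                      stringsAsFactors = FALSE)
  ev <- evaluate_classifier(calls[, c("read_id", "charged")], truth)
  fp_rate <- 100 * sum(scores$score > cutoff & !truth$charged) /
    sum(!truth$charged)
  list(eval = ev, F1 = ev$F1, fp_rate_pct = fp_rate, model = model,
       scores = scores, truth = truth)
}

#' Simulate one amino-acid panel library on a shared body
#'
#' All panels use the same synthetic tRNA body so that the only signal
#' separating amino acids is the amino acid itself (as in Flexizyme-charged
#' panels of a single synthetic tRNA).
#'
#' @param aa Amino-acid code, or `NA` for the uncharged control panel.
#' @param n_reads Reads in the panel.
#' @param seed Integer seed.
#' @param preset Effect preset (default `"flexizyme-panel"`).
#' @param mode Reference mode (default pairwise inserted-T).
#' @param body_code Isodecoder (by amino-acid code) providing the shared
#'   body.
#' @param signal Signal retention mode.
#' @return A `sim_library`.
#' @export
panel_library <- function(aa, n_reads = 500, seed = 1,
                          preset = "flexizyme-panel",
                          mode = "pairwise_insert_t", body_code = "G",
                          signal = "summary") {
  iso <- synthetic_isodecoders()[body_code]
  charged <- !is.na(aa)
  spec <- library_spec(
    isodecoders = iso,
    aa_assignment = stats::setNames(if (charged) aa else body_code, body_code),
    charged_fraction = if (charged) 1 else 0,
    n_reads = n_reads, condition = if (charged) aa else "uncharged",
    seed = seed)
  simulate_library(spec, preset = preset, mode = mode, signal = signal,
                   unblocking = FALSE)
}

#' Pairwise amino-acid classification experiment
#'
#' Simulates a panel per amino acid (shared body, inserted-T references,
#' flexizyme-panel preset), trains all ordered pairwise models and reports
#' the unordered mean-F1 matrix.
#'
#' @param n_per_aa Reads per amino-acid panel.
#' @param seed Master integer seed.
#' @param codes Amino-acid codes (default: all 20).
#' @param config Classifier configuration.
#' @param split Per-panel training fraction.
#' @return List from [train_pairwise_models()] plus `median_unordered`.
#' @export
pairwise_experiment <- function(n_per_aa = 500, seed = 1,
                                codes = aa_properties()$code,
                                config = classifier_config(), split = 0.8) {
  sets <- list()
  for (i in seq_along(codes)) {
    lib <- panel_library(codes[i], n_reads = n_per_aa,
                         seed = derive_seed(seed, 1000 + i))
    sets[[codes[i]]] <- extract_library_chunks(lib)
  }
  pw <- train_pairwise_models(sets, seed = derive_seed(seed, 5),
                              split = split, config = config)
  pw$median_unordered <-
    stats::median(pw$unordered[upper.tri(pw$unordered)], na.rm = TRUE)
  pw
}

#' Per-amino-acid panel signal summary
#'
#' For each amino acid, the mean dwell (ms) at offset +9 and, unless
#' `signal = "none"`, the mean normalized current at the charge site and
#' its difference from an uncharged control panel.
#'
#' @param n_per_aa Reads per panel.
#' @param seed Master integer seed.
#' @param preset Effect preset.
#' @param signal Signal retention mode (`"none"` skips currents).
#' @param codes Amino-acid codes.
#' @return `data.frame` with `code`, `mean_dwell9_ms`, `mean_cur0`,
#'   `dcur0` (charged minus uncharged control at offset 0).
#' @export
panel_experiment <- function(n_per_aa = 300, seed = 1,
                             preset = "flexizyme-panel", signal = "summary",
                             codes = aa_properties()$code) {
  want_current <- !identical(signal, "none")
  cur0_u <- NA_real_
  if (want_current) {
    lib_u <- panel_library(NA, n_reads = n_per_aa,
                           seed = derive_seed(seed, 999), preset = preset,
                           signal = signal)
    cur0_u <- mean(vapply(lib_u$reads,
                          function(r) r$current[r$anchor + 1L], 0))
  }
  rows <- lapply(seq_along(codes), function(i) {
    lib <- panel_library(codes[i], n_reads = n_per_aa,
                         seed = derive_seed(seed, i), preset = preset,
                         signal = signal)
    d9 <- vapply(lib$reads, function(r) r$dwell[r$anchor + 9L + 1L], 0) * 1000
    c0 <- if (want_current)
      mean(vapply(lib$reads, function(r) r$current[r$anchor + 1L], 0))
      else NA_real_
    data.frame(code = codes[i], mean_dwell9_ms = mean(d9), mean_cur0 = c0,
               dcur0 = c0 - cur0_u, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
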