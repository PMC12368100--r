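# Event-level squiggle simulator for adapter-ligated tRNA reads.
#
# A read is simulated per reference position: dwell ~ log-normal with mean
# dwell_multiplier/mean_speed, current samples ~ Normal(level(kmer) + shift,
# noise_sd), with the number of samples per position round(dwell x
# sample_rate), floored at 1. Uncharged reads receive zero shift and unit
# multipliers. Truncated ("unblocked") reads cover a 3'-terminal contiguous
# block of reference positions only (nanopore direct RNA sequencing enters
# from the 3' end, so the lost positions are in the 5' adapter).
#
# Memory modes: signal = "samples" retains the raw per-position sample
# vectors (pA); "summary" (default) computes per-position trimmed means of
# the median/MAD-normalized samples and then discards the raw samples;
# "none" skips current generation entirely (dwell-only studies).

#' Simulate one read
#'
#' @param ref An `extended_reference`.
#' @param truth List with fields `isodecoder`, `charged` (logical) and `aa`
#'   (one-letter code, required when charged).
#' @param model A `level_model`.
#' @param effects Profiles from [effect_profiles()].
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   reads.
#' @param signal `"summary"`, `"samples"` or `"none"` (see file header).
#' @param trim Trim fraction per tail for the stored current summary.
#' @param read_id Read identifier.
#' @param levels Optional precomputed `position_levels(model, ref$sequence)`
#'   (saves recomputation across reads of the same reference).
#' @return A list of class `sim_read`.
#' @export
simulate_read <- function(ref, truth, model, effects, seed,
                          signal = c("summary", "samples", "none"),
                          trim = 0.1, read_id = "read_000001", levels = NULL) {
  signal <- match.arg(signal)
  L <- nchar(ref$sequence)
  offsets <- seq_len(L) - 1L - ref$anchor
  if (isTRUE(truth$charged)) {
    if (is.null(truth$aa) || is.na(truth$aa) || is.null(effects[[truth$aa]])) {
      stopf("unknown amino-acid code for charged read: '%s'",
            truth$aa %||% "<missing>")
    }
    profile <- effects[[truth$aa]]
  } else {
    profile <- effects[["uncharged"]]
  }
  mult <- profile_dwell_at(profile, offsets)
  shift <- profile_shift_at(profile, offsets)
  m <- mult / model$mean_speed
  sdlog <- model$dwell_log_sd

  with_local_seed(seed, {
    dwell <- stats::rlnorm(L, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
    n_samples <- pmax(1L, as.integer(round(dwell * model$sample_rate)))
    samples <- NULL
    current <- rep(NA_real_, L)
    if (signal != "none") {
      if (is.null(levels)) levels <- position_levels(model, ref$sequence)
      mu <- levels + shift
      raw <- stats::rnorm(sum(n_samples), mean = rep(mu, n_samples),
                          sd = model$noise_sd)
      if (signal == "samples") {
        samples <- split(raw, rep.int(seq_len(L), n_samples))
        names(samples) <- NULL
      }
      # Normalize against the median/MAD of per-event mean currents so that
      # every position carries equal weight regardless of its dwell
      # (long-dwell events must not dominate the read's scale).
      grp <- rep.int(seq_len(L), n_samples)
      ev_mean <- rowsum(raw, grp)[, 1] / n_samples
      center <- stats::median(ev_mean)
      scale <- stats::mad(ev_mean, center = center)
      if (scale == 0) stopf("degenerate signal: zero MAD across event means")
      tmean <- vapply(split(raw, grp), mean, 0, trim = trim,
                      USE.NAMES = FALSE)
      current <- (tmean - center) / scale
    }
    structure(list(
      read_id = read_id,
      ref_name = ref$name,
      truth = truth,
      L = L,
      anchor = ref$anchor,
      n5 = ref$n5,
      mode = ref$mode,
      covered_from = 0L,
      dwell = dwell,
      current = current,
      samples = samples,
      n_samples = n_samples,
      total_duration = sum(dwell),
      truncated = FALSE,
      trim = trim
    ), class = "sim_read")
  })
}

#' Apply aberrant truncation ("unblocking") to a read
#'
#' With probability `prob` the molecule stalls and is ejected while its 5'
#' adapter transits the motor; the read then covers only the 3'-terminal
#' block from a stall position drawn uniformly within the 5' adapter region.
#'
#' @param read A `sim_read`.
#' @param effects Effect profiles; the read's amino acid (or the uncharged
#'   profile) supplies `unblock_prob` unless `prob` is given.
#' @param seed Integer seed.
#' @param prob Optional explicit truncation probability.
#' @return The (possibly truncated) `sim_read`.
#' @export
apply_unblocking <- function(read, effects = NULL, seed = 1, prob = NULL) {
  if (is.null(prob)) {
    key <- if (isTRUE(read$truth$charged)) read$truth$aa else "uncharged"
    prob <- effects[[key]]$unblock_prob
    if (is.null(prob)) stopf("no unblocking probability for '%s'", key)
  }
  if (length(read$dwell) == 0) stopf("read has no events")
  stall <- with_local_seed(seed, {
    if (stats::runif(1) >= prob) 0L
    else sample.int(max(read$n5, 2L) - 1L, 1L)  # 0-based stall in 1..n5-1
  })
  if (stall == 0L) return(read)
  idx <- seq_len(stall)
  read$dwell[idx] <- NA_real_
  read$current[idx] <- NA_real_
  read$n_samples[idx] <- NA_integer_
  if (!is.null(read$samples)) read$samples[idx] <- list(NULL)
  read$covered_from <- as.integer(stall)
  read$total_duration <- sum(read$dwell, na.rm = TRUE)
  read$truncated <- TRUE
  read
}

#' Emulate basecalling of a simulated read
#'
#' Applies substitutions, insertions and deletions per covered reference
#' position at `error_rate`, multiplied by `charged_error_boost` within
#' `window` positions of the anchor for charged reads only (the embedded
#' amino acid corrupts basecalls around the charge site).
#'
#' @param read A `sim_read`.
#' @param ref The read's `extended_reference`.
#' @param error_rate Per-position error probability in \[0,1\].
#' @param charged_error_boost Multiplier applied within the anchor window of
#'   charged reads.
#' @param window Half-width (positions) of the boosted window.
#' @param seed Integer seed.
#' @param type_probs Probabilities of substitution, insertion and deletion
#'   given an error.
#' @return Basecalled sequence (character scalar, reference orientation).
#' @export
emulate_basecalls <- function(read, ref, error_rate = 0.08,
                              charged_error_boost = 5, window = 3, seed = 1,
                              type_probs = c(sub = 0.6, ins = 0.2, del = 0.2)) {
  stopifnot(error_rate >= 0, error_rate <= 1, charged_error_boost >= 0)
  covered <- seq.int(read$covered_from, read$L - 1L)  # 0-based
  chars <- strsplit(substr(ref$sequence, read$covered_from + 1L, read$L),
                    "")[[1]]
  rate <- rep(error_rate, length(covered))
  if (isTRUE(read$truth$charged)) {
    boost_idx <- abs(covered - ref$anchor) <= window
    rate[boost_idx] <- pmin(1, rate[boost_idx] * charged_error_boost)
  }
  alphabet <- c("A", "C", "G", "U")
  with_local_seed(seed, {
    err <- stats::runif(length(covered)) < rate
    out <- chars
    if (any(err)) {
      type <- sample(names(type_probs), sum(err), replace = TRUE,
                     prob = type_probs)
      widx <- which(err)
      for (k in seq_along(widx)) {
        i <- widx[k]
        out[i] <- switch(type[k],
          sub = sample(setdiff(alphabet, chartr("T", "U", chars[i])), 1),
          ins = paste0(chars[i], sample(alphabet, 1)),
          del = "")
      }
    }
    paste(out, collapse = "")
  })
}

#' Specify a simulated library
#'
#' @param isodecoders Named list of `trna_isodecoder` objects (default: the
#'   20-amino-acid synthetic panel).
#' @param weights Relative abundances (recycled; need not sum to 1).
#' @param charged_fraction Charged fraction per isodecoder in \[0,1\]
#'   (scalar recycled).
#' @param aa_assignment Optional named character vector mapping isodecoder
#'   list names to amino-acid codes; defaults to the cognate amino acid
#'   inferred from the three-letter prefix of each isodecoder name.
#' @param n_reads Number of reads (count-budget mode), or `NULL`.
#' @param time_budget Per-channel sequencing time budget in seconds
#'   (time-budget mode), or `NULL`. Exactly one of `n_reads`/`time_budget`
#'   must be given.
#' @param n_channels Number of independent channels in time-budget mode.
#' @param adapter_mode `"hybrid_5p"` or `"legacy_rna_5p"`.
#' @param condition Condition label carried into the truth table.
#' @param seed Master integer seed.
#' @return A list of class `library_spec`.
#' @export
library_spec <- function(isodecoders = NULL, weights = 1,
                         charged_fraction = 0.5, aa_assignment = NULL,
                         n_reads = NULL, time_budget = NULL, n_channels = 1,
                         adapter_mode = c("hybrid_5p", "legacy_rna_5p"),
                         condition = "cond", seed = 1) {
  adapter_mode <- match.arg(adapter_mode)
  if (is.null(isodecoders)) isodecoders <- synthetic_isodecoders()
  if (length(isodecoders) == 0) stopf("library spec has no isodecoders")
  nms <- names(isodecoders) %||% as.character(seq_along(isodecoders))
  iso_names <- vapply(isodecoders, `[[`, "", "name")
  weights <- rep_len(weights, length(isodecoders))
  if (any(weights < 0) || sum(weights) <= 0) stopf("weights must be non-negative and normalizable")
  charged_fraction <- rep_len(charged_fraction, length(isodecoders))
  if (any(charged_fraction < 0 | charged_fraction > 1)) {
    stopf("charged_fraction must lie in [0,1]")
  }
  if (is.null(n_reads) == is.null(time_budget)) {
    stopf("exactly one of n_reads or time_budget must be given")
  }
  if (is.null(aa_assignment)) {
    three <- substr(iso_names, 1, 3)
    codes <- names(AA_THREE)[match(three, AA_THREE)]
    if (anyNA(codes)) {
      stopf("cannot infer cognate amino acid for isodecoder(s): %s",
            paste(iso_names[is.na(codes)], collapse = ", "))
    }
    aa_assignment <- stats::setNames(codes, nms)
  }
  structure(list(isodecoders = isodecoders, weights = weights / sum(weights),
                 charged_fraction = charged_fraction,
                 aa_assignment = aa_assignment, n_reads = n_reads,
                 time_budget = time_budget, n_channels = n_channels,
                 adapter_mode = adapter_mode, condition = condition,
                 seed = as.integer(seed)),
            class = "library_spec")
}

#' Simulate a library of reads
#'
#' In count-budget mode (`n_reads`), isodecoder and charged state are drawn
#' per read from the specified weights and charged fractions. In time-budget
#' mode, each channel draws reads sequentially and a read whose completion
#' would exceed the channel's remaining budget is discarded (its pore time
#' is lost), so slower -- charged -- reads are under-represented; this
#' reproduces the translocation-time sampling bias that makes sequencing
#' underestimate charging.
#'
#' @param spec A `library_spec`.
#' @param preset Effect preset passed to [effect_profiles()] when `effects`
#'   is not supplied.
#' @param model A `level_model` (default `level_model()`).
#' @param effects Optional pre-built effect profiles.
#' @param adapters Optional `adapter_set`; defaults to
#'   `default_adapters(spec$adapter_mode)`.
#' @param aa_table Amino-acid property table.
#' @param mode Reference mode (`"standard"` or `"pairwise_insert_t"`).
#' @param signal Signal retention mode, see [simulate_read()].
#' @param unblocking Apply aberrant truncation (default `TRUE`).
#' @param trim Trim fraction for stored current summaries.
#' @return A list of class `sim_library` with elements `reads` (list of
#'   `sim_read`), `truth` (data.frame: read_id, isodecoder, charged, aa,
#'   truncated, covered_from, duration, condition), `refs`, `spec`,
#'   `effects` and `model`.
#' @export
simulate_library <- function(spec, preset = "bio-default",
                             model = level_model(), effects = NULL,
                             adapters = NULL, aa_table = aa_properties(),
                             mode = "standard",
                             signal = c("summary", "samples", "none"),
                             unblocking = TRUE, trim = 0.1) {
  signal <- match.arg(signal)
  if (!inherits(spec, "library_spec")) stopf("spec must be a library_spec")
  if (is.null(adapters)) adapters <- default_adapters(spec$adapter_mode)
  iso <- spec$isodecoders
  keys <- names(iso)
  refs <- list()
  for (k in keys) {
    refs[[paste0(k, ":charged")]] <-
      build_extended_reference(iso[[k]], adapters, "charged", mode)
    refs[[paste0(k, ":uncharged")]] <-
      build_extended_reference(iso[[k]], adapters, "uncharged", mode)
  }
  if (is.null(effects)) {
    effects <- effect_profiles(preset, aa_table, spec$adapter_mode,
                               ref_length = nchar(refs[[1]]$sequence),
                               mean_speed = model$mean_speed)
  }
  levels_cache <- if (signal == "none") NULL else
    lapply(refs, function(r) position_levels(model, r$sequence))

  one_read <- function(i) {
    s <- derive_seed(spec$seed, i)
    draw <- with_local_seed(s, {
      ki <- sample.int(length(keys), 1L, prob = spec$weights)
      ch <- stats::runif(1) < spec$charged_fraction[ki]
      list(ki = ki, ch = ch)
    })
    k <- keys[draw$ki]
    ref <- refs[[paste0(k, ":", if (draw$ch) "charged" else "uncharged")]]
    truth <- list(isodecoder = iso[[k]]$name, charged = draw$ch,
                  aa = if (draw$ch) unname(spec$aa_assignment[[k]]) else NA_character_)
    read <- simulate_read(ref, truth, model, effects, seed = derive_seed(s, 1),
                          signal = signal, trim = trim,
                          read_id = sprintf("%s_s%d_%07d", spec$condition,
                                            spec$seed, i),
                          levels = levels_cache[[paste0(k, ":",
                            if (draw$ch) "charged" else "uncharged")]])
    if (unblocking) read <- apply_unblocking(read, effects,
                                             seed = derive_seed(s, 2))
    read
  }

  reads <- list()
  if (!is.null(spec$n_reads)) {
    reads <- lapply(seq_len(spec$n_reads), one_read)
  } else {
    i <- 0L
    for (ch in seq_len(spec$n_channels)) {
      t_used <- 0
      repeat {
        i <- i + 1L
        read <- one_read(i)
        if (t_used + read$total_duration > spec$time_budget) break
        t_used <- t_used + read$total_duration
        reads[[length(reads) + 1L]] <- read
      }
    }
    if (length(reads) == 0) stopf("time budget too small: no reads completed")
  }
  truth <- data.frame(
    read_id = vapply(reads, `[[`, "", "read_id"),
    isodecoder = vapply(reads, function(r) r$truth$isodecoder, ""),
    charged = vapply(reads, function(r) r$truth$charged, TRUE),
    aa = vapply(reads, function(r) r$truth$aa %||% NA_character_, ""),
    truncated = vapply(reads, `[[`, TRUE, "truncated"),
    covered_from = vapply(reads, `[[`, 0L, "covered_from"),
    duration = vapply(reads, `[[`, 0, "total_duration"),
    condition = spec$condition,
    stringsAsFactors = FALSE)
  structure(list(reads = reads, truth = truth, refs = refs, spec = spec,
                 effects = effects, model = model),
            class = "sim_library")
}
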