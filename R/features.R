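# Reference-anchored signal features: normalization, per-position metrics,
# trace summaries, training chunks, dwell-bias diagnostics and
# property correlations.

#' Median/MAD normalization of a sample vector
#'
#' Centers at the median and scales by the (1.4826-scaled) median absolute
#' deviation; invariant under affine transforms of the input and idempotent.
#'
#' @param samples Numeric vector (length >= 2).
#' @return Normalized numeric vector.
#' @export
normalize_signal <- function(samples) {
  if (length(samples) < 2) stopf("normalization requires at least 2 samples")
  med <- stats::median(samples)
  s <- stats::mad(samples, center = med)
  if (s == 0) stopf("zero MAD: input signal is (half-)constant and cannot be scaled")
  (samples - med) / s
}

# Per-read normalization constants: median/MAD of per-event mean currents,
# so every covered position carries equal weight regardless of its dwell.
read_event_normalization <- function(read) {
  covered <- which(!is.na(read$dwell))
  ev_mean <- vapply(read$samples[covered], mean, 0)
  center <- stats::median(ev_mean)
  scale <- stats::mad(ev_mean, center = center)
  if (scale == 0) stopf("degenerate signal: zero MAD across event means")
  list(center = center, scale = scale)
}

#' Per-position signal metrics of one read
#'
#' Dwell in milliseconds and the trimmed mean of the read-normalized current
#' at each covered reference position. Normalization is per read against
#' the median/MAD of per-event mean currents. Positions not covered by the
#' read (truncation) are absent from the result, not zero.
#'
#' @param read A `sim_read` (or compatible object with fields `dwell`,
#'   `current`/`samples`, `covered_from`).
#' @param trim Trim fraction per tail (default 0.1). When the read carries
#'   only a stored current summary, `trim` must match the one used at
#'   simulation time.
#' @param normalize Normalize currents (default `TRUE`; only applicable
#'   when raw samples are present).
#' @return `data.frame` with columns `read_id`, `pos` (0-based), `offset`
#'   (signed offset from the anchor), `dwell_ms`, `current`.
#' @export
per_position_metrics <- function(read, trim = 0.1, normalize = TRUE) {
  covered <- which(!is.na(read$dwell))
  if (length(covered) == 0) stopf("read has no covered events")
  if (!is.null(read$samples)) {
    current <- vapply(read$samples[covered], mean, 0, trim = trim,
                      USE.NAMES = FALSE)
    if (normalize) {
      nrm <- read_event_normalization(read)
      current <- (current - nrm$center) / nrm$scale
    }
  } else {
    if (!is.null(read$trim) && !isTRUE(all.equal(trim, read$trim))) {
      stopf("read stores a trim=%.3g current summary; raw samples needed for trim=%.3g",
            read$trim, trim)
    }
    current <- read$current[covered]
  }
  data.frame(read_id = read$read_id,
             pos = covered - 1L,
             offset = covered - 1L - read$anchor,
             dwell_ms = read$dwell[covered] * 1000,
             current = current,
             stringsAsFactors = FALSE)
}

#' Summarize signal traces across reads
#'
#' Per-position mean and SD of current and dwell over a read set, computed
#' only over reads covering each position.
#'
#' @param reads List of `sim_read`s over the same reference length.
#' @param positions 0-based reference positions (default: all).
#' @return `data.frame` with columns `pos`, `offset`, `n`, `mean_current`,
#'   `sd_current`, `mean_dwell_ms`, `sd_dwell_ms`.
#' @export
summarize_traces <- function(reads, positions = NULL) {
  if (length(reads) < 2) stopf("trace summaries require at least 2 reads")
  L <- reads[[1]]$L
  anchor <- reads[[1]]$anchor
  if (is.null(positions)) positions <- 0:(L - 1L)
  if (any(positions < 0 | positions >= L)) {
    stopf("requested positions fall outside the reference [0, %d)", L)
  }
  cur <- vapply(reads, function(r) r$current[positions + 1L],
                numeric(length(positions)))
  dw <- vapply(reads, function(r) r$dwell[positions + 1L] * 1000,
               numeric(length(positions)))
  cur <- matrix(cur, nrow = length(positions))
  dw <- matrix(dw, nrow = length(positions))
  data.frame(
    pos = positions,
    offset = positions - anchor,
    n = rowSums(!is.na(dw)),
    mean_current = rowMeans(cur, na.rm = TRUE),
    sd_current = apply(cur, 1, stats::sd, na.rm = TRUE),
    mean_dwell_ms = rowMeans(dw, na.rm = TRUE),
    sd_dwell_ms = apply(dw, 1, stats::sd, na.rm = TRUE))
}

#' Per-position difference of mean current between two read sets
#'
#' @param reads_a,reads_b Read sets (e.g. charged vs uncharged).
#' @param positions 0-based positions (default: all).
#' @return `data.frame` with `pos`, `offset`, `diff_current`
#'   (mean A - mean B) and `diff_dwell_ms`.
#' @export
trace_difference <- function(reads_a, reads_b, positions = NULL) {
  sa <- summarize_traces(reads_a, positions)
  sb <- summarize_traces(reads_b, positions)
  data.frame(pos = sa$pos, offset = sa$offset,
             diff_current = sa$mean_current - sb$mean_current,
             diff_dwell_ms = sa$mean_dwell_ms - sb$mean_dwell_ms)
}

#' Extract training chunks centered on the anchor
#'
#' One chunk per read that fully covers the feature window and (when raw
#' samples are retained) the fixed sample context around the anchor event's
#' center sample. Reads failing either requirement are skipped and counted.
#'
#' Each chunk carries the anchor-window reference sequence, a per-read
#' feature vector (trimmed-mean normalized current at offsets -3..+6 and
#' log dwell (ms) at offsets -3..+10) and, when available, a fixed-length
#' normalized sample vector centered on the anchor event.
#'
#' @param reads List of `sim_read`s.
#' @param ref The `extended_reference` the reads were simulated from.
#' @param motif Expected motif at the anchor (`"CCAGGC"` spanning offsets
#'   -3..+2 in standard mode, `"CCAT"` spanning -3..0 in pairwise mode).
#' @param motif_offset Offset of the modification position within the motif
#'   (3: the first base 3' of CCA).
#' @param context Samples kept on each side of the anchor event's center.
#' @param current_offsets,dwell_offsets Signed offsets contributing current
#'   and dwell features.
#' @param label Optional class label stored on every chunk.
#' @return List of `signal_chunk` objects with attribute `skipped` (named
#'   integer: `not_covering_window`, `not_covering_context`).
#' @export
extract_chunks <- function(reads, ref, motif = NULL, motif_offset = 3,
                           context = c(200, 200),
                           current_offsets = -3:6, dwell_offsets = -3:10,
                           label = NA) {
  if (is.null(motif)) motif <- if (ref$mode == "pairwise_insert_t") "CCAT" else "CCAGGC"
  at_anchor <- substr(ref$sequence, ref$anchor - (motif_offset - 1) - 1 + 1,
                      ref$anchor - motif_offset + nchar(motif))
  if (at_anchor != motif) {
    stopf("motif '%s' not found at the anchor of '%s' (saw '%s')",
          motif, ref$name, at_anchor)
  }
  need <- range(c(current_offsets, dwell_offsets))
  skipped <- c(not_covering_window = 0L, not_covering_context = 0L)
  chunks <- list()
  for (read in reads) {
    lo <- read$anchor + need[1]
    hi <- read$anchor + need[2]
    if (read$covered_from > lo || hi >= read$L) {
      skipped["not_covering_window"] <- skipped["not_covering_window"] + 1L
      next
    }
    cur <- read$current[read$anchor + current_offsets + 1L]
    dw <- read$dwell[read$anchor + dwell_offsets + 1L] * 1000
    feats <- c(stats::setNames(cur, paste0("cur_", current_offsets)),
               stats::setNames(log(dw), paste0("ldw_", dwell_offsets)))
    samples <- NULL
    if (!is.null(read$samples)) {
      covered <- which(!is.na(read$dwell))
      raw <- unlist(read$samples[covered], use.names = FALSE)
      nrm <- read_event_normalization(read)
      norm <- (raw - nrm$center) / nrm$scale
      counts <- vapply(read$samples[covered], length, 0L)
      ends <- cumsum(counts)
      a_idx <- match(read$anchor + 1L, covered)
      center <- ends[a_idx] - counts[a_idx] %/% 2L
      if (center - context[1] < 1 || center + context[2] - 1 > length(norm)) {
        skipped["not_covering_context"] <- skipped["not_covering_context"] + 1L
        next
      }
      samples <- norm[(center - context[1]):(center + context[2] - 1)]
    }
    chunks[[length(chunks) + 1L]] <- structure(list(
      read_id = read$read_id, anchor = read$anchor,
      context_seq = reference_window(ref, need[1], need[2]),
      features = feats, samples = samples, label = label),
      class = "signal_chunk")
  }
  attr(chunks, "skipped") <- skipped
  chunks
}

#' Extract chunks from a whole simulated library
#'
#' Groups the library's reads by reference and concatenates the per-
#' reference chunk sets; skip counts are summed into the `skipped`
#' attribute.
#'
#' @param lib A `sim_library`.
#' @param ... Passed to [extract_chunks()].
#' @return List of `signal_chunk`s with attribute `skipped`.
#' @export
extract_library_chunks <- function(lib, ...) {
  out <- list()
  skipped <- c(not_covering_window = 0L, not_covering_context = 0L)
  by_ref <- split(lib$reads, vapply(lib$reads, `[[`, "", "ref_name"))
  ref_names <- vapply(lib$refs, `[[`, "", "name")
  for (rn in names(by_ref)) {
    ref <- lib$refs[[match(rn, ref_names)]]
    ch <- extract_chunks(by_ref[[rn]], ref, ...)
    skipped <- skipped + attr(ch, "skipped")
    out <- c(out, ch)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Dwell-bias diagnostic
#'
#' Ratio of mean total translocation time between charged and uncharged
#' reads, with optional per-class resampling weights proportional to the
#' inverse class mean duration (normalized to mean 1 over the read set).
#'
#' @param durations Numeric vector of total read durations (s).
#' @param charged Logical vector, same length.
#' @return List with `ratio` (charged/uncharged), `mean_charged`,
#'   `mean_uncharged` and per-read `weights`.
#' @export
dwell_bias_diagnostic <- function(durations, charged) {
  stopifnot(length(durations) == length(charged))
  if (!any(charged) || !any(!charged)) {
    stopf("both charged and uncharged reads are required")
  }
  mc <- mean(durations[charged])
  mu <- mean(durations[!charged])
  w <- ifelse(charged, 1 / mc, 1 / mu)
  list(ratio = mc / mu, mean_charged = mc, mean_uncharged = mu,
       weights = w / mean(w))
}

#' Pearson correlation between a per-amino-acid feature and a property
#'
#' @param feature,property Paired numeric vectors (typically the 20 amino
#'   acids), no missing values.
#' @return List with `r`, `p` (two-sided, t-distribution with n-2 df),
#'   `t` and `n`.
#' @export
property_correlation <- function(feature, property) {
  if (length(feature) != length(property)) stopf("inputs must be paired")
  if (anyNA(feature) || anyNA(property)) stopf("missing values are not allowed")
  n <- length(feature)
  if (n < 3) stopf("at least 3 pairs are required")
  if (stats::sd(feature) == 0 || stats::sd(property) == 0) {
    stopf("zero variance input")
  }
  r <- stats::cor(feature, property)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p = min(p, 1), t = tstat, n = n)
}
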