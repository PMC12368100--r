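# Internal signal container and TSV interop.
#
# The container is a single binary file holding, per read: a JSON metadata
# record, the per-position dwell vector (float64, seconds; NaN for
# uncovered positions), the per-position sample-count vector (int32, the
# event index), and optionally the contiguous current-sample vector
# (float32, pA). A JSON footer with per-read byte offsets makes the file
# seekable; the byte layout is an implementation detail and only the
# round-trip contract is documented: write followed by read reproduces the
# reads (current samples at float32 precision).

CONTAINER_MAGIC <- "TRNACHARGE_SIG1\n"

#' Write reads to the internal signal container
#'
#' @param reads List of `sim_read` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_container <- function(reads, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(CONTAINER_MAGIC, con, eos = NULL)
  offsets <- integer(0)
  for (read in reads) {
    offsets <- c(offsets, seek(con))
    meta <- jsonlite::toJSON(list(
      read_id = read$read_id, ref_name = read$ref_name,
      truth = read$truth, L = read$L, anchor = read$anchor, n5 = read$n5,
      mode = read$mode, covered_from = read$covered_from,
      truncated = read$truncated, trim = read$trim,
      has_samples = !is.null(read$samples),
      has_current = !all(is.na(read$current))), auto_unbox = TRUE,
      digits = NA, null = "null", na = "null")
    meta_raw <- charToRaw(as.character(meta))
    writeBin(length(meta_raw), con, size = 4L)
    writeBin(meta_raw, con)
    writeBin(read$L, con, size = 4L)
    writeBin(as.double(read$dwell), con, size = 8L)
    ns <- read$n_samples
    ns[is.na(ns)] <- -1L
    writeBin(as.integer(ns), con, size = 4L)
    if (!all(is.na(read$current))) {
      writeBin(as.double(read$current), con, size = 8L)
    }
    if (!is.null(read$samples)) {
      flat <- unlist(read$samples, use.names = FALSE)
      writeBin(length(flat), con, size = 4L)
      writeBin(as.double(flat), con, size = 4L)  # float32
    }
  }
  footer <- charToRaw(as.character(jsonlite::toJSON(
    list(n_reads = length(reads), offsets = offsets), auto_unbox = TRUE)))
  writeBin(footer, con)
  writeBin(length(footer), con, size = 4L)
  invisible(path)
}

#' Read reads back from the internal signal container
#'
#' @param path Container path.
#' @return List of `sim_read` objects.
#' @export
read_signal_container <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchar(CONTAINER_MAGIC), useBytes = TRUE)
  if (!identical(magic, CONTAINER_MAGIC)) stopf("'%s' is not a signal container", path)
  sz <- file.size(path)
  seek(con, sz - 4L)
  flen <- readBin(con, "integer", size = 4L)
  seek(con, sz - 4L - flen)
  footer <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", flen)))
  reads <- vector("list", footer$n_reads)
  for (i in seq_len(footer$n_reads)) {
    seek(con, footer$offsets[i])
    mlen <- readBin(con, "integer", size = 4L)
    meta <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", mlen)),
                               simplifyVector = TRUE)
    L <- readBin(con, "integer", size = 4L)
    dwell <- readBin(con, "double", n = L, size = 8L)
    ns <- readBin(con, "integer", n = L, size = 4L)
    ns[ns < 0] <- NA_integer_
    current <- rep(NA_real_, L)
    if (isTRUE(meta$has_current)) {
      current <- readBin(con, "double", n = L, size = 8L)
    }
    samples <- NULL
    if (isTRUE(meta$has_samples)) {
      nflat <- readBin(con, "integer", size = 4L)
      flat <- readBin(con, "double", n = nflat, size = 4L)
      cnt <- ns
      cnt[is.na(cnt)] <- 0L
      samples <- split(flat, rep.int(seq_len(L), cnt))
      names(samples) <- NULL
      full <- vector("list", L)
      full[which(cnt > 0)] <- samples
      samples <- full
    }
    dwell[is.nan(dwell)] <- NA_real_
    truth <- meta$truth
    truth$aa <- truth$aa %||% NA_character_
    reads[[i]] <- structure(list(
      read_id = meta$read_id, ref_name = meta$ref_name, truth = truth,
      L = L, anchor = meta$anchor, n5 = meta$n5, mode = meta$mode,
      covered_from = meta$covered_from, dwell = dwell, current = current,
      samples = samples, n_samples = ns,
      total_duration = sum(dwell, na.rm = TRUE),
      truncated = isTRUE(meta$truncated), trim = meta$trim),
      class = "sim_read")
  }
  reads
}

#' Export per-read, per-position metrics as TSV
#'
#' Columns: `read_id`, `ref`, `pos`, `dwell_ms`, `current` -- the interop
#' format also accepted by [import_signal_tsv()] for externally produced
#' reference-anchored signal tables.
#'
#' @param reads List of `sim_read`s.
#' @param path Output TSV path.
#' @param trim Trim fraction for current summaries.
#' @return `path`, invisibly.
#' @export
export_metrics_tsv <- function(reads, path, trim = 0.1) {
  tabs <- lapply(reads, function(r) {
    pm <- per_position_metrics(r, trim = trim)
    data.frame(read_id = pm$read_id, ref = r$ref_name, pos = pm$pos,
               dwell_ms = pm$dwell_ms, current = pm$current,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Import externally produced per-position signal tables
#'
#' Loads a TSV with columns `read_id`, `ref`, `pos`, `dwell_ms`, `current`
#' into read-like objects usable by the feature and classification layers
#' in place of simulated reads. Anchors must be supplied per reference.
#'
#' @param path TSV path.
#' @param anchors Named integer vector: anchor (0-based) per `ref` value.
#' @param n5 Named integer vector (or scalar) of 5' adapter lengths.
#' @return List of `sim_read`-compatible objects.
#' @export
import_signal_tsv <- function(path, anchors, n5 = 0L) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- c("read_id", "ref", "pos", "dwell_ms", "current")
  if (!all(required %in% names(tab))) {
    stopf("TSV must have columns: %s", paste(required, collapse = ", "))
  }
  split_tab <- split(tab, tab$read_id)
  lapply(split_tab, function(d) {
    ref <- d$ref[1]
    if (is.na(anchors[ref])) stopf("no anchor supplied for reference '%s'", ref)
    L <- max(d$pos) + 1L
    dwell <- current <- rep(NA_real_, L)
    dwell[d$pos + 1L] <- d$dwell_ms / 1000
    current[d$pos + 1L] <- d$current
    covered_from <- min(d$pos)
    structure(list(
      read_id = d$read_id[1], ref_name = ref,
      truth = list(isodecoder = NA_character_, charged = NA, aa = NA_character_),
      L = L, anchor = unname(anchors[ref]),
      n5 = if (length(n5) > 1) unname(n5[ref]) else n5,
      mode = "standard", covered_from = covered_from, dwell = dwell,
      current = current, samples = NULL,
      n_samples = rep(NA_integer_, L),
      total_duration = sum(dwell, na.rm = TRUE),
      truncated = covered_from > 0, trim = 0.1), class = "sim_read")
  })
}
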