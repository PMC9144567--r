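# EDF / EDF+ (16-bit) reading and writing, including the text annotation
# channel ("EDF Annotations", TAL-encoded) used by public sleep archives to
# store hypnograms. Only the features needed for PSG staging are covered:
# one sampling rate across EEG channels, int16 samples, optional annotations.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

edf_num <- function(x, width = 8) {
  s <- format(x, scientific = FALSE, trim = TRUE)
  if (nchar(s) > width) s <- substr(format(round(x, 3), scientific = FALSE,
                                           trim = TRUE), 1, width)
  edf_pad(s, width)
}

#' Construct a raw multi-channel recording
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param rate sampling rate in Hz (one rate for all channels).
#' @param channel_names character vector, one label per channel.
#' @param subject_id subject identifier string.
#' @return Object of class `raw_recording`.
#' @export
raw_recording <- function(signal, rate, channel_names,
                          subject_id = "anonymous") {
  signal <- as.matrix(signal)
  if (length(channel_names) != nrow(signal))
    stop("channel_names length must equal the number of signal rows")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stop("rate must be a positive scalar")
  structure(list(subject_id = subject_id, rate = rate,
                 channel_names = as.character(channel_names),
                 signal = signal),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("raw_recording '%s': %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$signal), ncol(x$signal), x$rate,
              ncol(x$signal) / x$rate))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

# Encode one record's annotation events as a TAL byte string. TALs are
# nul-terminated; nul cannot live in an R string, so bytes are assembled
# at the raw level.
tal_encode <- function(rec_onset, events) {
  nul <- as.raw(0)
  out <- c(charToRaw(sprintf("+%s\x14\x14",
                             format(rec_onset, scientific = FALSE,
                                    trim = TRUE))), nul)
  if (nrow(events)) {
    ev <- sprintf("+%s\x15%s\x14%s\x14",
                  format(events$onset, scientific = FALSE, trim = TRUE),
                  format(events$duration, scientific = FALSE, trim = TRUE),
                  events$text)
    for (e in ev) out <- c(out, charToRaw(e), nul)
  }
  out
}

#' Write a recording to EDF (optionally EDF+ with annotations)
#'
#' Samples are quantized to 16-bit integers over a symmetric physical range
#' per channel, so the round-trip error is bounded by half a quantization
#' step. When `annotations` is supplied an "EDF Annotations" channel is
#' added (EDF+C) carrying the events as TALs.
#'
#' @param rec a `raw_recording`.
#' @param path output file path.
#' @param annotations optional data frame with columns `onset` (seconds),
#'   `duration` (seconds), `text` — e.g. a hypnogram as
#'   "Sleep stage W" events.
#' @param record_seconds data record duration in seconds (default 1).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, annotations = NULL, record_seconds = 1) {
  stopifnot(inherits(rec, "raw_recording"))
  q <- nrow(rec$signal)
  spr <- rec$rate * record_seconds
  if (spr != round(spr))
    stop("rate * record_seconds must be an integer number of samples")
  spr <- as.integer(spr)
  n_rec <- ncol(rec$signal) %/% spr
  if (n_rec < 1) stop("recording shorter than one data record")
  if (ncol(rec$signal) %% spr != 0)
    warning("signal length is not a whole number of records; tail dropped")

  pm <- apply(abs(rec$signal[, seq_len(n_rec * spr), drop = FALSE]), 1, max)
  pm[pm == 0] <- 1
  pm <- signif(pm * 1.0001, 6)  # keep extrema strictly inside the range
  dmin <- -32768; dmax <- 32767
  gain <- 2 * pm / (dmax - dmin)

  has_ann <- !is.null(annotations) && nrow(annotations) > 0
  tals <- NULL
  ann_spr <- 0L
  if (has_ann) {
    annotations <- annotations[order(annotations$onset), , drop = FALSE]
    rec_id <- pmin(n_rec - 1, floor(annotations$onset / record_seconds))
    tals <- lapply(seq_len(n_rec) - 1L, function(r)
      tal_encode(r * record_seconds, annotations[rec_id == r, , drop = FALSE]))
    ann_spr <- as.integer(ceiling(max(vapply(tals, length, 1L)) / 2))
  }

  ns <- q + has_ann
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad(rec$subject_id, 80))
  wr(edf_pad("Startdate 01-JAN-2000", 80))
  wr(edf_pad("01.01.00", 8))
  wr(edf_pad("00.00.00", 8))
  wr(edf_pad(256 * (ns + 1), 8))
  wr(edf_pad(if (has_ann) "EDF+C" else "", 44))
  wr(edf_pad(n_rec, 8))
  wr(edf_num(record_seconds))
  wr(edf_pad(ns, 4))
  labels <- c(rec$channel_names, if (has_ann) "EDF Annotations")
  for (l in labels) wr(edf_pad(l, 16))
  for (i in seq_len(ns)) wr(edf_pad("", 80))
  for (i in seq_len(ns)) wr(edf_pad(if (i <= q) "uV" else "", 8))
  for (i in seq_len(ns)) wr(edf_num(if (i <= q) -pm[i] else -1))
  for (i in seq_len(ns)) wr(edf_num(if (i <= q) pm[i] else 1))
  for (i in seq_len(ns)) wr(edf_num(dmin))
  for (i in seq_len(ns)) wr(edf_num(dmax))
  for (i in seq_len(ns)) wr(edf_pad("", 80))
  for (i in seq_len(ns)) wr(edf_pad(if (i <= q) spr else ann_spr, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 32))

  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(q)) {
      dig <- as.integer(pmax(dmin, pmin(dmax,
                                        round(rec$signal[i, idx] / gain[i]))))
      writeBin(dig, con, size = 2, endian = "little")
    }
    if (has_ann) {
      b <- tals[[r]]
      writeBin(c(b, raw(2 * ann_spr - length(b))), con)
    }
  }
  invisible(path)
}

# Parse the concatenated TAL byte stream of an annotation channel into a
# data frame of events (onset, duration, text).
tal_parse <- function(bytes) {
  txt <- rawToChar(bytes[bytes != as.raw(0)])
  # TALs start with "+" and end with \x14; split at those boundaries
  chunks <- strsplit(txt, "(?<=\x14)(?=\\+)", perl = TRUE)[[1]]
  out <- list()
  for (ch in chunks) {
    fields <- strsplit(ch, "\x14", fixed = TRUE)[[1]]
    if (!length(fields)) next
    head <- strsplit(fields[1], "\x15", fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(head[1]))
    duration <- if (length(head) > 1)
      suppressWarnings(as.numeric(head[2])) else NA_real_
    texts <- fields[-1]
    texts <- texts[nzchar(texts)]
    for (tx in texts)
      out[[length(out) + 1]] <- data.frame(onset = onset,
                                           duration = duration, text = tx,
                                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(onset = numeric(), duration = numeric(),
                      text = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

read_edf_header <- function(con) {
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  h <- list()
  h$version <- rd(8)
  h$patient <- rd(80)
  h$recording <- rd(80)
  h$startdate <- rd(8)
  h$starttime <- rd(8)
  h$header_bytes <- as.integer(rd(8))
  h$reserved <- rd(44)
  h$n_records <- as.integer(rd(8))
  h$record_seconds <- as.numeric(rd(8))
  h$ns <- as.integer(rd(4))
  ns <- h$ns
  h$labels <- vapply(seq_len(ns), function(i) rd(16), "")
  h$transducer <- vapply(seq_len(ns), function(i) rd(80), "")
  h$phys_dim <- vapply(seq_len(ns), function(i) rd(8), "")
  h$phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  h$phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  h$dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  h$dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  h$prefilter <- vapply(seq_len(ns), function(i) rd(80), "")
  h$spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  h$sig_reserved <- vapply(seq_len(ns), function(i) rd(32), "")
  h
}

#' Read an EDF/EDF+ recording
#'
#' Reads the 16-bit signal channels (rescaled to physical units) and, when
#' present, the "EDF Annotations" channel as an event table.
#'
#' @param path EDF file path.
#' @param channels optional character vector of channel labels to keep, in
#'   the requested order. Unknown labels are an error.
#' @return A `raw_recording` with attribute `annotations` (a data frame of
#'   onset/duration/text events, empty if the file has none).
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  ann_idx <- which(h$labels == "EDF Annotations")
  sig_idx <- setdiff(seq_len(h$ns), ann_idx)
  if (!is.null(channels)) {
    pos <- match(channels, h$labels[sig_idx])
    if (anyNA(pos))
      stop("channel(s) not found: ",
           paste(channels[is.na(pos)], collapse = ", "))
    sig_idx <- sig_idx[pos]
  }
  rates <- h$spr[sig_idx] / h$record_seconds
  if (length(unique(rates)) > 1)
    stop("selected channels have inconsistent sampling rates")

  bytes_per_rec <- 2L * sum(h$spr)
  raw_all <- readBin(con, "raw", n = bytes_per_rec * h$n_records)
  if (length(raw_all) < bytes_per_rec * h$n_records)
    stop("file truncated: fewer data records than the header declares")
  dim(raw_all) <- c(bytes_per_rec, h$n_records)
  offs <- c(0L, cumsum(2L * h$spr))

  get_channel_raw <- function(i)
    raw_all[(offs[i] + 1L):offs[i + 1L], , drop = FALSE]

  sig <- matrix(0, length(sig_idx), h$spr[sig_idx[1]] * h$n_records)
  for (k in seq_along(sig_idx)) {
    i <- sig_idx[k]
    dig <- readBin(as.vector(get_channel_raw(i)), "integer", size = 2,
                   n = h$spr[i] * h$n_records, signed = TRUE,
                   endian = "little")
    gain <- (h$phys_max[i] - h$phys_min[i]) / (h$dig_max[i] - h$dig_min[i])
    sig[k, ] <- gain * (dig - h$dig_min[i]) + h$phys_min[i]
  }
  ann <- data.frame(onset = numeric(), duration = numeric(),
                    text = character(), stringsAsFactors = FALSE)
  if (length(ann_idx))
    ann <- tal_parse(as.vector(get_channel_raw(ann_idx[1])))
  rec <- raw_recording(sig, rates[1], h$labels[sig_idx],
                       subject_id = h$patient)
  attr(rec, "annotations") <- ann
  rec
}

#' Write a hypnogram as a TSV file
#'
#' Two columns: `epoch_index` (0-based) and `label`.
#'
#' @param labels character vector of per-epoch stage labels.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hypnogram_tsv <- function(labels, path) {
  utils::write.table(
    data.frame(epoch_index = seq_along(labels) - 1L, label = labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a hypnogram
#'
#' Supports per-epoch TSV files (columns `epoch_index`, `label`; the
#' ISRUC-style one-label-per-epoch dialect) and EDF+ files whose
#' annotation channel carries duration-bearing stage events (the
#' sleep-EDF dialect). The format is auto-detected from the file
#' extension and can be forced with `format`.
#'
#' @param path file path (.tsv/.txt or .edf).
#' @param format `"auto"`, `"tsv"` or `"edf"`.
#' @param epoch_seconds epoch length used to expand EDF+ events (default 30).
#' @param aliases label alias table for canonicalization.
#' @return Character vector of per-epoch canonical labels (R&K or AASM
#'   vocabulary, not yet harmonized).
#' @export
read_hypnogram <- function(path, format = c("auto", "tsv", "edf"),
                           epoch_seconds = 30, aliases = label_aliases()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "tsv"
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("epoch_index", "label") %in% names(df)))
      stop("hypnogram TSV must have columns epoch_index and label")
    df <- df[order(df$epoch_index), ]
    return(canonical_labels(df$label, aliases))
  }
  rec <- read_edf(path)
  ann <- attr(rec, "annotations")
  known <- tolower(trimws(ann$text)) %in% names(aliases)
  ann <- ann[known & !is.na(ann$duration), , drop = FALSE]
  if (!nrow(ann)) stop("no stage annotations found in ", path)
  n_epochs <- as.integer(ceiling((max(ann$onset + ann$duration)) /
                                   epoch_seconds))
  labels <- rep(NA_character_, n_epochs)
  for (j in seq_len(nrow(ann))) {
    from <- floor(ann$onset[j] / epoch_seconds) + 1
    to <- ceiling((ann$onset[j] + ann$duration[j]) / epoch_seconds)
    labels[from:to] <- ann$text[j]
  }
  if (anyNA(labels)) stop("hypnogram has unannotated epochs")
  canonical_labels(labels, aliases)
}
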