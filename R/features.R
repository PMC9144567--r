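# Differential-entropy band features. Each 30-s epoch of each electrode is
# band-pass filtered into the classical sleep bands and summarized by the
# Gaussian differential entropy 0.5*log(2*pi*e*var), giving an N x Fde
# feature matrix per epoch; consecutive epochs are stacked into temporal
# context blocks that form the network input.

#' Default sleep frequency bands
#'
#' Delta 0.5-4, theta 4-8, alpha 8-13, sigma 11-16 and beta 16-30 Hz.
#' Sigma (the spindle band) deliberately overlaps alpha/beta; spindles are
#' the key N2 signature.
#'
#' @return Named list of length-2 numeric vectors (Hz).
#' @export
default_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
       sigma = c(11, 16), beta = c(16, 30))
}

validate_bands <- function(bands, rate) {
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2 || b[1] <= 0 || b[2] <= b[1])
      stop("band '", nm, "' must be an increasing positive interval")
    if (b[2] >= rate / 2)
      stop("band '", nm, "' upper edge must be below the Nyquist frequency")
  }
  invisible(bands)
}

#' Split a recording into fixed-length epochs
#'
#' @param rec a `raw_recording`.
#' @param epoch_seconds epoch length (default 30, the scoring standard).
#' @return Object of class `epoched_recording`: list with `epochs` (array
#'   channels x samples-per-epoch x n_epochs), `rate`, `channel_names`,
#'   `subject_id`, `epoch_seconds`. A trailing partial epoch is dropped.
#' @export
epoch_signal <- function(rec, epoch_seconds = 30) {
  stopifnot(inherits(rec, "raw_recording"))
  spe <- rec$rate * epoch_seconds
  if (spe != round(spe)) stop("epoch_seconds * rate must be an integer")
  spe <- as.integer(spe)
  n <- ncol(rec$signal) %/% spe
  if (n < 1) stop("recording shorter than one epoch")
  x <- rec$signal[, seq_len(n * spe), drop = FALSE]
  structure(list(epochs = array(x, c(nrow(x), spe, n),
                                dimnames = list(rec$channel_names, NULL, NULL)),
                 rate = rec$rate, channel_names = rec$channel_names,
                 subject_id = rec$subject_id, epoch_seconds = epoch_seconds),
            class = "epoched_recording")
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward
#' ([signal::filtfilt()]), so the pass band is amplitude-preserving and
#' phase distortion cancels.
#'
#' @param x numeric vector (one epoch of one channel).
#' @param band length-2 numeric, lower and upper edge in Hz.
#' @param rate sampling rate in Hz.
#' @param order filter order of each pass (default 4).
#' @return Filtered vector, same length as `x`.
#' @export
band_filter <- function(x, band, rate, order = 4) {
  if (band[1] <= 0 || band[2] >= rate / 2 || band[2] <= band[1])
    stop("band must lie strictly inside (0, Nyquist)")
  key <- paste(order, band[1], band[2], rate, sep = "_")
  bf <- .butter_cache[[key]]
  if (is.null(bf)) {
    bf <- signal::butter(order, band * 2 / rate, type = "pass")
    .butter_cache[[key]] <- bf
  }
  signal::filtfilt(bf, x)
}

.butter_cache <- new.env(parent = emptyenv())

#' Differential entropy of a signal (Gaussian closed form)
#'
#' For a band-limited signal modelled as Gaussian the differential entropy
#' is \eqn{\tfrac12 \ln(2\pi e \sigma^2)} nats, with \eqn{\sigma^2} the
#' population variance. Shift-invariant; scaling by `a` adds `log(|a|)`.
#'
#' @param x numeric vector, length >= 2.
#' @param floor_value value returned (with a warning) when the variance is
#'   zero, where the closed form diverges to minus infinity.
#' @return Scalar differential entropy in nats.
#' @examples
#' differential_entropy(rnorm(10000))  # ~ 0.5 * log(2 * pi * exp(1)) = 1.4189
#' @export
differential_entropy <- function(x, floor_value = -20) {
  if (length(x) < 2) stop("need at least 2 samples")
  v <- mean((x - mean(x))^2)
  if (v <= 0) {
    warning("zero-variance input; returning floor value")
    return(floor_value)
  }
  0.5 * log(2 * pi * exp(1) * v)
}

#' Per-epoch differential-entropy feature matrix
#'
#' Entry (n, f) is the differential entropy of channel n restricted to
#' band f.
#'
#' @param epoch numeric matrix, channels x samples.
#' @param rate sampling rate in Hz.
#' @param bands named list of band intervals (default [default_bands()]).
#' @param floor_value passed to [differential_entropy()].
#' @return Numeric matrix, channels x bands, in nats.
#' @export
feature_matrix <- function(epoch, rate, bands = default_bands(),
                           floor_value = -20) {
  validate_bands(bands, rate)
  out <- matrix(NA_real_, nrow(epoch), length(bands),
                dimnames = list(rownames(epoch), names(bands)))
  for (f in seq_along(bands)) {
    for (n in seq_len(nrow(epoch))) {
      out[n, f] <- differential_entropy(
        band_filter(epoch[n, ], bands[[f]], rate), floor_value)
    }
  }
  out
}

#' Differential-entropy features for every epoch of a recording
#'
#' @param er an `epoched_recording`.
#' @param bands named list of band intervals.
#' @param normalize z-score each electrode-band feature across the
#'   recording's epochs (default TRUE; stabilizes training across
#'   subjects).
#' @return Array channels x bands x epochs, in nats (z-scored if
#'   `normalize`).
#' @export
recording_features <- function(er, bands = default_bands(),
                               normalize = TRUE) {
  stopifnot(inherits(er, "epoched_recording"))
  n_ep <- dim(er$epochs)[3]
  feats <- array(NA_real_, c(dim(er$epochs)[1], length(bands), n_ep),
                 dimnames = list(er$channel_names, names(bands), NULL))
  for (t in seq_len(n_ep))
    feats[, , t] <- feature_matrix(er$epochs[, , t], er$rate, bands)
  if (normalize) {
    for (i in seq_len(dim(feats)[1])) for (j in seq_len(dim(feats)[2])) {
      v <- feats[i, j, ]
      s <- stats::sd(v)
      feats[i, j, ] <- if (s > 0) (v - mean(v)) / s else v - mean(v)
    }
  }
  feats
}

#' Assemble temporal context blocks
#'
#' The classifier input for epoch t is the block of k+1 feature matrices
#' at epochs t-kd, t-(k-1)d, ..., t (stride d), labelled with the stage of
#' epoch t. Epochs with t <= k*d have no complete history and are dropped.
#'
#' @param feats array channels x bands x epochs
#'   (from [recording_features()]).
#' @param labels per-epoch AASM labels, length = number of epochs.
#' @param k number of past segments in the context (default 4).
#' @param d temporal context stride in epochs (default 1).
#' @return List of class `feature_contexts`: `x` array
#'   (channels x bands x Tn x n_contexts) with Tn = k+1, `y` labels,
#'   `epoch` the 1-based epoch index each context is labelled with.
#'   Empty (with a warning) when k*d >= number of epochs.
#' @export
assemble_contexts <- function(feats, labels, k = 4, d = 1) {
  stopifnot(k >= 0, d >= 1)
  n_ep <- dim(feats)[3]
  if (length(labels) != n_ep)
    stop("labels length must equal the number of epochs")
  tn <- k + 1
  first <- k * d + 1
  if (first > n_ep) {
    warning("k*d >= number of epochs; no contexts can be formed")
    return(structure(list(
      x = array(0, c(dim(feats)[1], dim(feats)[2], tn, 0)),
      y = character(0), epoch = integer(0), k = k, d = d),
      class = "feature_contexts"))
  }
  idx <- first:n_ep
  x <- array(NA_real_, c(dim(feats)[1], dim(feats)[2], tn, length(idx)))
  for (j in seq_along(idx)) {
    t <- idx[j]
    x[, , , j] <- feats[, , t - (k:0) * d]
  }
  structure(list(x = x, y = as.character(labels[idx]), epoch = idx,
                 k = k, d = d),
            class = "feature_contexts")
}

#' @export
print.feature_contexts <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf(
    "feature_contexts: %d blocks (%d electrodes x %d bands x Tn=%d), k=%d d=%d\n",
    d[4], d[1], d[2], d[3], x$k, x$d))
  if (length(x$y)) print(table(x$y))
  invisible(x)
}

#' End-to-end feature extraction for one recording
#'
#' Epochs the signal, computes differential-entropy band features,
#' harmonizes/aligns the hypnogram, optionally trims peripheral wake, and
#' assembles temporal context blocks.
#'
#' @param rec a `raw_recording`.
#' @param labels per-epoch stage labels (R&K or AASM; harmonized
#'   internally).
#' @param bands band set (default [default_bands()]).
#' @param k,d temporal context parameters (defaults 4 and 1).
#' @param normalize z-score features per recording (default TRUE).
#' @param trim_wake apply [trim_peripheral_wake()] (default FALSE: the
#'   synthetic generator produces no long peripheral wake).
#' @param margin_minutes wake margin when trimming.
#' @return A `feature_contexts` object.
#' @export
extract_features <- function(rec, labels, bands = default_bands(), k = 4,
                             d = 1, normalize = TRUE, trim_wake = FALSE,
                             margin_minutes = 30) {
  er <- epoch_signal(rec)
  n_ep <- dim(er$epochs)[3]
  h <- harmonize_labels(labels[seq_len(min(length(labels), n_ep))])
  keep <- h$kept
  lab <- h$labels
  ep_use <- keep[keep <= n_ep]
  lab <- lab[keep <= n_ep]
  if (trim_wake) {
    tr <- trim_peripheral_wake(lab, margin_minutes)
    sel <- seq.int(tr$start, length.out = max(0, tr$end - tr$start + 1))
    ep_use <- ep_use[sel]
    lab <- lab[sel]
  }
  er$epochs <- er$epochs[, , ep_use, drop = FALSE]
  feats <- recording_features(er, bands, normalize)
  assemble_contexts(feats, lab, k, d)
}
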