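# Synthetic polysomnography: a first-order Markov hypnogram over the five
# AASM stages and per-epoch EEG synthesized as band-limited random-phase
# oscillations with stage-specific band-power profiles plus broadband
# noise. The spectra are caricatures (no spindle/K-complex morphology),
# but the stage-conditional band powers — hence the differential-entropy
# features — separate the classes the way real sleep EEG does.

#' Default stage transition matrix
#'
#' Row-stochastic 5x5 matrix over (W, N1, N2, N3, R) encoding realistic
#' sleep continuity: strong self-transitions for N2/N3, wake entering
#' sleep through N1, and REM reachable only from N2. Its stationary
#' distribution is N2-heavy with scarce N1, mirroring the class imbalance
#' of public sleep archives.
#'
#' @return 5x5 matrix with rows summing to 1.
#' @export
default_transitions <- function() {
  tm <- matrix(c(
    # to:  W     N1    N2    N3    R
    0.85, 0.15, 0.00, 0.00, 0.00,  # from W
    0.10, 0.55, 0.35, 0.00, 0.00,  # from N1
    0.02, 0.02, 0.85, 0.06, 0.05,  # from N2
    0.00, 0.00, 0.12, 0.88, 0.00,  # from N3
    0.03, 0.02, 0.10, 0.00, 0.85   # from R
  ), 5, 5, byrow = TRUE, dimnames = list(stage_levels(), stage_levels()))
  tm
}

#' Default stage spectral profiles
#'
#' Relative band-power weights (delta, theta, alpha, sigma, beta), an
#' amplitude scale in microvolts, and a white-noise floor per stage:
#' wake is alpha/beta dominant, N1 theta, N2 sigma+theta (spindle band),
#' N3 high-amplitude delta, and REM low-amplitude mixed theta/beta.
#'
#' @return Named list of per-stage lists with `weights`, `amp`, `noise`.
#' @export
default_profiles <- function() {
  list(
    W = list(weights = c(delta = 0.10, theta = 0.10, alpha = 0.50,
                         sigma = 0.05, beta = 0.25), amp = 20, noise = 2),
    N1 = list(weights = c(delta = 0.20, theta = 0.60, alpha = 0.10,
                          sigma = 0.05, beta = 0.05), amp = 25, noise = 2),
    N2 = list(weights = c(delta = 0.25, theta = 0.30, alpha = 0.05,
                          sigma = 0.35, beta = 0.05), amp = 35, noise = 2),
    N3 = list(weights = c(delta = 0.75, theta = 0.15, alpha = 0.04,
                          sigma = 0.04, beta = 0.02), amp = 60, noise = 2),
    R = list(weights = c(delta = 0.10, theta = 0.50, alpha = 0.10,
                         sigma = 0.05, beta = 0.25), amp = 15, noise = 1.5)
  )
}

#' Simulation specification
#'
#' @param n_subjects number of simulated subjects (default 4).
#' @param epochs_per_subject 30-s epochs per subject (default 200).
#' @param channels electrode labels (default the six-channel F/C/O
#'   montage).
#' @param rate sampling rate, 100 or 200 Hz (default 100).
#' @param transitions 5x5 row-stochastic stage transition matrix.
#' @param profiles per-stage spectral profiles
#'   (see [default_profiles()]).
#' @param bands band intervals matching the profile weights.
#' @param seed RNG seed; all simulator randomness flows from it.
#' @return List of class `sim_spec`.
#' @export
sim_spec <- function(n_subjects = 4, epochs_per_subject = 200,
                     channels = c("F3", "F4", "C3", "C4", "O1", "O2"),
                     rate = 100, transitions = default_transitions(),
                     profiles = default_profiles(),
                     bands = default_bands(), seed = 1) {
  if (!rate %in% c(100, 200)) stop("rate must be 100 or 200 Hz")
  if (any(abs(rowSums(transitions) - 1) > 1e-8))
    stop("transition matrix rows must sum to 1")
  validate_bands(bands, rate)
  structure(list(n_subjects = n_subjects,
                 epochs_per_subject = epochs_per_subject,
                 channels = channels, rate = rate,
                 transitions = transitions, profiles = profiles,
                 bands = bands, seed = seed),
            class = "sim_spec")
}

#' Sample a hypnogram from the Markov stage model
#'
#' @param n_epochs number of 30-s epochs.
#' @param transitions 5x5 row-stochastic matrix over
#'   `stage_levels()`.
#' @param init initial stage (default "W").
#' @return Character vector of AASM stage labels.
#' @export
sample_hypnogram <- function(n_epochs,
                             transitions = default_transitions(),
                             init = "W") {
  lv <- stage_levels()
  out <- character(n_epochs)
  s <- match(init, lv)
  for (t in seq_len(n_epochs)) {
    out[t] <- lv[s]
    s <- sample.int(5, 1, prob = transitions[s, ])
  }
  out
}

#' Stationary distribution of a stage transition matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1,
#' normalized to sum to 1.
#'
#' @param transitions row-stochastic matrix.
#' @return Named probability vector.
#' @export
stationary_distribution <- function(transitions = default_transitions()) {
  e <- eigen(t(transitions))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  stats::setNames(v / sum(v), rownames(transitions))
}

#' Synthesize one 30-s EEG epoch for a stage
#'
#' Sum over bands of random-phase sinusoids (frequencies drawn uniformly
#' inside each band; independent phases per channel) with amplitudes
#' proportional to the square root of the stage's band weights, plus
#' white noise at the stage's noise floor.
#'
#' @param stage AASM stage label.
#' @param spec a [sim_spec()].
#' @param n_osc sinusoids per band (default 3).
#' @return Matrix channels x (30 * rate) in microvolts.
#' @export
synth_epoch <- function(stage, spec = sim_spec(), n_osc = 3) {
  pr <- spec$profiles[[stage]]
  if (is.null(pr)) stop("no profile for stage ", stage)
  q <- length(spec$channels)
  ns <- 30 * spec$rate
  tgrid <- seq_len(ns) / spec$rate
  x <- matrix(stats::rnorm(q * ns, sd = pr$noise), q, ns)
  w <- pr$weights / sum(pr$weights)
  for (f in seq_along(spec$bands)) {
    a <- pr$amp * sqrt(w[f]) / sqrt(n_osc)
    if (a == 0) next
    freqs <- stats::runif(n_osc, spec$bands[[f]][1], spec$bands[[f]][2])
    for (o in seq_len(n_osc)) {
      ph <- stats::runif(q, 0, 2 * pi)
      x <- x + a * sin(outer(ph, 2 * pi * freqs[o] * tgrid, "+"))
    }
  }
  rownames(x) <- spec$channels
  x
}

#' Simulate a polysomnography cohort
#'
#' Draws one hypnogram and the matching multi-channel EEG per subject.
#' Fully deterministic given `spec$seed`.
#'
#' @param spec a [sim_spec()].
#' @return List of class `sim_psg`: per subject a list with `recording`
#'   (a `raw_recording`), `labels`, and `subject_id`.
#' @export
simulate_psg <- function(spec = sim_spec()) {
  set.seed(spec$seed)
  out <- lapply(seq_len(spec$n_subjects), function(s) {
    labels <- sample_hypnogram(spec$epochs_per_subject, spec$transitions)
    sig <- matrix(0, length(spec$channels),
                  spec$epochs_per_subject * 30 * spec$rate)
    ns <- 30 * spec$rate
    for (t in seq_along(labels))
      sig[, (t - 1) * ns + seq_len(ns)] <- synth_epoch(labels[t], spec)
    sid <- sprintf("sim%02d", s)
    list(recording = raw_recording(sig, spec$rate, spec$channels,
                                   subject_id = sid),
         labels = labels, subject_id = sid)
  })
  structure(out, class = "sim_psg", spec = spec)
}

#' Write a simulated cohort to disk as EDF + hypnogram TSV
#'
#' One EDF file and one TSV hypnogram per subject; round-trips through
#' [read_edf()] / [read_hypnogram()].
#'
#' @param sim a `sim_psg` from [simulate_psg()] (or a `sim_spec`, which
#'   is simulated first).
#' @param dir output directory (created if needed).
#' @param edf_annotations also embed the hypnogram as EDF+ annotations
#'   (default TRUE).
#' @return Data frame with columns `subject_id`, `edf`, `hypnogram`.
#' @export
write_dataset <- function(sim, dir, edf_annotations = TRUE) {
  if (inherits(sim, "sim_spec")) sim <- simulate_psg(sim)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(sim, function(s) {
    edf <- file.path(dir, paste0(s$subject_id, ".edf"))
    tsv <- file.path(dir, paste0(s$subject_id, "_hypnogram.tsv"))
    ann <- NULL
    if (edf_annotations) {
      r <- rle(s$labels)
      ends <- cumsum(r$lengths)
      ann <- data.frame(onset = 30 * (ends - r$lengths),
                        duration = 30 * r$lengths,
                        text = paste("Sleep stage", r$values))
    }
    write_edf(s$recording, edf, annotations = ann)
    write_hypnogram_tsv(s$labels, tsv)
    data.frame(subject_id = s$subject_id, edf = edf, hypnogram = tsv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Feature contexts for a whole simulated cohort
#'
#' Convenience wrapper: extracts differential-entropy contexts for every
#' simulated subject and concatenates them with a subject index, ready
#' for [subject_folds()] and [stgcn()].
#'
#' @param sim a `sim_psg`.
#' @param k,d temporal context parameters.
#' @param normalize per-recording z-scoring (default TRUE).
#' @return List with `x` (electrodes x bands x Tn x total samples), `y`,
#'   `subject` (per-sample subject ids).
#' @export
cohort_features <- function(sim, k = 4, d = 1, normalize = TRUE) {
  spec <- attr(sim, "spec")
  parts <- lapply(sim, function(s) {
    fc <- extract_features(s$recording, s$labels, bands = spec$bands,
                           k = k, d = d, normalize = normalize)
    list(x = fc$x, y = fc$y,
         subject = rep(s$subject_id, length(fc$y)))
  })
  x <- array(0, c(dim(parts[[1]]$x)[1:3],
                  sum(vapply(parts, function(p) dim(p$x)[4], 1))))
  off <- 0
  for (p in parts) {
    n <- dim(p$x)[4]
    if (n > 0) x[, , , off + seq_len(n)] <- p$x
    off <- off + n
  }
  list(x = x, y = unlist(lapply(parts, `[[`, "y")),
       subject = unlist(lapply(parts, `[[`, "subject")))
}
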