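#' Default hypnogram label aliases
#'
#' Maps the label strings found in public hypnograms (EDF+ annotation texts
#' such as "Sleep stage W", "Sleep stage 1", "Movement time", and bare
#' R&K/AASM codes) onto the canonical vocabulary
#' W/S1/S2/S3/S4/REM/MOVEMENT/UNKNOWN plus the AASM codes N1/N2/N3/R.
#' Matching is case-insensitive; users can extend or override the table.
#'
#' @return Named character vector: names are lower-case input strings,
#'   values canonical labels.
#' @export
label_aliases <- function() {
  c("w" = "W", "wake" = "W", "sleep stage w" = "W",
    "s1" = "S1", "stage 1" = "S1", "sleep stage 1" = "S1",
    "s2" = "S2", "stage 2" = "S2", "sleep stage 2" = "S2",
    "s3" = "S3", "stage 3" = "S3", "sleep stage 3" = "S3",
    "s4" = "S4", "stage 4" = "S4", "sleep stage 4" = "S4",
    "rem" = "REM", "sleep stage r" = "REM",
    "n1" = "N1", "sleep stage n1" = "N1",
    "n2" = "N2", "sleep stage n2" = "N2",
    "n3" = "N3", "sleep stage n3" = "N3",
    "r" = "R",
    "movement" = "MOVEMENT", "movement time" = "MOVEMENT",
    "unknown" = "UNKNOWN", "?" = "UNKNOWN", "sleep stage ?" = "UNKNOWN")
}

rk_levels <- function() c("W", "S1", "S2", "S3", "S4", "REM",
                          "MOVEMENT", "UNKNOWN")

#' Canonicalize raw hypnogram label strings
#'
#' @param labels character vector of raw label strings.
#' @param aliases alias table as returned by [label_aliases()].
#' @return Character vector of canonical labels.
#' @export
canonical_labels <- function(labels, aliases = label_aliases()) {
  key <- tolower(trimws(as.character(labels)))
  out <- unname(aliases[key])
  bad <- is.na(out)
  if (any(bad))
    stop("unrecognized stage label(s): ",
         paste(unique(labels[bad]), collapse = ", "))
  out
}

#' Harmonize R&K hypnogram labels to the 5-class AASM scheme
#'
#' Applies the standard merge used when re-scoring R&K hypnograms under
#' AASM rules: S1 becomes N1, S2 becomes N2, S3 and S4 are combined into
#' N3, REM becomes R and W stays W. MOVEMENT and UNKNOWN epochs carry no
#' stage and are removed; their positions are excluded from the returned
#' index list. Input already in the AASM vocabulary passes through
#' unchanged (the operation is idempotent).
#'
#' @param labels character vector of per-epoch labels (R&K or AASM codes;
#'   raw annotation strings are accepted and canonicalized first).
#' @param aliases alias table for canonicalization.
#' @return List with `labels` (AASM labels of the kept epochs) and `kept`
#'   (1-based indices into the input of the epochs that were kept).
#' @examples
#' harmonize_labels(c("W", "S1", "S2", "S3", "S4", "REM"))$labels
#' @export
harmonize_labels <- function(labels, aliases = label_aliases()) {
  lab <- canonical_labels(labels, aliases)
  map <- c(W = "W", S1 = "N1", S2 = "N2", S3 = "N3", S4 = "N3", REM = "R",
           N1 = "N1", N2 = "N2", N3 = "N3", R = "R")
  keep <- !(lab %in% c("MOVEMENT", "UNKNOWN"))
  out <- unname(map[lab[keep]])
  list(labels = out, kept = which(keep))
}

#' Trim peripheral wake from a hypnogram
#'
#' Retains the sleep period plus a fixed wake margin on both sides:
#' epochs from (first non-W epoch minus the margin) to (last non-W epoch
#' plus the margin), clamped to the record. This is the usual preprocessing
#' for ambulatory recordings where long wake stretches surround the night.
#'
#' @param labels character vector of AASM labels.
#' @param margin_minutes wake margin retained on each side, in minutes
#'   (default 30).
#' @param epoch_seconds epoch length in seconds (default 30).
#' @return List with `start` and `end` (1-based inclusive epoch indices of
#'   the kept range) and `all_wake` (TRUE when the record contains no sleep,
#'   in which case the range is empty: start = 1, end = 0).
#' @examples
#' lab <- c(rep("W", 10), rep("N2", 5), rep("W", 10))
#' trim_peripheral_wake(lab, margin_minutes = 1)
#' @export
trim_peripheral_wake <- function(labels, margin_minutes = 30,
                                 epoch_seconds = 30) {
  labels <- as.character(labels)
  sleep <- which(labels != "W")
  if (!length(sleep)) {
    warning("record contains no sleep epochs; empty range returned")
    return(list(start = 1L, end = 0L, all_wake = TRUE))
  }
  margin <- as.integer(round(margin_minutes * 60 / epoch_seconds))
  list(start = max(1L, min(sleep) - margin),
       end = min(length(labels), max(sleep) + margin),
       all_wake = FALSE)
}
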