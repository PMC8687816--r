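#' Construct an EEG recording
#'
#' A recording is one subject-session multichannel signal: a channels x
#' time-points numeric matrix with ordered channel names and a sample rate.
#' Values keep whatever physical units they were read in (typically
#' microvolts from EDF).
#'
#' @param signal numeric matrix, channels x time-points.
#' @param channel_names character vector of electrode labels, one per row of
#'   `signal`; normalized to canonical upper-case 10-10 labels.
#' @param sample_rate sampling frequency in Hz (> 0).
#' @param subject_id opaque subject label.
#' @param session session tag, `"EO"` (eyes open) or `"EC"` (eyes closed).
#' @return an object of class `eeg_recording`.
#' @export
recording <- function(signal, channel_names, sample_rate, subject_id,
                      session = c("EO", "EC")) {
  session <- match.arg(session)
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("`signal` must be a numeric matrix (channels x time-points)")
  channel_names <- normalize_channel_names(channel_names)
  if (nrow(signal) != length(channel_names))
    stop(sprintf("signal has %d rows but %d channel names given",
                 nrow(signal), length(channel_names)))
  if (anyDuplicated(channel_names))
    stop("duplicate channel names after normalization: ",
         paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a single positive number")
  if (ncol(signal) < 1L) stop("recording must contain at least one time-point")
  rownames(signal) <- channel_names
  structure(list(subject_id = as.character(subject_id),
                 session = session,
                 channel_names = channel_names,
                 sample_rate = sample_rate,
                 signal = signal),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s, session %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$session, nrow(x$signal), ncol(x$signal),
              x$sample_rate, ncol(x$signal) / x$sample_rate))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$signal)

n_samples <- function(rec) ncol(rec$signal)

#' Normalize electrode labels to canonical 10-10 form
#'
#' Strips non-alphanumeric characters (PhysioNet EDF labels carry trailing
#' dots, e.g. `"Fc5."`) and upper-cases, so that `"Fc5."`, `"FC5 "` and
#' `"fc5"` all map to `"FC5"`.
#'
#' @param x character vector of raw labels.
#' @return character vector of canonical labels.
#' @export
normalize_channel_names <- function(x) {
  toupper(gsub("[^A-Za-z0-9]", "", as.character(x)))
}
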