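#' Synthetic resting-state cohort specification
#'
#' Generates multichannel recordings under the linear mixing model the
#' network is built around: each synthetic subject owns a set of latent
#' oscillatory sources S (sinusoids at subject-specific frequencies with
#' broadband source noise) and a subject-specific mixing matrix A, and the
#' observed channels are X = AS plus white sensor noise. Identity is thus
#' encoded both in the spectral content of the sources and in their spatial
#' projection — exactly the structure a learnable channel-unmixing first
#' stage can exploit. Across the two sessions of one subject the identity
#' carriers (frequencies, amplitudes, A) are held fixed while phases and
#' noise are redrawn.
#'
#' Defaults model a small enrollment study: 8 subjects, 14 channels, 60 s
#' at 160 Hz, 4 sources with center frequencies uniform in 4-30 Hz
#' (theta-beta band, safely below Nyquist), unit-scale mixing
#' (entries N(0, 1)/sqrt(n_sources)), source broadband noise at 0.2 of unit
#' amplitude and sensor noise at 0.25 of the clean-signal RMS.
#'
#' @param n_subjects number of synthetic subjects.
#' @param n_channels observed channels; channel names are taken from the
#'   matching montage (14/32/64) or the first labels of the 64-channel set.
#' @param n_sources latent sources per subject.
#' @param duration_s recording length in seconds.
#' @param sample_rate sampling rate in Hz.
#' @param freq_range source center-frequency band in Hz (must stay below
#'   Nyquist).
#' @param amp_range per-source amplitude range.
#' @param source_noise per-source broadband noise scale.
#' @param noise_sd additive white sensor noise, as a fraction of the clean
#'   mixed-signal RMS.
#' @param seed master seed; all randomness derives from it per
#'   (subject, session) so fixtures are reproducible regardless of
#'   generation order.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 8L, n_channels = 14L, n_sources = 4L,
                           duration_s = 60, sample_rate = 160,
                           freq_range = c(4, 30), amp_range = c(0.5, 1.5),
                           source_noise = 0.2, noise_sd = 0.25, seed = 1L) {
  stopifnot(n_subjects >= 1, n_channels >= 1, n_sources >= 1,
            duration_s > 0, sample_rate > 0, noise_sd >= 0,
            source_noise >= 0, length(freq_range) == 2L,
            freq_range[1] > 0, freq_range[1] <= freq_range[2])
  if (freq_range[2] >= sample_rate / 2)
    stop(sprintf("source frequencies up to %g Hz would alias at %g Hz sampling (Nyquist %g Hz)",
                 freq_range[2], sample_rate, sample_rate / 2))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_channels = as.integer(n_channels),
                 n_sources = as.integer(n_sources),
                 duration_s = duration_s, sample_rate = sample_rate,
                 freq_range = freq_range, amp_range = amp_range,
                 source_noise = source_noise, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# deterministic sub-seed per (subject, session); kept inside 32-bit range
.derive_seed <- function(seed, subject_index, session) {
  sess <- match(session, c("EO", "EC"))
  as.integer((as.double(seed) * 48271 + subject_index * 9973 + sess * 7919) %%
               2147483647)
}

# channel labels for a synthetic montage of the given width
.synthetic_channels <- function(n_channels) {
  tbl <- .montages()
  if (n_channels == 14L) return(tbl$EPOC14)
  if (n_channels == 32L) return(tbl$FLEX32)
  if (n_channels <= 64L) return(tbl$FULL64[seq_len(n_channels)])
  stop("at most 64 synthetic channels are supported")
}

#' Generate one synthetic recording
#'
#' Deterministic under `(spec$seed, subject_index, session)`. Subject-level
#' parameters (source frequencies, amplitudes, mixing matrix) are redrawn
#' identically for both sessions of a subject; phases and noise are
#' session-specific.
#'
#' @param spec a [synthetic_spec()].
#' @param subject_index 1-based subject number (`<= spec$n_subjects`).
#' @param session `"EO"` or `"EC"`.
#' @return an `eeg_recording` of shape `n_channels` x
#'   `duration_s * sample_rate`, in microvolt-scale units.
#' @export
generate_recording <- function(spec, subject_index, session = "EO") {
  stopifnot(inherits(spec, "synthetic_spec"),
            subject_index >= 1, subject_index <= spec$n_subjects,
            session %in% c("EO", "EC"))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  # subject-level identity parameters: shared across sessions
  set.seed(.derive_seed(spec$seed, subject_index, "EO") %/% 4L)
  freqs <- runif(spec$n_sources, spec$freq_range[1], spec$freq_range[2])
  amps <- runif(spec$n_sources, spec$amp_range[1], spec$amp_range[2])
  A <- matrix(rnorm(spec$n_channels * spec$n_sources) / sqrt(spec$n_sources),
              nrow = spec$n_channels)

  # session-level realization
  set.seed(.derive_seed(spec$seed, subject_index, session))
  T <- as.integer(round(spec$duration_s * spec$sample_rate))
  t <- (seq_len(T) - 1) / spec$sample_rate
  phases <- runif(spec$n_sources, 0, 2 * pi)
  S <- matrix(0, nrow = spec$n_sources, ncol = T)
  for (s in seq_len(spec$n_sources)) {
    S[s, ] <- amps[s] * sin(2 * pi * freqs[s] * t + phases[s]) +
      spec$source_noise * rnorm(T)
  }
  X <- A %*% S
  if (spec$noise_sd > 0) {
    rms <- sqrt(mean(X^2))
    X <- X + spec$noise_sd * rms * matrix(rnorm(length(X)), nrow = nrow(X))
  }
  # microvolt-scale physical units
  X <- 20 * X
  rec <- recording(X, .synthetic_channels(spec$n_channels),
                   spec$sample_rate, sprintf("S%03d", subject_index), session)
  attr(rec, "sources") <- list(freqs = freqs, amps = amps, phases = phases,
                               mixing = A)
  rec
}

#' Generate a synthetic cohort
#'
#' One recording per subject per requested session, each with distinct
#' subject-level mixing and spectra. Optionally exports the cohort as EDF
#' files laid out like the PhysioNet distribution
#' (`S001/S001R01.edf` = eyes-open, `R02` = eyes-closed).
#'
#' @param spec a [synthetic_spec()].
#' @param sessions character subset of `c("EO", "EC")`.
#' @param out_dir optional directory for EDF export.
#' @return list of `eeg_recording` (subject-major order). When exported,
#'   the file paths are attached as attribute `"paths"`.
#' @export
generate_cohort <- function(spec, sessions = "EO", out_dir = NULL) {
  stopifnot(all(sessions %in% c("EO", "EC")))
  recs <- list(); paths <- character(0)
  for (i in seq_len(spec$n_subjects)) {
    for (sess in sessions) {
      rec <- generate_recording(spec, i, sess)
      recs[[length(recs) + 1L]] <- rec
      if (!is.null(out_dir)) {
        sdir <- file.path(out_dir, sprintf("S%03d", i))
        dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
        p <- file.path(sdir, sprintf("S%03dR%02d.edf", i,
                                     match(sess, c("EO", "EC"))))
        write_edf(rec, p)
        paths <- c(paths, p)
      }
    }
  }
  if (!is.null(out_dir)) attr(recs, "paths") <- paths
  recs
}
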