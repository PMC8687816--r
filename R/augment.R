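#' Sliding-window specification
#'
#' Governs segmentation of a recording into fixed-size samples: a window of
#' `length_s` seconds advanced by `stride_s` seconds. `stride_s = length_s`
#' is the fixed (non-overlapping) window; `stride_s < length_s` produces
#' overlapping windows (the "sliding ratio" reported alongside results is
#' `stride_s / length_s`, e.g. ratio 0.5 = 50% overlap). The default is the
#' 0.5 s window with 0.25 s stride selected for the identification system.
#'
#' @param length_s window duration in seconds (> 0).
#' @param stride_s hop between window starts in seconds; `0 < stride_s <=
#'   length_s`.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(length_s = 0.5, stride_s = length_s / 2) {
  if (!is.numeric(length_s) || length_s <= 0)
    stop("`length_s` must be > 0")
  if (!is.numeric(stride_s) || stride_s <= 0 || stride_s > length_s)
    stop("`stride_s` must satisfy 0 < stride_s <= length_s")
  structure(list(length_s = length_s, stride_s = stride_s),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %g s window, %g s stride (sliding ratio %g)\n",
              x$length_s, x$stride_s, x$stride_s / x$length_s))
  invisible(x)
}

# window / stride lengths in samples; must be whole numbers at this rate
.window_samples <- function(spec, sample_rate) {
  L <- spec$length_s * sample_rate
  S <- spec$stride_s * sample_rate
  if (abs(L - round(L)) > 1e-9 || abs(S - round(S)) > 1e-9)
    stop(sprintf("window %g s / stride %g s are not whole samples at %g Hz",
                 spec$length_s, spec$stride_s, sample_rate))
  c(L = as.integer(round(L)), S = as.integer(round(S)))
}

# 0-based start offsets of every complete window in [0, T)
.segment_starts <- function(T, L, S) {
  if (T < L) return(integer(0))
  n <- (T - L) %/% S + 1L
  (seq_len(n) - 1L) * S
}

#' Number of sliding windows in a span
#'
#' `floor((T - L) / S) + 1` complete windows fit in `T` samples (0 if
#' `T < L`): windows start at offsets `0, S, 2S, ...` and trailing data that
#' does not fill a window is discarded.
#'
#' @param duration_s span duration in seconds.
#' @param spec a [window_spec()].
#' @param sample_rate sampling rate in Hz.
#' @param n_recordings multiply the per-span count (e.g. number of subjects).
#' @return integer segment count.
#' @export
#' @examples
#' # 48 s of 160 Hz signal, 0.5 s window, 0.25 s stride, 109 subjects
#' segment_count(48, window_spec(0.5, 0.25), 160, n_recordings = 109)
segment_count <- function(duration_s, spec, sample_rate, n_recordings = 1L) {
  ls <- .window_samples(spec, sample_rate)
  T <- duration_s * sample_rate
  if (abs(T - round(T)) > 1e-9)
    stop("duration_s is not a whole number of samples at this rate")
  length(.segment_starts(as.integer(round(T)), ls["L"], ls["S"])) *
    n_recordings
}

#' Segment one recording into sliding windows
#'
#' Cuts every complete window `[kS, kS + L)` from the recording (trailing
#' remainder discarded) and returns the windows as segments. Each segment's
#' `data` is a Points x Channels matrix — the transpose of the channels x
#' time slice — which is the input plane the network consumes (temporal
#' axis first).
#'
#' @param rec an [recording()].
#' @param spec a [window_spec()].
#' @param offset sample offset (0-based) added to every window start, used
#'   when segmenting a sub-range of a recording.
#' @return list of `eeg_segment` objects (empty, with a warning, if the
#'   recording is shorter than one window).
#' @export
segment_recording <- function(rec, spec, offset = 0L) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "window_spec"))
  ls <- .window_samples(spec, rec$sample_rate)
  starts <- .segment_starts(n_samples(rec), ls["L"], ls["S"])
  if (length(starts) == 0L)
    warning(sprintf("recording %s (%d samples) is shorter than one %d-sample window",
                    rec$subject_id, n_samples(rec), ls["L"]))
  lapply(starts, function(s0)
    structure(list(data = t(rec$signal[, (s0 + 1):(s0 + ls["L"]), drop = FALSE]),
                   subject_id = rec$subject_id,
                   session = rec$session,
                   start_sample = as.integer(s0 + offset)),
              class = "eeg_segment"))
}

#' Build a labeled segment dataset from recordings
#'
#' Segments each supplied sample range of each recording independently —
#' windows never straddle a range boundary, which is what keeps overlapping
#' windows from leaking across a train/test split — and assigns dense
#' 0-based integer labels by lexicographically sorted subject id.
#'
#' @param recs list of [recording()] objects.
#' @param spec a [window_spec()].
#' @param ranges `NULL` to segment whole recordings, or a data frame with
#'   columns `rec_index`, `start`, `end` (0-based half-open sample
#'   intervals); intervals for one recording must be disjoint.
#' @param label_map optional named integer vector (subject id -> 0-based
#'   class index) to reuse an existing enrollment's labeling.
#' @return an object of class `segmented_dataset`: `x` — a P x C x N array
#'   of segment planes; `meta` — a data frame with `subject_id`, `session`,
#'   `start_sample`, `label` per segment; `label_map`; `window`;
#'   `sample_rate`; `channel_names`.
#' @export
build_dataset <- function(recs, spec, ranges = NULL, label_map = NULL) {
  if (inherits(recs, "eeg_recording")) recs <- list(recs)
  stopifnot(length(recs) > 0L, inherits(spec, "window_spec"))
  rates <- unique(vapply(recs, function(r) r$sample_rate, 0))
  if (length(rates) != 1L)
    stop("recordings have inconsistent sample rates: ",
         paste(rates, collapse = ", "))
  chans <- lapply(recs, function(r) r$channel_names)
  if (length(unique(chans)) != 1L)
    stop("recordings have inconsistent channel sets; apply a montage first")

  if (is.null(ranges)) {
    ranges <- data.frame(rec_index = seq_along(recs), start = 0L,
                         end = vapply(recs, n_samples, 0L))
  }
  stopifnot(all(c("rec_index", "start", "end") %in% names(ranges)))
  for (ri in unique(ranges$rec_index)) {
    rr <- ranges[ranges$rec_index == ri, , drop = FALSE]
    rr <- rr[order(rr$start), , drop = FALSE]
    if (any(rr$start < 0) || any(rr$end > n_samples(recs[[ri]])))
      stop("range outside recording bounds for recording ", ri)
    if (nrow(rr) > 1L && any(rr$start[-1] < rr$end[-nrow(rr)]))
      stop("overlapping ranges for recording ", ri)
  }

  ls <- .window_samples(spec, rates)
  L <- ls[["L"]]

  if (is.null(label_map)) {
    subjects <- sort(unique(vapply(recs, function(r) r$subject_id, "")))
    label_map <- stats::setNames(seq_along(subjects) - 1L, subjects)
  }

  xs <- list(); meta <- list()
  for (i in seq_len(nrow(ranges))) {
    rec <- recs[[ranges$rec_index[i]]]
    starts <- .segment_starts(ranges$end[i] - ranges$start[i], L, ls[["S"]])
    if (length(starts) == 0L) next
    abs_starts <- starts + ranges$start[i]
    # one aperm per range: (C, L, n) slab -> (L, C, n)
    idx <- outer(seq_len(L), abs_starts, `+`)  # L x n sample indices (1-based)
    slab <- array(rec$signal[, as.vector(idx)], dim = c(nrow(rec$signal), L,
                                                        length(starts)))
    xs[[length(xs) + 1L]] <- aperm(slab, c(2, 1, 3))
    meta[[length(meta) + 1L]] <- data.frame(
      subject_id = rec$subject_id, session = rec$session,
      start_sample = as.integer(abs_starts),
      label = unname(label_map[rec$subject_id]))
  }
  n_tot <- sum(vapply(xs, function(a) dim(a)[3], 0))
  P <- L; C <- length(recs[[1]]$channel_names)
  x <- array(0, dim = c(P, C, n_tot))
  at <- 0L
  for (a in xs) {
    n <- dim(a)[3]
    if (n > 0) x[, , (at + 1):(at + n)] <- a
    at <- at + n
  }
  meta <- if (length(meta)) do.call(rbind, meta) else
    data.frame(subject_id = character(), session = character(),
               start_sample = integer(), label = integer())
  if (any(is.na(meta$label)))
    stop("segments from subjects absent from label_map: ",
         paste(unique(meta$subject_id[is.na(meta$label)]), collapse = ", "))
  structure(list(x = x, meta = meta, label_map = label_map, window = spec,
                 sample_rate = rates, channel_names = recs[[1]]$channel_names),
            class = "segmented_dataset")
}

#' @export
print.segmented_dataset <- function(x, ...) {
  cat(sprintf("<segmented_dataset> %d segments (%d x %d), %d subjects, %g s window / %g s stride\n",
              n_segments(x), dim(x$x)[1], dim(x$x)[2], length(x$label_map),
              x$window$length_s, x$window$stride_s))
  invisible(x)
}

#' Number of segments in a dataset
#' @param ds a `segmented_dataset`.
#' @export
n_segments <- function(ds) dim(ds$x)[3]

#' Concatenate segment datasets
#'
#' Pools segments (e.g. the eyes-open and eyes-closed sessions of a cohort)
#' into one dataset; all parts must share geometry and label map.
#'
#' @param ... `segmented_dataset` objects.
#' @return a `segmented_dataset`.
#' @export
bind_datasets <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "segmented_dataset"))
    parts <- parts[[1]]
  stopifnot(length(parts) >= 1L)
  ref <- parts[[1]]
  for (p in parts[-1]) {
    stopifnot(identical(dim(p$x)[1:2], dim(ref$x)[1:2]),
              identical(p$label_map, ref$label_map))
  }
  x <- array(0, dim = c(dim(ref$x)[1:2], sum(vapply(parts, n_segments, 0))))
  at <- 0L
  for (p in parts) {
    n <- n_segments(p)
    if (n > 0) x[, , (at + 1):(at + n)] <- p$x
    at <- at + n
  }
  structure(list(x = x, meta = do.call(rbind, lapply(parts, `[[`, "meta")),
                 label_map = ref$label_map, window = ref$window,
                 sample_rate = ref$sample_rate,
                 channel_names = ref$channel_names),
            class = "segmented_dataset")
}
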