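#' Per-subject signal statistics
#'
#' Computes the mean and standard deviation pooled over *all* values — every
#' channel, every time-point, every provided session — of one subject's
#' recordings. These are the statistics of the subject-wise Z-score
#' standardization
#' \deqn{\mathrm{Output}_{i,j} = (\mathrm{Input}_{i,j} - \mu)/\sigma ,}
#' computed for each subject separately. The standard deviation is the
#' population (divide-by-N) form; at recording scale (N in the hundreds of
#' thousands) the Bessel correction would be immaterial, but fixing the
#' convention keeps runs reproducible.
#'
#' @param recs a single [recording()] or a list of recordings, all from the
#'   same subject.
#' @return an object of class `subject_stats`: list with `subject_id`, `mu`,
#'   `sigma`.
#' @export
compute_stats <- function(recs) {
  if (inherits(recs, "eeg_recording")) recs <- list(recs)
  if (length(recs) == 0L) stop("no recordings supplied")
  stopifnot(all(vapply(recs, inherits, TRUE, "eeg_recording")))
  ids <- unique(vapply(recs, function(r) r$subject_id, ""))
  if (length(ids) != 1L)
    stop("recordings from multiple subjects supplied: ",
         paste(ids, collapse = ", "))
  pool <- unlist(lapply(recs, function(r) as.vector(r$signal)),
                 use.names = FALSE)
  if (length(pool) == 0L) stop("recordings contain no samples")
  mu <- mean(pool)
  sigma <- sqrt(mean((pool - mu)^2))
  structure(list(subject_id = ids, mu = mu, sigma = sigma),
            class = "subject_stats")
}

#' @export
print.subject_stats <- function(x, ...) {
  cat(sprintf("<subject_stats> %s: mu = %.6g, sigma = %.6g\n",
              x$subject_id, x$mu, x$sigma))
  invisible(x)
}

#' Z-score standardize a recording
#'
#' Applies `(x - mu) / sigma` elementwise with a subject's pooled
#' statistics. Shape, channel names and sample rate are unchanged. No
#' filtering, artifact rejection or re-referencing is performed anywhere in
#' the pipeline: the raw signal is preserved apart from this affine scaling.
#'
#' @param rec an [recording()].
#' @param stats a `subject_stats` from [compute_stats()]; defaults to the
#'   recording's own statistics.
#' @return a standardized `eeg_recording`.
#' @export
standardize <- function(rec, stats = compute_stats(rec)) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(stats, "subject_stats"))
  if (stats$sigma <= 0)
    stop("cannot standardize: sigma = 0 (constant/degenerate recording for subject ",
         stats$subject_id, ")")
  out <- rec
  out$signal <- (rec$signal - stats$mu) / stats$sigma
  out
}

#' Invert a standardization
#'
#' @param rec a standardized recording.
#' @param stats the `subject_stats` that produced it.
#' @return the recording on its original scale.
#' @export
unstandardize <- function(rec, stats) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(stats, "subject_stats"))
  out <- rec
  out$signal <- rec$signal * stats$sigma + stats$mu
  out
}

#' Serialize / restore subject statistics as JSON
#'
#' Enrollment persistence: statistics computed at enrollment must be reused
#' verbatim at identification time.
#'
#' @param stats a `subject_stats` or list of them.
#' @param path file path.
#' @name stats_json
#' @export
write_stats_json <- function(stats, path) {
  if (inherits(stats, "subject_stats")) stats <- list(stats)
  jsonlite::write_json(lapply(stats, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname stats_json
#' @export
read_stats_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(raw)), function(i)
    structure(list(subject_id = raw$subject_id[i], mu = raw$mu[i],
                   sigma = raw$sigma[i]), class = "subject_stats"))
}
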