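#' Named electrode montages
#'
#' A montage is a named, ordered subset of the 64 scalp electrodes of the
#' 10-10 system used by the BCI2000 recording cap:
#'
#' * `EPOC14` — the 14 saline electrodes of the EMOTIV EPOC X consumer
#'   headset, all present in the 64-channel cap.
#' * `FLEX32` — a 32-electrode layout modeled on the EMOTIV EPOC Flex kit,
#'   with the four positions absent from the 64-channel cap reselected to
#'   FT7, TP7, TP8 and FT8.
#' * `FULL64` — the full 64-channel cap in its native file order.
#'
#' The label lists ship as a plain-text JSON asset
#' (`system.file("extdata/montages.json", package = "eegid")`).
#'
#' @param name one of `"EPOC14"`, `"FLEX32"`, `"FULL64"`.
#' @return an object of class `eeg_montage`: list with `name` and ordered
#'   `channels`.
#' @export
#' @examples
#' montage("EPOC14")$channels
montage <- function(name = c("EPOC14", "FLEX32", "FULL64")) {
  name <- match.arg(name)
  structure(list(name = name, channels = .montages()[[name]]),
            class = "eeg_montage")
}

.montage_cache <- new.env(parent = emptyenv())

.montages <- function() {
  if (is.null(.montage_cache$tbl)) {
    path <- system.file("extdata", "montages.json", package = "eegid",
                        mustWork = TRUE)
    .montage_cache$tbl <- lapply(jsonlite::read_json(path),
                                 function(x) unlist(x, use.names = FALSE))
  }
  .montage_cache$tbl
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %s (%d channels): %s\n", x$name,
              length(x$channels), paste(x$channels, collapse = " ")))
  invisible(x)
}

#' Restrict a recording to a montage
#'
#' Returns a recording whose rows are exactly the montage's channels, in the
#' montage's declared order (not the file's), so the channel-mixing layer's
#' input dimensions are assigned identically across files. Retained samples
#' are copied bit-exactly; the time dimension is untouched.
#'
#' @param rec an [recording()].
#' @param mont an [montage()], or a montage name.
#' @return an `eeg_recording` with `length(mont$channels)` rows.
#' @export
select_channels <- function(rec, mont) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.character(mont)) mont <- montage(mont)
  stopifnot(inherits(mont, "eeg_montage"))
  missing <- setdiff(mont$channels, rec$channel_names)
  if (length(missing) > 0L)
    stop(sprintf("recording %s lacks montage %s channel(s): %s",
                 rec$subject_id, mont$name, paste(missing, collapse = ", ")))
  idx <- match(mont$channels, rec$channel_names)
  out <- rec
  out$signal <- rec$signal[idx, , drop = FALSE]
  out$channel_names <- mont$channels
  rownames(out$signal) <- mont$channels
  out
}
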