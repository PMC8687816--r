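#' Temporal hold-out split
#'
#' Per recording: the first `train_s` seconds are the training interval and
#' the following `test_s` seconds the testing interval (the reference
#' protocol uses 48 s / 12 s of the 60 s resting sessions). Windowing is
#' performed after splitting, so no window straddles the boundary.
#'
#' @param recs list of [recording()] objects.
#' @param train_s training span in seconds.
#' @param test_s testing span in seconds.
#' @return a `split_plan`: data frame with columns `rec_index`,
#'   `subject_id`, `session`, `role` (`"train"`/`"test"`), `start`, `end`
#'   (0-based half-open sample intervals).
#' @export
make_holdout_split <- function(recs, train_s = 48, test_s = 12) {
  if (inherits(recs, "eeg_recording")) recs <- list(recs)
  stopifnot(train_s > 0, test_s > 0)
  plans <- lapply(seq_along(recs), function(i) {
    rec <- recs[[i]]
    tr <- as.integer(round(train_s * rec$sample_rate))
    te <- as.integer(round(test_s * rec$sample_rate))
    if (n_samples(rec) < tr + te)
      stop(sprintf("recording for subject %s (%s) is too short: %d samples < %d required",
                   rec$subject_id, rec$session, n_samples(rec), tr + te))
    data.frame(rec_index = i, subject_id = rec$subject_id,
               session = rec$session,
               role = c("train", "test"),
               start = c(0L, tr), end = c(tr, tr + te))
  })
  structure(do.call(rbind, plans), class = c("split_plan", "data.frame"))
}

#' Contiguous temporal k-fold cross-validation splits
#'
#' Divides every recording into `k` contiguous equal spans; fold i uses the
#' i-th span of *every* recording (every subject, every session present) as
#' the test interval and the remaining spans as training intervals. Folds
#' are temporal blocks, not shuffled segments: with overlapping windows a
#' shuffled-segment split would leak near-duplicate windows from train into
#' test, while block splits keep windows strictly inside one fold.
#'
#' @param recs list of [recording()] objects, all of one length.
#' @param k number of folds (>= 2); recording length in samples must be
#'   divisible by `k`.
#' @return list of `k` `split_plan` objects.
#' @export
make_cv_splits <- function(recs, k = 5L) {
  if (inherits(recs, "eeg_recording")) recs <- list(recs)
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be at least 2")
  lens <- vapply(recs, n_samples, 0L)
  bad <- which(lens %% k != 0L)
  if (length(bad))
    stop(sprintf("recording length %d samples is not divisible by k = %d (subject %s); trim the recording to a multiple of k spans first",
                 lens[bad[1]], k, recs[[bad[1]]]$subject_id))
  lapply(seq_len(k), function(fold) {
    plans <- lapply(seq_along(recs), function(i) {
      span <- lens[i] %/% k
      starts <- (seq_len(k) - 1L) * span
      data.frame(rec_index = i, subject_id = recs[[i]]$subject_id,
                 session = recs[[i]]$session,
                 role = ifelse(seq_len(k) == fold, "test", "train"),
                 start = starts, end = starts + span)
    })
    structure(do.call(rbind, plans), class = c("split_plan", "data.frame"))
  })
}

#' Verify a split plan leaks no test samples into training windows
#'
#' Interval arithmetic over the plan: training windows are always cut
#' strictly inside training intervals, so the plan is leak-free iff no
#' train interval overlaps a test interval of the same recording (and
#' window extents never exceed their interval, which [build_dataset()]
#' guarantees by construction). Errors if an overlap exists.
#'
#' @param plan a `split_plan`.
#' @return `TRUE`, invisibly.
#' @export
verify_split <- function(plan) {
  for (ri in unique(plan$rec_index)) {
    p <- plan[plan$rec_index == ri, ]
    tr <- p[p$role == "train", ]
    te <- p[p$role == "test", ]
    for (a in seq_len(nrow(tr))) for (b in seq_len(nrow(te))) {
      if (tr$start[a] < te$end[b] && te$start[b] < tr$end[a])
        stop(sprintf("split leakage: recording %d train [%d,%d) overlaps test [%d,%d)",
                     ri, tr$start[a], tr$end[a], te$start[b], te$end[b]))
    }
  }
  invisible(TRUE)
}

#' Mean and spread of per-fold metrics
#'
#' Aggregates fold-level values as mean plus sample (n-1) standard
#' deviation. A single fold reports sd 0 with a warning.
#'
#' @param x numeric vector of per-fold values.
#' @return named numeric vector `c(mean, sd)`.
#' @export
fold_summary <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L)
  if (length(x) == 1L) {
    warning("single fold: standard deviation reported as 0")
    return(c(mean = x, sd = 0))
  }
  c(mean = mean(x), sd = stats::sd(x))
}

#' Run an identification experiment end-to-end
#'
#' Executes the full pipeline for one split plan (hold-out) or a list of
#' plans (cross-validation folds): per-subject standardization, montage
#' selection, post-split sliding-window segmentation, training, and
#' biometric evaluation; then aggregates Rank-1 and EER across folds.
#'
#' Standardization statistics are pooled over all recordings of a subject
#' present in `recs` and, by default, over the full recording span
#' (preprocessing precedes the train/test division in the reference
#' pipeline — a mild, documented leakage; set `stats_scope = "train"` for
#' the strict variant using training intervals only).
#'
#' @param recs list of [recording()] objects (one or both sessions per
#'   subject; pooling both realizes the EO&EC union protocol).
#' @param plans a `split_plan` or list of them (one per fold).
#' @param mont an [montage()] or montage name, or `NULL` to keep all
#'   channels.
#' @param spec a [window_spec()].
#' @param train_cfg a [train_config()]; fold f trains with seed
#'   `train_cfg$seed + f - 1`.
#' @param n_sources,conv_width,fc_width,dropout_p network hyperparameters,
#'   see [model_config()].
#' @param stats_scope `"full"` or `"train"`, see Details.
#' @param expected_rate expected sampling rate in Hz; recordings deviating
#'   from it are handled per `on_rate_mismatch`.
#' @param on_rate_mismatch `"exclude"` (drop such recordings, with a
#'   warning), `"keep"`, or `"error"`.
#' @param verbose print progress.
#' @return list: `folds` — per-fold lists with `report` ([evaluate()]
#'   output), `trace`, `model`; `summary` — data frame (fold, rank1, eer,
#'   n_train, n_test); `aggregate` — list with `rank1` and `eer` as
#'   `c(mean, sd)` across folds.
#' @export
run_experiment <- function(recs, plans, mont = NULL, spec = window_spec(),
                           train_cfg = train_config(),
                           n_sources = 64L, conv_width = 32L,
                           fc_width = 512L, dropout_p = 0.5,
                           stats_scope = c("full", "train"),
                           expected_rate = 160,
                           on_rate_mismatch = c("exclude", "keep", "error"),
                           verbose = FALSE) {
  stats_scope <- match.arg(stats_scope)
  on_rate_mismatch <- match.arg(on_rate_mismatch)
  if (inherits(recs, "eeg_recording")) recs <- list(recs)
  if (inherits(plans, "split_plan")) plans <- list(plans)

  rates <- vapply(recs, function(r) r$sample_rate, 0)
  if (any(rates != expected_rate)) {
    off <- which(rates != expected_rate)
    msg <- sprintf("%d recording(s) deviate from the expected %g Hz",
                   length(off), expected_rate)
    if (on_rate_mismatch == "error") stop(msg)
    if (on_rate_mismatch == "exclude") {
      warning(msg, "; excluded")
      keep <- setdiff(seq_along(recs), off)
      remap <- match(seq_along(recs), keep)
      recs <- recs[keep]
      plans <- lapply(plans, function(p) {
        p <- p[p$rec_index %in% keep, , drop = FALSE]
        p$rec_index <- remap[p$rec_index]
        p
      })
    }
  }
  if (!is.null(mont)) recs <- lapply(recs, select_channels, mont = mont)

  subjects <- sort(unique(vapply(recs, function(r) r$subject_id, "")))
  label_map <- stats::setNames(seq_along(subjects) - 1L, subjects)

  fold_out <- vector("list", length(plans))
  for (f in seq_along(plans)) {
    plan <- plans[[f]]
    verify_split(plan)

    # standardization statistics per subject: full span or train-only
    std_recs <- recs
    for (s in subjects) {
      idx <- which(vapply(recs, function(r) r$subject_id, "") == s)
      if (stats_scope == "full") {
        st <- compute_stats(recs[idx])
      } else {
        clipped <- lapply(idx, function(i) {
          tr <- plan[plan$rec_index == i & plan$role == "train", ]
          keep <- unlist(lapply(seq_len(nrow(tr)),
                                function(j) (tr$start[j] + 1):tr$end[j]))
          r <- recs[[i]]; r$signal <- r$signal[, keep, drop = FALSE]; r
        })
        st <- compute_stats(clipped)
      }
      for (i in idx) std_recs[[i]] <- standardize(recs[[i]], st)
    }

    tr_plan <- plan[plan$role == "train", ]
    te_plan <- plan[plan$role == "test", ]
    train_set <- build_dataset(std_recs, spec, ranges = tr_plan,
                               label_map = label_map)
    test_set <- build_dataset(std_recs, spec, ranges = te_plan,
                              label_map = label_map)

    cfg <- model_config(n_channels = dim(train_set$x)[2],
                        n_points = dim(train_set$x)[1],
                        n_classes = length(label_map),
                        n_sources = n_sources, conv_width = conv_width,
                        fc_width = fc_width, dropout_p = dropout_p)
    fold_seed <- train_cfg$seed + f - 1L
    model <- ica_convnet(cfg, seed = fold_seed)
    tc <- train_config(train_cfg$learning_rate, train_cfg$batch_size,
                       train_cfg$epochs, fold_seed)
    if (verbose)
      message(sprintf("fold %d/%d: %d train / %d test segments, %d classes",
                      f, length(plans), n_segments(train_set),
                      n_segments(test_set), length(label_map)))
    fit <- train(model, train_set, tc, verbose = verbose)
    report <- evaluate(fit$model, test_set)
    if (verbose)
      message(sprintf("fold %d: Rank-1 %.2f%%, EER %.2f%%", f,
                      report$rank1, report$eer))
    fold_out[[f]] <- list(report = report, trace = fit$trace,
                          model = fit$model,
                          n_train = n_segments(train_set),
                          n_test = n_segments(test_set))
  }

  summary <- data.frame(
    fold = seq_along(fold_out),
    rank1 = vapply(fold_out, function(x) x$report$rank1, 0),
    eer = vapply(fold_out, function(x) x$report$eer, 0),
    n_train = vapply(fold_out, function(x) x$n_train, 0L),
    n_test = vapply(fold_out, function(x) x$n_test, 0L))
  aggregate <- list(
    rank1 = suppressWarnings(fold_summary(summary$rank1)),
    eer = suppressWarnings(fold_summary(summary$eer)))
  if (length(plans) == 1L)
    warning("single fold: standard deviation reported as 0")
  list(folds = fold_out, summary = summary, aggregate = aggregate)
}
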