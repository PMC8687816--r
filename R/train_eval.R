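#' Training configuration
#'
#' The training recipe: Adam with learning rate 3e-3, batch size 64, a fixed
#' epoch budget (2000 in the reference protocol; scale down for desk-scale
#' runs), seeded batch shuffling, no early stopping and no learning-rate
#' schedule. Final-epoch weights are the result.
#'
#' @param learning_rate Adam step size.
#' @param batch_size segments per minibatch.
#' @param epochs passes over the training set (>= 1).
#' @param seed RNG seed for shuffling and dropout.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 3e-3, batch_size = 64L,
                         epochs = 2000L, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

#' Train the network
#'
#' Runs exactly `cfg$epochs` passes over seeded shuffles of the training
#' set, updating all weights (including the channel-mixing matrix) with
#' Adam on the mean cross-entropy loss. Identical seeds and inputs give
#' identical traces on one platform.
#'
#' @param model an [ica_convnet()].
#' @param train_set a `segmented_dataset` with dense labels `0..O-1`.
#' @param cfg a [train_config()].
#' @param eval_set optional `segmented_dataset` scored for Rank-1 accuracy
#'   every `eval_every` epochs (adds compute; `NULL` to skip).
#' @param eval_every epochs between evaluations of `eval_set`.
#' @param verbose print a line per evaluation.
#' @return list: `model` (trained), `trace` (data frame with `epoch`,
#'   `loss`, `train_rank1`, and `test_rank1` where evaluated).
#' @export
train <- function(model, train_set, cfg = train_config(), eval_set = NULL,
                  eval_every = 10L, verbose = FALSE) {
  stopifnot(inherits(model, "ica_convnet"),
            inherits(train_set, "segmented_dataset"),
            inherits(cfg, "train_config"))
  n <- n_segments(train_set)
  if (n == 0L) stop("training set is empty")
  labels <- train_set$meta$label
  O <- model$cfg$n_classes
  present <- sort(unique(labels))
  if (!identical(present, 0:(length(present) - 1L)))
    stop("training labels are not dense 0..k-1: gap detected")
  if (max(labels) >= O)
    stop("training labels exceed the model's class count")

  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)

  params <- model$params
  opt <- adam_init(params)
  trace <- data.frame(epoch = seq_len(cfg$epochs), loss = NA_real_,
                      train_rank1 = NA_real_, test_rank1 = NA_real_)

  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0; ep_hits <- 0L
    for (at in seq(1L, n, by = cfg$batch_size)) {
      sel <- perm[at:min(at + cfg$batch_size - 1L, n)]
      xb <- train_set$x[, , sel, drop = FALSE]
      yb <- labels[sel]
      model$params <- params
      cache <- .forward(model, xb, training = TRUE, keep_cache = TRUE)
      ep_loss <- ep_loss + cross_entropy(cache$logp, yb) * length(sel)
      ep_hits <- ep_hits + sum(max.col(cache$logp, ties.method = "first") ==
                                 yb + 1L)
      grads <- .backward(model, cache, yb)
      upd <- adam_step(params, grads, opt, cfg$learning_rate)
      params <- upd$params
      opt <- upd$state
    }
    trace$loss[epoch] <- ep_loss / n
    trace$train_rank1[epoch] <- 100 * ep_hits / n
    if (!is.null(eval_set) &&
        (epoch %% eval_every == 0L || epoch == cfg$epochs)) {
      model$params <- params
      trace$test_rank1[epoch] <- rank1(model, eval_set)
    }
    if (verbose && (epoch %% eval_every == 0L || epoch == cfg$epochs))
      message(sprintf("epoch %4d  loss %.4f  train rank-1 %.2f%%%s",
                      epoch, trace$loss[epoch], trace$train_rank1[epoch],
                      if (is.na(trace$test_rank1[epoch])) "" else
                        sprintf("  test rank-1 %.2f%%", trace$test_rank1[epoch])))
  }
  model$params <- params
  list(model = model, trace = trace)
}

#' Rank-1 identification accuracy
#'
#' Percentage of test segments whose top-scoring identity is the true one.
#' Ties at the maximum are broken toward the lowest class index (a
#' measure-zero event for float scores, fixed for determinism). The system
#' is closed-set: every test subject must be enrolled.
#'
#' @param model an [ica_convnet()].
#' @param test_set a `segmented_dataset`.
#' @return accuracy in percent (0..100).
#' @export
rank1 <- function(model, test_set) {
  stopifnot(inherits(test_set, "segmented_dataset"))
  if (n_segments(test_set) == 0L) stop("test set is empty")
  if (any(test_set$meta$label >= model$cfg$n_classes |
          is.na(test_set$meta$label)))
    stop("test set contains subjects unknown to the model (closed-set system)")
  logp <- model_forward(model, test_set)
  pred <- max.col(logp, ties.method = "first")
  100 * mean(pred == test_set$meta$label + 1L)
}

#' Genuine and impostor claim scores
#'
#' Verification-style scoring from a closed-set classifier: every test
#' segment claims every enrolled identity in turn, and the match score of
#' claim (segment, k) is the posterior probability the network assigns to
#' class k. Claims of the true identity populate the genuine set, all
#' others the impostor set, giving `n` genuine and `n * (O - 1)` impostor
#' scores.
#'
#' @param model an [ica_convnet()].
#' @param test_set a `segmented_dataset`.
#' @return an object of class `score_set`: list with numeric vectors
#'   `genuine` and `impostor` (probabilities in `[0, 1]`).
#' @export
score_claims <- function(model, test_set) {
  stopifnot(inherits(test_set, "segmented_dataset"))
  if (n_segments(test_set) == 0L) stop("test set is empty")
  probs <- exp(model_forward(model, test_set))
  truth <- cbind(seq_len(nrow(probs)), test_set$meta$label + 1L)
  genuine <- probs[truth]
  impostor <- probs
  impostor[truth] <- NA
  impostor <- impostor[!is.na(impostor)]
  structure(list(genuine = genuine, impostor = impostor),
            class = "score_set")
}

#' FAR/FRR threshold sweep, equal error rate and DET points
#'
#' Sweeps every distinct observed score as an acceptance threshold theta:
#' FAR(theta) = % impostor scores >= theta (non-increasing in theta),
#' FRR(theta) = % genuine scores < theta (non-decreasing). The EER is read
#' off at the crossing of the two piecewise-linear curves, interpolating
#' between the bracketing thresholds; the swept (FAR, FRR) pairs are the
#' DET curve.
#'
#' @param scores a `score_set` from [score_claims()], or a list with
#'   numeric `genuine` and `impostor` elements.
#' @return an object of class `eer_curve`: data frame `curve` with columns
#'   `threshold`, `far`, `frr` (percent), plus `eer`, `eer_threshold` and
#'   `det_points`.
#' @export
compute_eer <- function(scores) {
  g <- scores$genuine; i <- scores$impostor
  if (length(g) == 0L || length(i) == 0L)
    stop("both genuine and impostor score sets must be nonempty")
  thr <- sort(unique(c(g, i)))
  # append a threshold above every score so the sweep reaches FAR = 0
  thr <- c(thr, thr[length(thr)] + 1)
  ng <- length(g); ni <- length(i)
  far <- 100 * vapply(thr, function(t) sum(i >= t), 0) / ni
  frr <- 100 * vapply(thr, function(t) sum(g < t), 0) / ng
  d <- far - frr
  if (any(d == 0)) {
    k <- which(d == 0)[1]
    eer <- far[k]; eer_thr <- thr[k]
  } else {
    k <- which(d[-length(d)] > 0 & d[-1] < 0)[1]
    if (is.na(k)) { # degenerate: curves never bracket (all-equal scores)
      k <- which.min(abs(d))
      eer <- (far[k] + frr[k]) / 2; eer_thr <- thr[k]
    } else {
      t_frac <- d[k] / (d[k] - d[k + 1])
      eer <- far[k] + t_frac * (far[k + 1] - far[k])
      eer_thr <- thr[k] + t_frac * (thr[k + 1] - thr[k])
    }
  }
  structure(list(curve = data.frame(threshold = thr, far = far, frr = frr),
                 eer = eer, eer_threshold = eer_thr,
                 det_points = data.frame(far = far, frr = frr)),
            class = "eer_curve")
}

#' @export
print.eer_curve <- function(x, ...) {
  cat(sprintf("<eer_curve> EER %.3f%% at threshold %.4g (%d swept thresholds)\n",
              x$eer, x$eer_threshold, nrow(x$curve)))
  invisible(x)
}

#' Full biometric evaluation of a trained model
#'
#' Combines closed-set identification (Rank-1) and verification-style
#' FAR/FRR/EER analysis into one report.
#'
#' @param model a trained [ica_convnet()].
#' @param test_set a `segmented_dataset`.
#' @return an object of class `eval_report`: `rank1` (percent), `eer`
#'   (percent), `eer_threshold`, `far_curve`/`frr_curve` via `curve`,
#'   `det_points`, `n_test`, and the `scores`.
#' @export
evaluate <- function(model, test_set) {
  r1 <- rank1(model, test_set)
  sc <- score_claims(model, test_set)
  ec <- compute_eer(sc)
  structure(list(rank1 = r1, eer = ec$eer, eer_threshold = ec$eer_threshold,
                 curve = ec$curve, det_points = ec$det_points,
                 n_test = n_segments(test_set), scores = sc),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> Rank-1 %.2f%%, EER %.2f%% (n_test = %d)\n",
              x$rank1, x$eer, x$n_test))
  invisible(x)
}

#' Plot a DET curve
#'
#' Detection error trade-off: FRR against FAR as the acceptance threshold
#' varies.
#'
#' @param report an `eval_report` or `eer_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_det <- function(report, ...) {
  pts <- report$det_points
  graphics::plot(pts$far, pts$frr, type = "l", xlab = "FAR (%)",
                 ylab = "FRR (%)", main = "DET curve", ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  eer <- report$eer
  if (!is.null(eer)) graphics::points(eer, eer, pch = 19, col = "red3")
  invisible(report)
}

#' Write training trace and evaluation report to disk
#'
#' CSV files for the per-epoch trace and the threshold sweep, plus a JSON
#' summary (`rank1`, `eer`, sizes, config echo).
#'
#' @param report an `eval_report`.
#' @param trace training trace data frame (or `NULL`).
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, trace = NULL, dir = ".", prefix = "eegid") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$curve,
                   file.path(dir, paste0(prefix, "_far_frr.csv")),
                   row.names = FALSE)
  if (!is.null(trace))
    utils::write.csv(trace, file.path(dir, paste0(prefix, "_trace.csv")),
                     row.names = FALSE)
  jsonlite::write_json(
    list(rank1 = report$rank1, eer = report$eer,
         eer_threshold = report$eer_threshold, n_test = report$n_test),
    file.path(dir, paste0(prefix, "_summary.json")),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
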