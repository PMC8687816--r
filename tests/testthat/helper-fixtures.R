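# Shared fixtures: everything is generated in code at test time.

# small deterministic recording with arbitrary labels
make_rec <- function(n_ch = 4, n_t = 100, rate = 160, subject = "S001",
                     session = "EO", seed = 1, labels = NULL) {
  set.seed(seed)
  if (is.null(labels)) labels <- montage("FULL64")$channels[seq_len(n_ch)]
  recording(matrix(rnorm(n_ch * n_t), nrow = n_ch), labels, rate, subject,
            session)
}

# tiny network configuration that keeps test-time training in milliseconds
tiny_cfg <- function(n_channels = 3, n_points = 16, n_classes = 2,
                     n_sources = 4, conv_width = 2, fc_width = 8,
                     dropout_p = 0) {
  model_config(n_channels, n_points, n_classes, n_sources = n_sources,
               conv_width = conv_width, fc_width = fc_width,
               dropout_p = dropout_p)
}

# brute-force sliding-window count: enumerate starts 0, S, 2S, ... and keep
# those whose window fits entirely
enum_window_count <- function(T, L, S) {
  if (T < L) return(0L)
  sum((seq(0, T, by = S) + L) <= T + 0L) # starts at 0 step S, need start+L <= T
}

# independent EER oracle: dense sweep over all candidate thresholds with the
# two empirical step curves linearly interpolated in theta; crossing solved
# segment by segment
eer_oracle <- function(genuine, impostor) {
  thr <- sort(unique(c(genuine, impostor)))
  thr <- c(thr, max(thr) + 1)
  far <- sapply(thr, function(t) 100 * mean(impostor >= t))
  frr <- sapply(thr, function(t) 100 * mean(genuine < t))
  d <- far - frr
  for (k in seq_along(d)) {
    if (d[k] == 0) return(far[k])
    if (k < length(d) && d[k] > 0 && d[k + 1] < 0) {
      a <- d[k] / (d[k] - d[k + 1])
      return(far[k] + a * (far[k + 1] - far[k]))
    }
  }
  (far[which.min(abs(d))] + frr[which.min(abs(d))]) / 2
}

# dataset of segments that a linear map provably separates: each class is a
# distinct constant-offset pattern plus small noise
separable_dataset <- function(n_classes = 2, n_per_class = 40, P = 16,
                              C = 3, rate = 160, seed = 5) {
  set.seed(seed)
  x <- array(0, dim = c(P, C, n_classes * n_per_class))
  lab <- integer(n_classes * n_per_class)
  k <- 0L
  for (cl in seq_len(n_classes) - 1L) {
    offs <- rnorm(C, sd = 2)
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      x[, , k] <- matrix(rep(offs, each = P), nrow = P) + 0.1 * rnorm(P * C)
      lab[k] <- cl
    }
  }
  subjects <- sprintf("S%03d", lab + 1L)
  structure(list(
    x = x,
    meta = data.frame(subject_id = subjects, session = "EO",
                      start_sample = 0L, label = lab),
    label_map = stats::setNames(seq_len(n_classes) - 1L,
                                sprintf("S%03d", seq_len(n_classes))),
    window = window_spec(P / rate, P / rate),
    sample_rate = rate,
    channel_names = montage("FULL64")$channels[seq_len(C)]),
    class = "segmented_dataset")
}
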