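#' Network configuration
#'
#' Hyperparameters of the channel-mixing convolutional network. The
#' architecture needs the temporal axis `n_points` divisible by 8 (three
#' temporal halvings) and an even `n_sources` (one halving on the source
#' axis). Defaults are the selected hyperparameters of the reference
#' system: 64 latent sources, 32 feature maps per convolution block, a
#' 512-unit hidden layer, dropout 0.5.
#'
#' @param n_channels C, number of input channels (montage size).
#' @param n_points P, samples per segment; divisible by 8.
#' @param n_classes O, number of enrolled identities.
#' @param n_sources width of the channel-mixing ("ICA") stage output.
#' @param conv_width feature maps per convolution block.
#' @param fc_width hidden units of the first fully connected layer.
#' @param dropout_p dropout probability between the fully connected layers.
#' @return an object of class `model_config`.
#' @export
model_config <- function(n_channels, n_points, n_classes, n_sources = 64L,
                         conv_width = 32L, fc_width = 512L, dropout_p = 0.5) {
  if (n_points %% 8 != 0)
    stop("`n_points` must be divisible by 8 (got ", n_points, ")")
  if (n_sources %% 2 != 0 || n_sources < 2)
    stop("`n_sources` must be an even number >= 2")
  stopifnot(n_channels >= 1, n_classes >= 1, conv_width >= 1, fc_width >= 1,
            dropout_p >= 0, dropout_p < 1)
  structure(list(n_channels = as.integer(n_channels),
                 n_points = as.integer(n_points),
                 n_classes = as.integer(n_classes),
                 n_sources = as.integer(n_sources),
                 conv_width = as.integer(conv_width),
                 fc_width = as.integer(fc_width),
                 dropout_p = dropout_p),
            class = "model_config")
}

# width of the flattened feature vector entering FC_1
flatten_width <- function(cfg) {
  cfg$conv_width * (cfg$n_points %/% 8L) * (cfg$n_sources %/% 2L)
}

#' Build the channel-mixing convolutional network
#'
#' Constructs the identification network. The first stage is a learnable
#' linear map on the channel axis — a separation matrix W applied to each
#' time-point's channel vector (Y = WX), motivated by the blind source
#' separation model X = AS in which observed electrodes are a linear mixing
#' of latent cortical sources; W is optimized by backpropagation like every
#' other weight. It is followed by three convolution blocks (2-D
#' convolution + ELU + max-pool) and a fully connected output stage with
#' dropout and log-softmax scores:
#'
#' \preformatted{
#' input  (1, P, C)
#' mix    (1, P, S)      linear C -> S on the channel axis, no bias
#' conv1  (32, P/2, S)   5x3 kernel, stride (2,1), padding (2,1), ELU
#' pool1  (32, P/4, S)   max 2x1, stride (2,1)
#' conv2  (32, P/4, S)   3x3 kernel, stride (1,1), padding (1,1), ELU
#' pool2  (32, P/4, S/2) max 1x2, stride (1,2)
#' conv3  (32, P/4, S/2) 3x3 kernel, stride (1,1), padding (1,1), ELU
#' pool3  (32, P/8, S/2) max 2x1, stride (2,1)
#' flatten -> FC(512) -> dropout(0.5) -> FC(O) -> log-softmax
#' }
#'
#' Weights are drawn from the uniform fan-in scheme
#' U(-1/sqrt(fan_in), 1/sqrt(fan_in)) under the given seed; identical seeds
#' give identical initial weights.
#'
#' @param cfg a [model_config()].
#' @param seed integer RNG seed for weight initialization.
#' @return an object of class `ica_convnet`.
#' @export
ica_convnet <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  K <- cfg$conv_width
  flat <- flatten_width(cfg)
  params <- list(
    ica    = init_uniform(c(cfg$n_sources, cfg$n_channels), cfg$n_channels),
    conv1_w = init_uniform(c(5, 3, 1, K), 15),
    conv1_b = init_uniform(K, 15),
    conv2_w = init_uniform(c(3, 3, K, K), 9 * K),
    conv2_b = init_uniform(K, 9 * K),
    conv3_w = init_uniform(c(3, 3, K, K), 9 * K),
    conv3_b = init_uniform(K, 9 * K),
    fc1_w  = init_uniform(c(flat, cfg$fc_width), flat),
    fc1_b  = init_uniform(cfg$fc_width, flat),
    fc2_w  = init_uniform(c(cfg$fc_width, cfg$n_classes), cfg$fc_width),
    fc2_b  = init_uniform(cfg$n_classes, cfg$fc_width))
  structure(list(cfg = cfg, params = params, seed = as.integer(seed)),
            class = "ica_convnet")
}

#' @export
print.ica_convnet <- function(x, ...) {
  cat(sprintf("<ica_convnet> C=%d P=%d O=%d | sources=%d conv=%d fc=%d dropout=%g | %s parameters\n",
              x$cfg$n_channels, x$cfg$n_points, x$cfg$n_classes,
              x$cfg$n_sources, x$cfg$conv_width, x$cfg$fc_width,
              x$cfg$dropout_p, format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Total trainable parameter count
#' @param model an [ica_convnet()].
#' @return integer.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, 0L))
}

# coerce various inputs to a (P, C, B) array
.as_batch <- function(x, cfg) {
  if (inherits(x, "segmented_dataset")) x <- x$x
  if (inherits(x, "eeg_segment")) x <- x$data
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (length(d) != 3L || d[1] != cfg$n_points || d[2] != cfg$n_channels)
    stop(sprintf("input shape mismatch: expected %d x %d x B, got %s",
                 cfg$n_points, cfg$n_channels, paste(d, collapse = " x ")))
  x
}

# full forward pass; keep_cache stores every intermediate needed by .backward
.forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  cfg <- model$cfg; pr <- model$params
  P <- cfg$n_points; S <- cfg$n_sources
  B <- dim(x)[3]
  flat <- flatten_width(cfg)

  Xm <- matrix(aperm(x, c(1, 3, 2)), nrow = P * B)        # (P*B) x C
  Y <- Xm %*% t(pr$ica)                                   # (P*B) x S
  a1 <- array(aperm(array(Y, c(P, B, S)), c(1, 3, 2)), dim = c(P, S, 1, B))
  e1 <- conv2d(a1, pr$conv1_w, pr$conv1_b, stride = c(2, 1), pad = c(2, 1),
               apply_elu = TRUE)
  pl1 <- maxpool(e1, c(2, 1))
  e2 <- conv2d(pl1$y, pr$conv2_w, pr$conv2_b, stride = c(1, 1), pad = c(1, 1),
               apply_elu = TRUE)
  pl2 <- maxpool(e2, c(1, 2))
  e3 <- conv2d(pl2$y, pr$conv3_w, pr$conv3_b, stride = c(1, 1), pad = c(1, 1),
               apply_elu = TRUE)
  pl3 <- maxpool(e3, c(2, 1))
  f <- t(matrix(pl3$y, nrow = flat))                      # B x flat
  h <- f %*% pr$fc1_w
  h <- h + rep(pr$fc1_b, each = B)
  mask <- NULL
  if (training && cfg$dropout_p > 0) {
    mask <- matrix((runif(length(h)) >= cfg$dropout_p) / (1 - cfg$dropout_p),
                   nrow = B)
    h <- h * mask
  }
  o <- h %*% pr$fc2_w
  o <- o + rep(pr$fc2_b, each = B)
  logp <- log_softmax(o)

  if (!keep_cache) return(list(logp = logp))
  list(logp = logp, Xm = Xm, a1 = a1, e1 = e1, pl1 = pl1, e2 = e2,
       pl2 = pl2, e3 = e3, pl3 = pl3, f = f, h = h, mask = mask)
}

# gradients of the mean cross-entropy loss w.r.t. every parameter
.backward <- function(model, cache, labels) {
  cfg <- model$cfg; pr <- model$params
  P <- cfg$n_points; S <- cfg$n_sources
  B <- nrow(cache$logp)
  flat <- flatten_width(cfg)

  dlog <- exp(cache$logp)
  dlog[cbind(seq_len(B), labels + 1L)] <-
    dlog[cbind(seq_len(B), labels + 1L)] - 1
  dlog <- dlog / B

  g <- list()
  g$fc2_w <- crossprod(cache$h, dlog)
  g$fc2_b <- colSums(dlog)
  dh <- tcrossprod(dlog, pr$fc2_w)
  if (!is.null(cache$mask)) dh <- dh * cache$mask
  g$fc1_w <- crossprod(cache$f, dh)
  g$fc1_b <- colSums(dh)
  df <- tcrossprod(dh, pr$fc1_w)                          # B x flat

  dp3 <- array(t(df), dim = dim(cache$pl3$y))
  dz3 <- maxpool_elu_grad(cache$pl3, dp3, cache$e3)
  g3 <- conv2d_grad(cache$pl2$y, pr$conv3_w, dz3, c(1, 1), c(1, 1))
  g$conv3_w <- g3$dw; g$conv3_b <- g3$db

  dz2 <- maxpool_elu_grad(cache$pl2, g3$dx, cache$e2)
  g2 <- conv2d_grad(cache$pl1$y, pr$conv2_w, dz2, c(1, 1), c(1, 1))
  g$conv2_w <- g2$dw; g$conv2_b <- g2$db

  dz1 <- maxpool_elu_grad(cache$pl1, g2$dx, cache$e1)
  g1 <- conv2d_grad(cache$a1, pr$conv1_w, dz1, c(2, 1), c(2, 1))
  g$conv1_w <- g1$dw; g$conv1_b <- g1$db

  dY <- matrix(aperm(array(g1$dx, c(P, S, B)), c(1, 3, 2)), nrow = P * B)
  g$ica <- crossprod(dY, cache$Xm)
  g[names(model$params)]
}

#' Forward pass: per-segment log class scores
#'
#' Evaluation-mode forward pass (dropout disabled, deterministic). The
#' exponentials of each output row sum to 1: rows are log-probabilities
#' over the enrolled identities.
#'
#' @param model an [ica_convnet()].
#' @param x a P x C matrix, a P x C x B array, or a `segmented_dataset`.
#' @param batch_size internal chunking of large inputs.
#' @return a B x O matrix of log class scores.
#' @export
model_forward <- function(model, x, batch_size = 256L) {
  x <- .as_batch(x, model$cfg)
  B <- dim(x)[3]
  out <- matrix(0, nrow = B, ncol = model$cfg$n_classes)
  for (at in seq(1L, B, by = batch_size)) {
    sel <- at:min(at + batch_size - 1L, B)
    out[sel, ] <- .forward(model, x[, , sel, drop = FALSE])$logp
  }
  out
}

#' Mean cross-entropy loss
#'
#' Mean over the batch of the negative log-probability assigned to the true
#' identity: zero iff every true class has probability 1.
#'
#' @param log_scores B x O matrix of log class scores (rows log-normalized).
#' @param labels integer vector of true class indices, 0-based, in `[0, O)`.
#' @return non-negative scalar.
#' @export
cross_entropy <- function(log_scores, labels) {
  stopifnot(is.matrix(log_scores), length(labels) == nrow(log_scores))
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= ncol(log_scores)))
    stop("labels out of range [0, ", ncol(log_scores), ")")
  -mean(log_scores[cbind(seq_len(nrow(log_scores)), labels + 1L)])
}

#' Save / load a model checkpoint
#'
#' A checkpoint bundles everything needed to reproduce evaluation outputs
#' bit-identically: configuration, weights, the enrollment label map and
#' the per-subject standardization statistics.
#'
#' @param model an [ica_convnet()].
#' @param path checkpoint file path.
#' @param label_map named integer vector (subject -> class index).
#' @param stats list of `subject_stats` used at enrollment.
#' @name checkpoint
#' @export
save_checkpoint <- function(model, path, label_map = NULL, stats = NULL) {
  saveRDS(list(format = "eegid-checkpoint", version = 1L,
               cfg = model$cfg, params = model$params, seed = model$seed,
               label_map = label_map, stats = stats),
          path)
  invisible(path)
}

#' @rdname checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "eegid-checkpoint"))
    stop("not an eegid checkpoint: ", path)
  list(model = structure(list(cfg = obj$cfg, params = obj$params,
                              seed = obj$seed), class = "ica_convnet"),
       label_map = obj$label_map, stats = obj$stats)
}
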