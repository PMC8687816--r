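# Minimal dense neural-network layers on (H, W, C, B) column-major arrays.
# Convolution and pooling dispatch to the compiled kernels in src/; linear
# layers, ELU, log-softmax and Adam are plain BLAS-backed R.

conv2d <- function(x, w, b, stride = c(1L, 1L), pad = c(0L, 0L),
                   apply_elu = FALSE) {
  .conv2d_forward(x, w, b, as.integer(stride[1]), as.integer(stride[2]),
                  as.integer(pad[1]), as.integer(pad[2]), apply_elu)
}

conv2d_grad <- function(x, w, dy, stride = c(1L, 1L), pad = c(0L, 0L)) {
  .conv2d_backward(x, w, dy, as.integer(stride[1]), as.integer(stride[2]),
                   as.integer(pad[1]), as.integer(pad[2]))
}

maxpool <- function(x, kernel, stride = kernel) {
  .maxpool_forward(x, as.integer(kernel[1]), as.integer(kernel[2]),
                   as.integer(stride[1]), as.integer(stride[2]))
}

maxpool_grad <- function(pool, dy, xdim) {
  dx <- .maxpool_backward(pool$idx, dy, as.integer(prod(xdim)))
  dim(dx) <- xdim
  dx
}

# combined pool + ELU backward: e is the pre-pool activation (ELU output)
maxpool_elu_grad <- function(pool, dy, e) {
  dx <- .maxpool_elu_backward(pool$idx, dy, e, length(e))
  dim(dx) <- dim(e)
  dx
}

elu <- function(x) .elu(x)

# derivative of ELU expressed through its output: 1 for x > 0, exp(x) = y + 1 otherwise
elu_grad <- function(y, dy) .elu_grad(y, dy)

# row-wise numerically stable log-softmax of a B x O matrix
log_softmax <- function(z) {
  m <- apply(z, 1L, max)
  zs <- z - m
  zs - log(rowSums(exp(zs)))
}

# uniform fan-in initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in))
init_uniform <- function(dims, fan_in) {
  bound <- 1 / sqrt(fan_in)
  array(runif(prod(dims), -bound, bound), dim = dims)
}

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    mhat <- state$m[[k]] / bc1
    vhat <- state$v[[k]] / bc2
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
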