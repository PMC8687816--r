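test_that("configuration invariants are enforced before any allocation", {
  expect_error(model_config(14, 81, 8), "divisible by 8")
  expect_error(model_config(14, 80, 8, n_sources = 3), "even")
  expect_error(model_config(14, 80, 8, dropout_p = 1))
  expect_silent(model_config(14, 80, 8))
})

test_that("intermediate shapes follow the architecture table at P = 80", {
  for (C in c(14, 32, 64)) {
    m <- ica_convnet(model_config(C, 80, 109), seed = 1)
    x <- array(rnorm(80 * C * 2), dim = c(80, C, 2))
    cc <- eegid:::.forward(m, x, keep_cache = TRUE)
    expect_identical(dim(cc$a1), c(80L, 64L, 1L, 2L))      # mixing C -> 64
    expect_identical(dim(cc$e1), c(40L, 64L, 32L, 2L))     # conv1: P/2
    expect_identical(dim(cc$pl1$y), c(20L, 64L, 32L, 2L))  # pool1: P/4
    expect_identical(dim(cc$e2), c(20L, 64L, 32L, 2L))     # conv2: same
    expect_identical(dim(cc$pl2$y), c(20L, 32L, 32L, 2L))  # pool2: width/2
    expect_identical(dim(cc$e3), c(20L, 32L, 32L, 2L))     # conv3: same
    expect_identical(dim(cc$pl3$y), c(10L, 32L, 32L, 2L))  # pool3: P/8
    expect_identical(ncol(cc$f), 10240L)                   # flatten 32*(P/8)*32
    expect_identical(dim(cc$logp), c(2L, 109L))
  }
})

test_that("a forward pass succeeds and flattens to 32*(P/8)*32 for any valid P", {
  for (P in c(8L, 16L, 64L, 80L, 320L)) {
    for (C in c(1L, 14L, 64L)) {
      m <- ica_convnet(model_config(C, P, 5), seed = 1)
      cc <- eegid:::.forward(m, array(0, dim = c(P, C, 1)), keep_cache = TRUE)
      expect_identical(ncol(cc$f), 32L * (P %/% 8L) * 32L)
    }
  }
})

test_that("parameter count matches the closed-form layer walk", {
  for (C in c(14L, 64L)) {
    m <- ica_convnet(model_config(C, 80, 109), seed = 1)
    expected <- C * 64 +                       # mixing matrix, no bias
      (1 * 32 * 15 + 32) +                     # conv1 5x3 kernels + bias
      2 * (32 * 32 * 9 + 32) +                 # conv2, conv3 3x3
      (10240 * 512 + 512) +                    # FC_1
      (512 * 109 + 109)                        # FC_2
    expect_identical(n_params(m), as.integer(expected))
  }
})

test_that("log scores are normalized, deterministic, and degenerate at O = 1", {
  m <- ica_convnet(model_config(4, 16, 7, n_sources = 4, conv_width = 3,
                                fc_width = 10), seed = 2)
  x <- array(rnorm(16 * 4 * 5), dim = c(16, 4, 5))
  lp <- model_forward(m, x)
  expect_lt(max(abs(rowSums(exp(lp)) - 1)), 1e-6)
  expect_identical(lp, model_forward(m, x))    # bit-identical in eval mode

  m1 <- ica_convnet(tiny_cfg(n_classes = 1), seed = 1)
  lp1 <- model_forward(m1, array(rnorm(16 * 3 * 3), dim = c(16, 3, 3)))
  expect_true(all(lp1 == 0))
})

test_that("shape mismatches name expected and actual dimensions", {
  m <- ica_convnet(tiny_cfg(), seed = 1)
  expect_error(model_forward(m, array(0, dim = c(8, 3, 2))),
               "expected 16 x 3")
})

test_that("cross entropy matches its closed forms and a direct oracle", {
  O <- 5
  uniform <- matrix(log(1 / O), nrow = 3, ncol = O)
  expect_equal(cross_entropy(uniform, c(0L, 3L, 4L)), log(O),
               tolerance = 1e-12)

  perfect <- log(diag(4) * (1 - 1e-12) + 1e-13)
  expect_lt(cross_entropy(perfect, 0:3), 1e-10)

  set.seed(9)
  raw <- matrix(rnorm(12), 3, 4)
  lp <- raw - log(rowSums(exp(raw)))
  lab <- c(2L, 0L, 3L)
  oracle <- -mean(sapply(1:3, function(i) lp[i, lab[i] + 1]))
  expect_equal(cross_entropy(lp, lab), oracle, tolerance = 1e-7)

  expect_error(cross_entropy(lp, c(0L, 1L, 4L)), "out of range")
})

test_that("analytic gradients agree with finite differences everywhere", {
  set.seed(99)
  cfg <- model_config(3, 8, 3, n_sources = 4, conv_width = 2, fc_width = 5,
                      dropout_p = 0)
  m <- ica_convnet(cfg, seed = 3)
  x <- array(rnorm(8 * 3 * 4), dim = c(8, 3, 4))
  y <- c(0L, 2L, 1L, 0L)
  cc <- eegid:::.forward(m, x, keep_cache = TRUE)
  g <- eegid:::.backward(m, cc, y)
  loss_at <- function(mm) cross_entropy(eegid:::.forward(mm, x)$logp, y)
  eps <- 1e-6
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (j in sample(seq_along(p), min(6, length(p)))) {
      m2 <- m; m2$params[[nm]][j] <- p[j] + eps
      m3 <- m; m3$params[[nm]][j] <- p[j] - eps
      num <- (loss_at(m2) - loss_at(m3)) / (2 * eps)
      expect_lt(abs(num - g[[nm]][j]) /
                  max(1e-8, abs(num) + abs(g[[nm]][j])), 1e-4)
    }
  }
})

test_that("identical seeds give identical weights; different seeds differ", {
  cfg <- tiny_cfg()
  expect_identical(ica_convnet(cfg, seed = 5)$params,
                   ica_convnet(cfg, seed = 5)$params)
  expect_false(identical(ica_convnet(cfg, seed = 5)$params$ica,
                         ica_convnet(cfg, seed = 6)$params$ica))
})

test_that("permuting the output layer permutes class scores identically", {
  m <- ica_convnet(tiny_cfg(n_classes = 4), seed = 8)
  x <- array(rnorm(16 * 3 * 3), dim = c(16, 3, 3))
  perm <- c(3L, 1L, 4L, 2L)
  m2 <- m
  m2$params$fc2_w <- m$params$fc2_w[, perm]
  m2$params$fc2_b <- m$params$fc2_b[perm]
  expect_equal(model_forward(m2, x), model_forward(m, x)[, perm],
               tolerance = 1e-12)
})

test_that("checkpoints restore bit-identical evaluation outputs", {
  m <- ica_convnet(tiny_cfg(), seed = 4)
  x <- array(rnorm(16 * 3 * 2), dim = c(16, 3, 2))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path, label_map = c(a = 0L, b = 1L))
  back <- load_checkpoint(path)
  expect_identical(model_forward(back$model, x), model_forward(m, x))
  expect_identical(back$label_map, c(a = 0L, b = 1L))
  expect_error(suppressWarnings(load_checkpoint(tempfile(fileext = ".rds"))))
})
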