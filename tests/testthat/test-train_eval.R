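test_that("training configuration and inputs are validated", {
  expect_error(train_config(epochs = 0))
  expect_error(train_config(learning_rate = 0))
  ds <- separable_dataset()
  m <- ica_convnet(tiny_cfg(), seed = 1)
  gap <- ds
  gap$meta$label[gap$meta$label == 1L] <- 2L
  expect_error(train(m, gap, train_config(epochs = 1)), "dense")
  empty <- ds
  empty$x <- array(0, dim = c(16, 3, 0))
  empty$meta <- ds$meta[0, ]
  expect_error(train(m, empty, train_config(epochs = 1)), "empty")
})

test_that("a linearly separable toy cohort is learned to 100% within 50 epochs", {
  ds <- separable_dataset(n_classes = 2, n_per_class = 40)
  m <- ica_convnet(tiny_cfg(n_classes = 2), seed = 1)
  fit <- train(m, ds, train_config(epochs = 50L, batch_size = 16L, seed = 1L))
  expect_lt(tail(fit$trace$loss, 1), fit$trace$loss[1])
  expect_true(any(fit$trace$train_rank1 == 100))
  expect_equal(rank1(fit$model, ds), 100)
})

test_that("training is reproducible under a fixed seed", {
  ds <- separable_dataset(n_classes = 2, n_per_class = 10)
  m <- ica_convnet(tiny_cfg(n_classes = 2), seed = 2)
  f1 <- train(m, ds, train_config(epochs = 3L, seed = 11L))
  f2 <- train(m, ds, train_config(epochs = 3L, seed = 11L))
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("one optimization step moves the channel-mixing matrix", {
  ds <- separable_dataset(n_classes = 2, n_per_class = 5)
  m <- ica_convnet(tiny_cfg(n_classes = 2), seed = 3)
  fit <- train(m, ds, train_config(epochs = 1L, seed = 1L))
  expect_false(identical(fit$model$params$ica, m$params$ica))
})

test_that("rank-1 equals a brute-force argmax recount and honors tie-breaks", {
  ds <- separable_dataset(n_classes = 3, n_per_class = 8, C = 3)
  m <- ica_convnet(tiny_cfg(n_classes = 3), seed = 5)
  r1 <- rank1(m, ds)
  probs <- exp(model_forward(m, ds))
  hits <- sum(apply(probs, 1, which.max) == ds$meta$label + 1L)
  expect_equal(r1, 100 * hits / n_segments(ds))
  # confusion-matrix identity: rank-1 = 100 - classification error
  pred <- apply(probs, 1, which.max) - 1L
  cm <- table(factor(pred, levels = 0:2), factor(ds$meta$label, levels = 0:2))
  expect_equal(r1, 100 - 100 * (1 - sum(diag(cm)) / sum(cm)))

  # all-zero weights give uniform scores; lowest class index wins every tie
  mz <- m
  mz$params <- lapply(mz$params, function(p) p * 0)
  balanced <- separable_dataset(n_classes = 2, n_per_class = 10)
  expect_equal(rank1(mz, balanced), 50)
})

test_that("closed-set evaluation rejects unknown subjects", {
  ds <- separable_dataset(n_classes = 3, n_per_class = 4)
  m <- ica_convnet(tiny_cfg(n_classes = 2), seed = 1)
  expect_error(rank1(m, ds), "closed-set")
})

test_that("claim scores count O-1 impostors per segment and sum to one", {
  ds <- separable_dataset(n_classes = 3, n_per_class = 4)  # 12 segments? 3*4
  m <- ica_convnet(tiny_cfg(n_classes = 3), seed = 6)
  sc <- score_claims(m, ds)
  n <- n_segments(ds)
  expect_length(sc$genuine, n)
  expect_length(sc$impostor, n * 2L)
  expect_true(all(sc$genuine >= 0 & sc$genuine <= 1))
  expect_true(all(sc$impostor >= 0 & sc$impostor <= 1))
  # per segment, the genuine claim plus its O-1 impostor claims sum to 1
  probs <- exp(model_forward(m, ds))
  expect_lt(max(abs(rowSums(probs) - 1)), 1e-9)
  expect_equal(sum(sc$genuine) + sum(sc$impostor), n, tolerance = 1e-9)
})

test_that("EER handles perfect, chance and the worked three-score example", {
  perfect <- compute_eer(list(genuine = c(1, 1, 1), impostor = c(0, 0, 0)))
  expect_equal(perfect$eer, 0)

  same <- compute_eer(list(genuine = rep(c(.2, .5, .8), 50),
                           impostor = rep(c(.2, .5, .8), 50)))
  expect_equal(same$eer, 50, tolerance = 1e-9)

  ex <- compute_eer(list(genuine = c(0.9, 0.8, 0.4),
                         impostor = c(0.5, 0.3, 0.1)))
  expect_equal(ex$eer, 100 / 3, tolerance = 1e-9)
  expect_equal(ex$eer, eer_oracle(c(0.9, 0.8, 0.4), c(0.5, 0.3, 0.1)),
               tolerance = 1e-12)

  expect_error(compute_eer(list(genuine = numeric(0), impostor = 1)),
               "nonempty")
})

test_that("FAR falls and FRR rises along the sweep; EER is rank-invariant", {
  set.seed(31)
  g <- rbeta(200, 5, 2)
  i <- rbeta(400, 2, 5)
  ec <- compute_eer(list(genuine = g, impostor = i))
  expect_true(all(diff(ec$curve$far) <= 0))
  expect_true(all(diff(ec$curve$frr) >= 0))
  # strictly monotone transforms of all scores leave the EER unchanged
  tr <- function(x) 1 / (1 + exp(-(5 * x - 2)))
  ec2 <- compute_eer(list(genuine = tr(g), impostor = tr(i)))
  expect_equal(ec$eer, ec2$eer, tolerance = 1e-9)
})

test_that("evaluation reports bundle rank-1, EER and DET points coherently", {
  ds <- separable_dataset(n_classes = 2, n_per_class = 15)
  m <- ica_convnet(tiny_cfg(n_classes = 2), seed = 7)
  fit <- train(m, ds, train_config(epochs = 20L, batch_size = 10L, seed = 2L))
  rep <- evaluate(fit$model, ds)
  expect_gte(rep$rank1, 0); expect_lte(rep$rank1, 100)
  expect_gte(rep$eer, 0); expect_lte(rep$eer, 100)
  expect_identical(rep$n_test, n_segments(ds))
  expect_identical(names(rep$det_points), c("far", "frr"))

  dir <- tempfile(); dir.create(dir)
  write_report(rep, fit$trace, dir, prefix = "toy")
  expect_true(file.exists(file.path(dir, "toy_summary.json")))
  expect_true(file.exists(file.path(dir, "toy_far_frr.csv")))
  expect_true(file.exists(file.path(dir, "toy_trace.csv")))
  js <- jsonlite::read_json(file.path(dir, "toy_summary.json"))
  expect_equal(js$rank1, rep$rank1, tolerance = 1e-9)
})
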