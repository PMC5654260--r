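# CNN building blocks: softmax, cross-entropy, forward/backward, training
# determinism, prediction. Heavy end-to-end training lives in
# test-acceptance.R.

test_that("softmax squashes scores with shift invariance", {
  expect_equal(softmax(rep(0, 5)), rep(0.2, 5))
  expect_equal(softmax(c(log(2), 0)), c(2 / 3, 1 / 3))
  set.seed(1)
  for (i in 1:20) {
    q <- rnorm(sample(2:8, 1), sd = 5)
    p <- softmax(q)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p > 0 & p < 1))
    expect_equal(softmax(q + runif(1, -50, 50)), p)
  }
  # huge scores do not overflow
  expect_equal(sum(softmax(c(1e4, 1e4 - 1))), 1)
  # matrix form: one score vector per row
  m <- softmax(rbind(c(0, 0), c(log(3), 0)))
  expect_equal(m[1, ], c(0.5, 0.5))
  expect_equal(m[2, ], c(0.75, 0.25))
})

test_that("cross-entropy matches closed forms and is non-negative", {
  expect_equal(cross_entropy(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(cross_entropy(rep(0.2, 5), 3), log(5))
  expect_equal(cross_entropy(c(0.25, 0.75), c(1, 0)), log(4))
  # clamped at zero probability
  expect_true(is.finite(cross_entropy(c(0, 1), 1)))
  set.seed(2)
  for (i in 1:10) {
    p <- softmax(rnorm(4))
    expect_gte(cross_entropy(p, sample(4, 1)), 0)
  }
})

test_that("network spec computes dimensions and rejects collapse", {
  spec <- network_spec(8)
  expect_identical(spec$flat, 6L * 6L * 128L)
  expect_error(network_spec(5, input_size = 6,
                            conv_kernels = c(7, 5, 4)), "larger")
})

test_that("forward pass has the right output arity and is deterministic", {
  spec <- network_spec(8, input_size = 20, conv_filters = c(4, 6, 8),
                       conv_kernels = c(3, 3, 2), fc_units = 12)
  params <- init_params(spec, seed = 3)
  set.seed(4)
  x <- array(runif(20 * 20 * 2), c(20, 20, 1, 2))
  f1 <- rbcmorph:::cnn_forward(spec, params, x)
  expect_identical(dim(f1$scores), c(8L, 2L))
  f2 <- rbcmorph:::cnn_forward(spec, params, x)
  expect_identical(f1$scores, f2$scores)    # eval mode is bitwise stable
  expect_error(rbcmorph:::cnn_forward(spec, params,
                                      array(0, c(19, 19, 1, 1))),
               "expects")
})

test_that("first conv layer matches a brute-force correlation oracle and is
           translation equivariant", {
  spec <- network_spec(5, input_size = 12, conv_filters = 2,
                       conv_kernels = 3, fc_units = 4)
  params <- init_params(spec, seed = 5)
  w <- params$conv[[1]]$w
  impulse <- array(0, c(12, 12, 1, 1))
  impulse[4, 5, 1, 1] <- 1
  y1 <- rbcmorph:::cpp_conv_fwd(impulse, w, params$conv[[1]]$b)
  shifted <- array(0, c(12, 12, 1, 1))
  shifted[6, 8, 1, 1] <- 1
  y2 <- rbcmorph:::cpp_conv_fwd(shifted, w, params$conv[[1]]$b)
  # translation of the input translates the feature map by the same offset
  expect_equal(y1[1:8, 1:7, , , drop = FALSE],
               y2[3:10, 4:10, , , drop = FALSE])
  # brute-force correlation oracle on a random input
  set.seed(6)
  x <- array(runif(144), c(12, 12, 1, 1))
  y <- rbcmorph:::cpp_conv_fwd(x, w, params$conv[[1]]$b)
  for (f in 1:2) {
    for (i in c(1, 5, 10)) {
      for (j in c(2, 6, 9)) {
        ref <- sum(x[i:(i + 2), j:(j + 2), 1, 1] * w[, , 1, f]) +
          params$conv[[1]]$b[f]
        expect_equal(y[i, j, f, 1], ref, tolerance = 1e-12)
      }
    }
  }
})

test_that("analytic gradients match central differences on a reduced spec", {
  spec <- network_spec(3, input_size = 14, conv_filters = c(3, 4),
                       conv_kernels = c(3, 3), fc_units = 6, dropout = 0)
  params <- init_params(spec, seed = 1)
  set.seed(2)
  x <- array(runif(14 * 14 * 3), c(14, 14, 1, 3))
  y <- c(1L, 2L, 3L)
  lg <- rbcmorph:::cnn_loss_grads(spec, params, x, y)
  eps <- 1e-5
  paths <- list(
    list(get = function(p, i) p$conv[[1]]$w[i],
         set = function(p, i, v) { p$conv[[1]]$w[i] <- v; p },
         g = function(l, i) l$grads$conv[[1]]$w[i],
         n = function() length(params$conv[[1]]$w)),
    list(get = function(p, i) p$conv[[2]]$w[i],
         set = function(p, i, v) { p$conv[[2]]$w[i] <- v; p },
         g = function(l, i) l$grads$conv[[2]]$w[i],
         n = function() length(params$conv[[2]]$w)),
    list(get = function(p, i) p$fc$w[i],
         set = function(p, i, v) { p$fc$w[i] <- v; p },
         g = function(l, i) l$grads$fc$w[i],
         n = function() length(params$fc$w)),
    list(get = function(p, i) p$out$w[i],
         set = function(p, i, v) { p$out$w[i] <- v; p },
         g = function(l, i) l$grads$out$w[i],
         n = function() length(params$out$w)),
    list(get = function(p, i) p$out$b[i],
         set = function(p, i, v) { p$out$b[i] <- v; p },
         g = function(l, i) l$grads$out$b[i],
         n = function() length(params$out$b)))
  set.seed(3)
  for (path in paths) {
    for (t in 1:5) {
      i <- sample(path$n(), 1)
      v <- path$get(params, i)
      lp <- rbcmorph:::cnn_loss_grads(spec, path$set(params, i, v + eps),
                                      x, y)$loss
      lm <- rbcmorph:::cnn_loss_grads(spec, path$set(params, i, v - eps),
                                      x, y)$loss
      num <- (lp - lm) / (2 * eps)
      ana <- path$g(lg, i)
      expect_lt(abs(num - ana) / max(abs(num) + abs(ana), 1e-6), 1e-4)
    }
  }
})

test_that("training is seed-deterministic and records history", {
  spec <- network_spec(3, input_size = 16, conv_filters = c(3, 4),
                       conv_kernels = c(3, 3), fc_units = 6)
  set.seed(10)
  x <- array(runif(16 * 16 * 30) * 255, c(16, 16, 30))
  y <- rep(1:3, 10)
  cfg <- train_config(lr = 0.05, batch_size = 10, epochs = 3, seed = 9)
  m1 <- train_cnn(x, y, spec, cfg)
  m2 <- train_cnn(x, y, spec, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_identical(nrow(m1$history), 3L)
  expect_true(all(c("epoch", "loss", "train_error") %in%
                    names(m1$history)))
})

test_that("prediction ties break low, batching does not matter", {
  spec <- network_spec(3, input_size = 16, conv_filters = c(3, 4),
                       conv_kernels = c(3, 3), fc_units = 6)
  model <- structure(list(spec = spec, params = init_params(spec, 1),
                          config = train_config(), history = NULL),
                     class = "rbc_cnn")
  set.seed(11)
  x <- array(runif(16 * 16 * 7) * 255, c(16, 16, 7))
  all_at_once <- predict_cnn(model, x, batch_size = 7)
  one_by_one <- lapply(1:7, function(i) predict_cnn(model, x[, , i]))
  expect_identical(all_at_once$labels,
                   vapply(one_by_one, function(p) p$labels, 0L))
  # documented argmax tie-break
  expect_identical(max.col(rbind(c(0.5, 0.5)), ties.method = "first"), 1L)
  expect_identical(which.max(c(0.1, 0.7, 0.2)), 2L)
})

test_that("model checkpoints round-trip through JSON", {
  spec <- network_spec(3, input_size = 16, conv_filters = c(3, 4),
                       conv_kernels = c(3, 3), fc_units = 6)
  model <- structure(list(spec = spec, params = init_params(spec, 1),
                          config = train_config(),
                          history = data.frame(epoch = 1L, loss = 0.5,
                                               train_error = 0.2)),
                     class = "rbc_cnn")
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(back$params, model$params, tolerance = 1e-12)
  set.seed(12)
  x <- array(runif(16 * 16 * 3) * 255, c(16, 16, 3))
  expect_identical(predict_cnn(model, x)$labels,
                   predict_cnn(back, x)$labels)
})
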