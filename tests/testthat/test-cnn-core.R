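# The depthwise-separable CNN engine: architecture bookkeeping, exact
# gradients, capacity, determinism.

test_that("architecture layer counts match both scales", {
  full <- count_layers("full")
  expect_equal(full$common_conv, 3)
  expect_equal(full$separable, 33)
  expect_equal(full$modules, 14)
  mini <- count_layers("mini")
  expect_equal(mini$modules, 3) # 2 separable residual blocks + stem
  expect_equal(mini$separable, 4)
})

test_that("backpropagation matches finite differences", {
  ns <- asNamespace("emofc")
  set.seed(7)
  arch <- ns$build_arch("mini")
  x <- array(runif(6 * 10 * 1 * 3), dim = c(6, 10, 1, 3))
  y <- c(1L, 2L, 1L)
  params <- ns$init_params(arch, 1)
  loss_fn <- function(p) {
    pr <- ns$softmax_probs(ns$net_forward(arch, p, x)$z)
    -sum(log(pr[cbind(y, 1:3)])) / 3
  }
  fw <- ns$net_forward(arch, params, x)
  probs <- ns$softmax_probs(fw$z)
  onehot <- matrix(0, 2, 3)
  onehot[cbind(y, 1:3)] <- 1
  grads <- ns$net_backward(arch, params, fw$caches, (probs - onehot) / 3)
  eps <- 1e-6
  cases <- list(
    list(\(p) p[[1]]$w, \(p, v) {
      p[[1]]$w <- v
      p
    }, grads[[1]]$w),
    list(\(p) p[[3]]$sep[[1]]$dw, \(p, v) {
      p[[3]]$sep[[1]]$dw <- v
      p
    }, grads[[3]]$sep[[1]]$dw),
    list(\(p) p[[3]]$skip$w, \(p, v) {
      p[[3]]$skip$w <- v
      p
    }, grads[[3]]$skip$w),
    list(\(p) p[[4]]$sep[[2]]$pw, \(p, v) {
      p[[4]]$sep[[2]]$pw <- v
      p
    }, grads[[4]]$sep[[2]]$pw),
    list(\(p) p[[6]]$w, \(p, v) {
      p[[6]]$w <- v
      p
    }, grads[[6]]$w)
  )
  set.seed(9)
  for (cs in cases) {
    arr <- cs[[1]](params)
    for (i in sample(length(arr), 3)) {
      v <- arr
      v[i] <- v[i] + eps
      num <- (loss_fn(cs[[2]](params, v)) - loss_fn(params)) / eps
      expect_lt(
        abs(num - cs[[3]][i]) / max(1e-4, abs(num) + abs(cs[[3]][i])),
        1e-4
      )
    }
  }
})

test_that("softmax outputs are probabilities summing to one", {
  s <- make_separable_samples(10, seed = 2)
  fit <- train_cnn(s$image, s$label,
    cfg = model_config(epochs = 2, batch_size = 8, seed = 1)
  )
  p <- predict(fit, s$image, type = "prob")
  expect_equal(dim(p), c(20, 2))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(p >= 0))
})

test_that("the CNN fits a linearly separable image set in few epochs", {
  s <- make_separable_samples(60, seed = 3)
  expect_true(linearly_separable(s)) # oracle: a linear model gets 100%
  fit <- train_cnn(s$image, s$label,
    cfg = model_config(
      epochs = 5, batch_size = 16, learning_rate = 1e-2,
      seed = 1
    )
  )
  expect_gt(tail(fit$history$train_accuracy, 1), 0.95)
})

test_that("a single batch can be memorized (capacity sanity check)", {
  s <- make_separable_samples(4, seed = 5, offset = 40)
  fit <- train_cnn(s$image, s$label,
    cfg = model_config(
      epochs = 150, batch_size = 8, learning_rate = 1e-2,
      seed = 1
    )
  )
  expect_equal(tail(fit$history$train_accuracy, 1), 1)
})

test_that("training is deterministic under a fixed seed", {
  s <- make_separable_samples(20, seed = 6)
  cfg <- model_config(epochs = 3, batch_size = 16, seed = 123)
  f1 <- train_cnn(s$image, s$label, cfg = cfg)
  f2 <- train_cnn(s$image, s$label, cfg = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(
    predict(f1, s$image, type = "prob"),
    predict(f2, s$image, type = "prob")
  )
})

test_that("permuted labels give chance-level training signal", {
  set.seed(11)
  accs <- vapply(1:3, function(i) {
    s <- make_separable_samples(30, seed = 30 + i)
    s$label <- sample(s$label)
    cv <- cross_validate(s,
      model = "mini", k = 5, seed = i,
      cfg = model_config(epochs = 4, batch_size = 16, learning_rate = 1e-2)
    )
    mean(cv$accuracy)
  }, numeric(1))
  expect_gt(mean(accs), 35)
  expect_lt(mean(accs), 65)
})

test_that("empty and malformed training inputs error", {
  expect_error(
    train_cnn(list(), character(0)),
    class = "emofc_config_error"
  )
  s <- make_separable_samples(4, seed = 1)
  expect_error(
    train_cnn(s$image, rep("XX", 8)),
    class = "emofc_config_error"
  )
})

test_that("model summaries expose the architecture and history", {
  s <- make_separable_samples(8, seed = 1)
  fit <- train_cnn(s$image, s$label,
    x_val = s$image, y_val = s$label,
    cfg = model_config(epochs = 2, batch_size = 8)
  )
  g <- glance(fit)
  expect_equal(g$separable_conv_layers, 4L)
  expect_equal(nrow(tidy(fit)), 2)
  expect_false(is.na(g$val_accuracy))
})
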