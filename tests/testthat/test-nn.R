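test_that("a built model allocates exactly the declared parameters and is seed-reproducible", {
  spec <- modified_lenet5_spec()
  m <- build_model(spec, seed = 4)
  expect_equal(n_allocated_parameters(m), count_parameters(spec)$total)
  # forward on a zero tensor yields valid distributions
  x0 <- list(x = array(0, dim = c(3, 900, 2)), y = c("A", "N", "A"))
  p <- predict_proba(m, x0)
  expect_true(all(p$prob_apnea >= 0 & p$prob_apnea <= 1))
  # same seed, same initial outputs; different seed differs (on a
  # non-degenerate input)
  set.seed(0)
  xr <- list(x = array(rnorm(3 * 900 * 2), dim = c(3, 900, 2)),
             y = c("A", "N", "A"))
  m2 <- build_model(spec, seed = 4)
  expect_identical(predict_proba(m2, xr)$prob_apnea,
                   predict_proba(m, xr)$prob_apnea)
  m3 <- build_model(spec, seed = 5)
  expect_false(identical(predict_proba(m3, xr)$prob_apnea,
                         predict_proba(m, xr)$prob_apnea))
})

test_that("training separates a constructed fixture and is fully seed-determined", {
  xy <- separable_windows(n = 200)
  cfg <- train_config(epochs = 30, batch_size = 64, seed = 5)
  m <- train_cnn(build_model(modified_lenet5_spec(), seed = 1), xy, cfg)
  # pre-training loss of a near-uniform softmax on balanced classes ~ log 2
  expect_equal(m$history$train_loss[1], log(2), tolerance = 0.02)
  # loss decreases over training
  expect_lt(tail(m$history$train_loss, 1), m$history$train_loss[1])
  # the separable fixture is learned
  pred <- predict_proba(m, xy)
  expect_gte(mean(pred$label == xy$y), 0.95)
  # identical loss history on a seed-fixed rerun
  m2 <- train_cnn(build_model(modified_lenet5_spec(), seed = 1), xy, cfg)
  expect_identical(m$history$train_loss, m2$history$train_loss)
  expect_identical(m$params, m2$params)
})

test_that("training refuses a single-class window set", {
  xy <- separable_windows(n = 20)
  xy$y <- rep("A", 20)
  expect_error(train_cnn(build_model(modified_lenet5_spec(), seed = 1), xy),
               "both classes")
})

test_that("inference is stateless, order-equivariant and dropout-free", {
  xy <- separable_windows(n = 24)
  m <- train_cnn(build_model(modified_lenet5_spec(), seed = 2), xy,
                 train_config(epochs = 2, batch_size = 12, seed = 3,
                              validation_split = 0))
  p1 <- predict_proba(m, xy)
  # dropout disabled at inference: repeated passes identical
  p2 <- predict_proba(m, xy)
  expect_identical(p1$prob_apnea, p2$prob_apnea)
  # rows sum to one by the softmax contract (prob_apnea in [0,1])
  expect_true(all(p1$prob_apnea >= 0 & p1$prob_apnea <= 1))
  # shuffled input gives correspondingly shuffled output
  set.seed(9)
  perm <- sample(24)
  xp <- list(x = xy$x[perm, , , drop = FALSE], y = xy$y[perm])
  pp <- predict_proba(m, xp)
  expect_equal(pp$prob_apnea, p1$prob_apnea[perm], tolerance = 1e-12)
  # hard label matches the 0.5 threshold on the probability
  expect_identical(p1$label, ifelse(p1$prob_apnea >= 0.5, "A", "N"))
  # empty input yields an empty prediction set
  expect_equal(nrow(predict_proba(m, list())), 0)
})

test_that("with dropout disabled the training-mode forward pass equals evaluation mode", {
  spec <- modified_lenet5_spec(dropout_rate = 0)
  m <- build_model(spec, seed = 6)
  x <- array(rnorm(5 * 900 * 2), dim = c(5, 900, 2))
  f_train <- apneanet:::forward_cnn(m, x, training = TRUE)$probs
  f_eval <- apneanet:::forward_cnn(m, x, training = FALSE)$probs
  expect_identical(f_train, f_eval)
})

test_that("backpropagation gradients match finite differences on a tiny network", {
  # independent oracle: numerical differentiation of the loss
  tiny <- structure(list(
    input_length = 12L, input_channels = 2L,
    layers = list(
      layer_spec("conv1d", filters = 3L, kernel = 3L, stride = 2L,
                 activation = "relu", name = "c1"),
      layer_spec("maxpool1d", kernel = 2L, stride = 2L, name = "p1"),
      layer_spec("dense", filters = 4L, activation = "relu", name = "d1"),
      layer_spec("dense", filters = 2L, activation = "softmax",
                 name = "out"))),
    class = "model_spec")
  m <- build_model(tiny, seed = 8)
  set.seed(12)
  x <- array(rnorm(4 * 12 * 2), dim = c(4, 12, 2))
  y1h <- apneanet:::labels_to_onehot(c("A", "N", "A", "N"))
  loss_at <- function(model) {
    p <- apneanet:::forward_cnn(model, x, training = FALSE)$probs
    cross_entropy_loss(y1h, p)
  }
  fw <- apneanet:::forward_cnn(m, x, training = FALSE, keep_cache = TRUE)
  grads <- apneanet:::backward_cnn(m, fw$caches, fw$probs, y1h,
                                   rep(1, 4))
  eps <- 1e-6
  for (nm in names(grads)) {
    w <- m$params[[nm]]$w
    for (idx in sample(length(w), min(6, length(w)))) {
      mp <- m
      mp$params[[nm]]$w[idx] <- w[idx] + eps
      mm <- m
      mm$params[[nm]]$w[idx] <- w[idx] - eps
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_equal(grads[[nm]]$w[idx], num, tolerance = 1e-4)
    }
  }
})
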