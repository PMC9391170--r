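test_that("attention columns are softmax-normalized convex combinations", {
  set.seed(61)
  k <- 5; m <- 7
  E <- matrix(rnorm(k * m), k, m)
  wq <- matrix(rnorm(k * k, sd = 0.3), k, k)
  wk <- matrix(rnorm(k * k, sd = 0.3), k, k)
  wv <- matrix(rnorm(k * k, sd = 0.3), k, k)
  H <- attention_layer(E, wq, wk, wv)
  A <- attr(H, "weights")
  expect_equal(unname(colSums(A)), rep(1, m), tolerance = 1e-6)
  expect_true(all(A >= 0 & A <= 1))

  # convex-hull property: each output column within V's columnwise range
  V <- wv %*% E
  expect_true(all(H <= apply(V, 1, max) + 1e-12))
  expect_true(all(H >= apply(V, 1, min) - 1e-12))

  # w_k = 0: uniform weights, every output column is the mean of V's columns
  H0 <- attention_layer(E, wq, matrix(0, k, k), wv)
  expect_equal(unname(attr(H0, "weights")), matrix(1 / m, m, m))
  expect_equal(unname(H0), matrix(rowMeans(V), k, m), ignore_attr = TRUE)

  # m = 1: softmax of a single element is 1
  H1 <- attention_layer(E[, 1, drop = FALSE], wq, wk, wv)
  expect_equal(unname(H1), unname(wv %*% E[, 1, drop = FALSE]),
               ignore_attr = TRUE)

  expect_error(attention_layer(E, wq[, -1], wk, wv), "shapes")
})

test_that("stacked attention composes two layers without residuals", {
  set.seed(62)
  k <- 4; m <- 6
  E <- matrix(rnorm(k * m), k, m)
  cfg <- sac_config(n_filters = 2, windows = 2, seed = 1)
  params <- init_sac_params(k, m, cfg)
  H <- stack_attention(E, params)
  expect_equal(dim(H), c(k, m))
  expect_identical(H, stack_attention(E, params)) # deterministic

  # zero query/key and identity value maps: two rounds of column means
  params$wq1 <- params$wk1 <- params$wq2 <- params$wk2 <- matrix(0, k, k)
  params$wv1 <- params$wv2 <- diag(k)
  Hm <- stack_attention(E, params)
  expect_equal(unname(Hm), matrix(rowMeans(E), k, m), ignore_attr = TRUE)
})

test_that("conv_pool matches a brute-force convolution oracle", {
  set.seed(63)
  k <- 4; m <- 11
  cfg <- sac_config(n_filters = 3, windows = c(2, 3, 4), seed = 2)
  params <- init_sac_params(k, m, cfg)
  E <- matrix(rnorm(k * m), k, m)
  Z <- conv_pool(E, params$conv)
  expect_length(Z, 3 * 3)
  expect_equal(Z, brute_force_conv_pool(E, params$conv))

  # zero input with zero bias pools to zero
  expect_equal(conv_pool(matrix(0, k, m), params$conv), rep(0, 9))

  # window wider than the sequence is an error
  expect_error(conv_pool(E[, 1:3], params$conv), "window size 4")
})

test_that("the output layer is an affine map with softmax probabilities", {
  fc_w <- matrix(0, 2, 4)
  out <- predict_scores(rep(1, 4), fc_w, c(0, 0))
  expect_equal(out$probs, c(0.5, 0.5))
  out2 <- predict_scores(rep(0, 4), fc_w, c(log(2), 0))
  expect_equal(out2$probs, c(2 / 3, 1 / 3))
  set.seed(64)
  fc_w <- matrix(rnorm(8), 2, 4)
  out3 <- predict_scores(rnorm(4), fc_w, rnorm(2))
  expect_equal(sum(out3$probs), 1)
  expect_length(out3$scores, 2)
  expect_error(predict_scores(rep(0, 3), fc_w, c(0, 0)), "match")
})

test_that("cross-entropy loss has its closed-form values and symmetry", {
  expect_equal(cross_entropy_loss(rep(0.5, 10), rep(c(0, 1), 5)), log(2))
  expect_lte(cross_entropy_loss(c(1, 0, 1), c(1, 0, 1)), 2e-7)
  set.seed(65)
  p <- runif(20, 0.05, 0.95); y <- rbinom(20, 1, 0.5)
  expect_equal(cross_entropy_loss(p, y), cross_entropy_loss(1 - p, 1 - y))
  expect_gte(cross_entropy_loss(p, y), 0)
})

test_that("compiled forward pass equals the definitional R composition", {
  set.seed(66)
  k <- 5; m <- 6; n <- 7
  cfg <- sac_config(n_filters = 4, windows = c(2, 3), seed = 3)
  params <- init_sac_params(k, m, cfg)
  E <- array(rnorm(k * m * n), c(k, m, n))
  fwd <- kgdx:::sac_forward_cpp(E, params)
  meanA <- matrix(0, m, m)
  for (s in seq_len(n)) {
    ref <- kgdx:::sac_forward_r(E[, , s], params)
    expect_equal(unname(fwd$probs[s, ]), unname(ref$probs))
    meanA <- meanA + ref$attention1 / n
  }
  expect_equal(fwd$mean_attention1, meanA)
})

test_that("analytic gradients agree with numeric differentiation", {
  set.seed(67)
  k <- 4; m <- 5; n <- 3
  cfg <- sac_config(n_filters = 2, windows = c(2, 3), seed = 4)
  params <- init_sac_params(k, m, cfg)
  E <- array(rnorm(k * m * n), c(k, m, n))
  y <- c(0L, 1L, 0L)
  lg <- kgdx:::sac_loss_grad_cpp(E, y, params)
  num_loss <- function(p) {
    mean(vapply(seq_len(n), function(s) {
      -log(kgdx:::sac_forward_r(E[, , s], p)$probs[y[s] + 1])
    }, numeric(1)))
  }
  expect_equal(lg$loss, num_loss(params))

  eps <- 1e-6
  pick <- function(w) sample(length(w), min(8, length(w)))
  paths <- list(
    list(get = function(p) p$wq1, set = function(p, w) {p$wq1 <- w; p},
         g = lg$grads$wq1),
    list(get = function(p) p$wk2, set = function(p, w) {p$wk2 <- w; p},
         g = lg$grads$wk2),
    list(get = function(p) p$wv1, set = function(p, w) {p$wv1 <- w; p},
         g = lg$grads$wv1),
    list(get = function(p) p$conv[[1]]$W,
         set = function(p, w) {p$conv[[1]]$W <- w; p},
         g = lg$grads$conv[[1]]$W),
    list(get = function(p) p$fc_w, set = function(p, w) {p$fc_w <- w; p},
         g = lg$grads$fc_w)
  )
  for (pp in paths) {
    w <- pp$get(params)
    for (i in pick(w)) {
      wp <- w; wp[i] <- wp[i] + eps
      wm <- w; wm[i] <- wm[i] - eps
      num <- (num_loss(pp$set(params, wp)) - num_loss(pp$set(params, wm))) /
        (2 * eps)
      expect_equal(pp$g[i], num, tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss and is seed-deterministic", {
  d <- separable_encoding()
  cfg <- sac_config(epochs = 20, batch_size = 16, learning_rate = 2e-3,
                    dropout = 0.2, n_filters = 3, windows = c(2, 3), seed = 5)
  fit <- train_sac(d$E, d$y, cfg)
  expect_lt(fit$history$train_loss[20], fit$history$train_loss[1])
  pred <- predict(fit, d$E)
  expect_gt(mean(pred$class == d$y), 0.9)

  fit2 <- train_sac(d$E, d$y, cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params$fc_w, fit2$params$fc_w)

  # zero epochs returns the initialization unchanged
  cfg0 <- sac_config(epochs = 0, n_filters = 3, windows = c(2, 3), seed = 5)
  fit0 <- train_sac(d$E, d$y, cfg0)
  expect_equal(fit0$params$wq1,
               init_sac_params(dim(d$E)[1], dim(d$E)[2], cfg0)$wq1)

  expect_error(train_sac(d$E, rep(1L, length(d$y)), cfg), "single class")
})

test_that("the loss history tracks held-out data when supplied", {
  d <- separable_encoding(n = 40)
  cfg <- sac_config(epochs = 5, batch_size = 8, n_filters = 2, windows = 2,
                    seed = 6)
  fit <- train_sac(d$E[, , 1:30], d$y[1:30], cfg,
                   test = list(E = d$E[, , 31:40], y = d$y[31:40]))
  expect_true(all(c("train_loss", "test_loss") %in% names(fit$history)))
  expect_equal(nrow(fit$history), 5)
  expect_true(all(is.finite(fit$history$test_loss)))
})

test_that("exported attention weights are a row-stochastic indicator map", {
  d <- separable_encoding(k = 4, m = 5, n = 30)
  dimnames(d$E)[[2]] <- paste0("ind", 1:5)
  cfg <- sac_config(epochs = 3, batch_size = 8, n_filters = 2, windows = 2,
                    seed = 7)
  fit <- train_sac(d$E, d$y, cfg)
  W <- export_attention(fit, d$E)
  expect_equal(dim(W), c(5, 5))
  expect_equal(unname(rowSums(W)), rep(1, 5), tolerance = 1e-6)
  expect_true(all(W >= 0 & W <= 1))
  expect_equal(rownames(W), paste0("ind", 1:5))

  # single-sample export equals that sample's own weight matrix
  W1 <- export_attention(fit, d$E[, , 1, drop = FALSE])
  ref <- kgdx:::sac_forward_r(d$E[, , 1], fit$params)
  expect_equal(unname(W1), unname(t(ref$attention1)))

  fit0 <- train_sac(d$E, d$y, sac_config(epochs = 0, n_filters = 2,
                                         windows = 2, seed = 7))
  expect_error(export_attention(fit0, d$E), "not been trained")
})

test_that("max pooling is permutation-consistent and shift-monotone", {
  set.seed(68)
  k <- 3; m <- 6
  cfg <- sac_config(n_filters = 4, windows = 2, seed = 8)
  params <- init_sac_params(k, m, cfg)
  E <- matrix(rnorm(k * m), k, m)
  Z <- conv_pool(E, params$conv)
  # permuting filters within a window permutes the outputs identically
  perm <- c(3, 1, 4, 2)
  conv2 <- params$conv
  conv2[[1]]$W <- conv2[[1]]$W[perm, ]
  conv2[[1]]$b <- conv2[[1]]$b[perm]
  expect_equal(conv_pool(E, conv2), Z[perm])
  # raising the bias raises every pooled value monotonically
  conv3 <- params$conv
  conv3[[1]]$b <- conv3[[1]]$b + 1
  expect_true(all(conv_pool(E, conv3) >= Z))
})
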