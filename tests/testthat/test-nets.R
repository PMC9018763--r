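# Network engine: shapes, activations, losses, gradients, training loop.

tiny_cfg <- function(heads, cin = 1L, patch = c(8L, 8L, 8L), classifier = NULL)
  net_config(cin, levels = 2L, base_channels = 2L, patch = patch,
             heads = heads, classifier = classifier, convs_per_stage = 1L)

test_that("head outputs respect shapes and activation ranges", {
  cfg <- tiny_cfg(list(head_spec("mask", 1L, "sigmoid")), patch = c(16L, 16L, 16L))
  net <- build_segnet(cfg, seed = 1)
  x <- array(runif(16^3), c(1, 16, 16, 16))
  out <- predict_patch(net, x)
  expect_identical(dim(out$mask), c(1L, 16L, 16L, 16L))
  expect_true(all(out$mask > 0 & out$mask < 1))

  cfg2 <- tiny_cfg(list(head_spec("offset", 3L, "linear"),
                        head_spec("mask", 1L, "sigmoid")))
  net2 <- build_segnet(cfg2, seed = 2)
  out2 <- predict_patch(net2, array(rnorm(8^3), c(1, 8, 8, 8)))
  expect_identical(dim(out2$offset), c(3L, 8L, 8L, 8L))
  expect_identical(dim(out2$mask), c(1L, 8L, 8L, 8L))

  cfg3 <- tiny_cfg(list(head_spec("prob", 3L, "softmax")), cin = 2L)
  net3 <- build_segnet(cfg3, seed = 3)
  out3 <- predict_patch(net3, array(rnorm(2 * 8^3), c(2, 8, 8, 8)))
  sums <- apply(out3$prob, 2:4, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(out3$prob >= 0 & out3$prob <= 1))
})

test_that("a classifier adds 32 logits over the bottleneck", {
  cfg <- tiny_cfg(list(head_spec("mask", 1L, "sigmoid")), cin = 3L,
                  classifier = list(n_classes = 32L))
  net <- build_segnet(cfg, seed = 4)
  out <- predict_patch(net, array(runif(3 * 8^3), c(3, 8, 8, 8)))
  expect_length(out$logits, 32L)
})

test_that("config constraints are enforced", {
  expect_error(net_config(1, levels = 3, base_channels = 2, patch = c(10, 10, 10),
                          heads = list(head_spec("m", 1))),
               "divisible")
  expect_error(net_config(1, levels = 2, base_channels = 2, patch = c(8, 8, 8),
                          heads = list(head_spec("m", 1), head_spec("m", 2))),
               "unique")
})

test_that("losses match closed forms and degenerate rules", {
  heads <- list(head_spec("offset", 3L, "linear", masked = TRUE),
                head_spec("mask", 1L, "sigmoid"))
  y <- array(runif(3 * 4^3), c(3, 4, 4, 4))
  m <- array(TRUE, c(4, 4, 4))
  # perfect fit -> zero L2
  out <- compute_losses(list(offset = y), list(offset = y), m, heads)
  expect_equal(out$per_head$offset, 0)
  # constant 0.5 prediction on any binary target -> BCE = ln 2
  yb <- array(sample(0:1, 4^3, replace = TRUE), c(1, 4, 4, 4))
  p <- array(0.5, c(1, 4, 4, 4))
  out <- compute_losses(list(mask = p), list(mask = yb), NULL, heads)
  expect_equal(out$per_head$mask, log(2), tolerance = 1e-12)
  # empty foreground mask -> offset loss defined as 0
  out <- compute_losses(list(offset = y + 1), list(offset = y),
                        array(FALSE, c(4, 4, 4)), heads)
  expect_equal(out$per_head$offset, 0)
  # weighted total
  cfg <- train_config(loss_weights = c(mask = 2))
  out <- compute_losses(list(mask = p), list(mask = yb), NULL, heads, cfg)
  expect_equal(out$total, 2 * log(2), tolerance = 1e-12)
  # shape mismatch
  expect_error(compute_losses(list(mask = p), list(mask = yb[, 1:2, , , drop = FALSE]),
                              NULL, heads),
               "mismatch")
})

test_that("backpropagated gradients match finite differences", {
  cfg <- tiny_cfg(list(head_spec("mask", 1L, "sigmoid"),
                       head_spec("offset", 3L, "linear", masked = TRUE)),
                  patch = c(4L, 4L, 4L), classifier = list(n_classes = 5L, hidden = 4L))
  net <- build_segnet(cfg, seed = 9)
  set.seed(10)
  msk <- array(runif(4^3) > 0.4, c(4, 4, 4))
  sample_ <- list(x = array(runif(4^3), c(1, 4, 4, 4)),
                  targets = list(mask = array(as.numeric(runif(4^3) > 0.5), c(1, 4, 4, 4)),
                                 offset = array(rnorm(3 * 4^3), c(3, 4, 4, 4))),
                  mask = msk, class = 3L)
  tc <- train_config()
  sg <- dentseg:::train_step_grads(net, sample_, tc)

  loss_at <- function(net) dentseg:::train_step_grads(net, sample_, tc)$loss
  eps <- 1e-5
  check <- function(getter, setter, gval, label) {
    for (k in seq_len(3)) {
      net2 <- net
      w <- getter(net2)
      i <- ((k * 7L) %% length(w)) + 1L
      w[i] <- w[i] + eps
      net2 <- setter(net2, w)
      num <- (loss_at(net2) - sg$loss) / eps
      expect_equal(num, gval(i), tolerance = 1e-3 * max(1, abs(num)),
                   label = paste(label, "param", i))
    }
  }
  # encoder conv weights
  check(function(n) n$params$enc[[1]][[1]]$w,
        function(n, w) { n$params$enc[[1]][[1]]$w <- w; n },
        function(i) sg$grads$enc[[1]][[1]]$w[i], "enc1")
  # decoder conv weights
  check(function(n) n$params$dec[[1]][[1]]$w,
        function(n, w) { n$params$dec[[1]][[1]]$w <- w; n },
        function(i) sg$grads$dec[[1]][[1]]$w[i], "dec1")
  # head weights
  check(function(n) n$params$heads$mask$w,
        function(n, w) { n$params$heads$mask$w <- w; n },
        function(i) sg$grads$heads$mask$w[i], "mask head")
  # classifier
  check(function(n) n$params$cls[[2]]$w,
        function(n, w) { n$params$cls[[2]]$w <- w; n },
        function(i) sg$grads$cls[[2]]$w[i], "fc2")
})

test_that("the early-stopping rule fires where the patience rule dictates", {
  # improvement at epoch 2, then flat: 5 unchanged epochs end at epoch 7
  expect_equal(early_stop_epoch(c(1.0, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9), 5, 0), 7L)
  # strictly decreasing: never stops early
  expect_equal(early_stop_epoch(seq(1, 0.1, by = -0.1), 5, 0), 10L)
  # immediate plateau stops at epoch 6 (first epoch sets the best)
  expect_equal(early_stop_epoch(rep(1, 20), 5, 0), 6L)
  # tolerance masks sub-threshold improvements
  expect_equal(early_stop_epoch(c(1, 0.999, 0.998, 0.997, 0.996, 0.995), 5, 0.01), 6L)
  expect_equal(early_stop_epoch(c(1, 0.9, 0.8, 0.7), 2, 0), 4L)
})

test_that("training is deterministic and stops via the patience rule", {
  cfg <- tiny_cfg(list(head_spec("mask", 1L, "sigmoid")))
  mk_sample <- function(seed) {
    set.seed(seed)
    x <- array(runif(8^3), c(1, 8, 8, 8))
    list(x = x, targets = list(mask = array(as.numeric(x > 0.5), c(1, 8, 8, 8))))
  }
  tr <- lapply(1:3, mk_sample)
  va <- lapply(4:5, mk_sample)
  tc <- train_config(max_epochs = 6L, patience_epochs = 3L, seed = 42L)
  r1 <- train_model(build_segnet(cfg, seed = 1), tr, va, tc)
  r2 <- train_model(build_segnet(cfg, seed = 1), tr, va, tc)
  expect_identical(r1$history, r2$history)
  expect_true(nrow(r1$history) <= 6L)
  expect_error(train_model(build_segnet(cfg, seed = 1), list(), va, tc), "nonempty")
})

test_that("one phantom crop is overfit within a few epochs", {
  ph <- fixture_phantom("small")
  v <- clip_normalize(ph$image)
  win <- list(start = c(13L, 13L, 13L), size = c(24L, 24L, 24L))
  x <- array(dentseg:::crop_window(v$voxels, win), c(1, 24, 24, 24))
  y <- array(as.numeric(dentseg:::crop_window(ph$gt$tooth_labels$voxels > 0, win)),
             c(1, 24, 24, 24))
  cfg <- net_config(1L, 2L, 4L, c(24L, 24L, 24L),
                    heads = list(head_spec("mask", 1L, "sigmoid")),
                    convs_per_stage = 1L)
  net <- build_segnet(cfg, seed = 3)
  s <- list(x = x, targets = list(mask = y))
  r <- train_model(net, list(s), list(s),
                   train_config(learning_rate = 4e-3, max_epochs = 10L,
                                patience_epochs = 10L, seed = 1L))
  expect_lt(tail(r$history$train_loss, 1), r$history$train_loss[1])
  expect_lt(tail(r$history$val_loss, 1), r$history$val_loss[1])
})

test_that("patchwise prediction averages tiles consistently", {
  ph <- fixture_phantom("small")
  gt <- ph$gt
  v <- clip_normalize(ph$image)
  # constant predictor: output independent of tiling
  const_pred <- function(x, window) list(mask = array(0.3, c(1L, dim(x)[2:4])))
  out <- predict_patchwise(const_pred, v, c(24, 24, 24), overlap_fraction = 0.5)
  expect_true(all(abs(out$mask - 0.3) < 1e-12))

  # oracle passthrough: tiling reproduces the full-volume maps exactly
  orc <- oracle_predictor(gt, "roi")
  out1 <- predict_patchwise(orc, v, c(24, 24, 24), overlap_fraction = 0.25)
  expect_equal(out1$mask, array(as.numeric(gt$tooth_labels$voxels > 0), dim(v$voxels)))

  # single window equals a direct call
  out2 <- predict_patchwise(orc, v, dim(v$voxels), overlap_fraction = 0)
  direct <- predict_patch(orc, array(v$voxels, c(1L, dim(v$voxels))),
                          window = list(start = c(1L, 1L, 1L), size = dim(v$voxels)))
  expect_equal(out2$mask, array(direct$mask, dim(v$voxels)))
})
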