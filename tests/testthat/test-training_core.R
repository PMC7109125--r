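test_that("median frequency balancing upweights the rare class correctly", {
  # equal frequencies -> unit weights
  w <- median_frequency_weights(c(a = 100, b = 100), c(a = 10, b = 10), 100)
  expect_equal(unname(w$weights), c(1, 1))

  # two classes with frequencies 0.99 / 0.01
  w2 <- median_frequency_weights(c(background = 990, canal = 10),
                                 c(background = 10, canal = 10), 100)
  expect_equal(w2$weights[["background"]], 0.5 / 0.99, tolerance = 1e-12)
  expect_equal(w2$weights[["canal"]], 50, tolerance = 1e-12)

  # the clinical operating point: a canal/background frequency ratio of
  # 5.3/1000 yields weights in the ratio 5.3 : 1000 (background : canal)
  w3 <- median_frequency_weights(c(background = 1000, canal = 5.3),
                                 c(background = 100, canal = 100), 1000)
  ratio <- w3$weights[["background"]] / w3$weights[["canal"]]
  expect_equal(ratio, 5.3 / 1000, tolerance = 1e-12)
  expect_equal(unname(1000 * w3$weights / w3$weights[["canal"]]),
               c(5.3, 1000), tolerance = 1e-9)

  expect_error(median_frequency_weights(c(a = 1, b = 1), c(a = 0, b = 1), 10),
               "presence")
})

test_that("weighted BCE reduces to the reference cross-entropy at unit weights", {
  set.seed(31)
  p <- array(runif(64, 0.01, 0.99), c(4, 4, 4))
  t_ <- array(runif(64) > 0.5, c(4, 4, 4))
  ref <- -mean(t_ * log(p) + (1 - t_) * log(1 - p))
  expect_equal(weighted_bce(p, t_), ref, tolerance = 1e-10)

  # single canal voxel at p = 0.5 under the 5.3:1000 weights
  loss <- weighted_bce(array(0.5, c(1, 1)), array(TRUE, c(1, 1)),
                       manual_weights(c(background = 5.3, canal = 1000)))
  expect_equal(loss, 1000 * log(2), tolerance = 1e-9)

  # perfect prediction is clipped, not infinite
  hit <- weighted_bce(array(1, c(2, 2)), array(TRUE, c(2, 2)))
  expect_lt(hit, 1e-5)
  expect_gt(hit, 0)
})

test_that("dataset splitting follows the floor arithmetic and is reproducible", {
  sp <- split_dataset(49094, c(6, 2, 2), seed = 1)
  expect_length(sp$test, 9818)
  expect_length(sp$valid, 9818)
  expect_length(sp$train, 49094 - 2 * 9818)

  sp10 <- split_dataset(10, c(6, 2, 2), seed = 3)
  expect_equal(lengths(sp10), c(train = 6L, valid = 2L, test = 2L))

  expect_identical(split_dataset(500, seed = 9), split_dataset(500, seed = 9))
  expect_false(identical(split_dataset(500, seed = 9),
                         split_dataset(500, seed = 10)))
})

test_that("splits are disjoint and exhaustive for random sizes and ratios", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:500, 1)
    ratio <- sample(1:6, 3, replace = TRUE)
    sp <- split_dataset(n, ratio, seed = i)
    all_idx <- c(sp$train, sp$valid, sp$test)
    expect_equal(sort(all_idx), 1:n)
    expect_equal(anyDuplicated(all_idx), 0)
  }
})

test_that("stratified splits balance canal-containing items", {
  labels <- rep(c(TRUE, FALSE), c(40, 160))
  sp <- split_dataset(200, c(6, 2, 2), seed = 2, labels = labels,
                      stratified = TRUE)
  expect_equal(sort(c(sp$train, sp$valid, sp$test)), 1:200)
  expect_equal(sum(labels[sp$test]), 8)    # 40 * 2/10
  expect_equal(sum(labels[sp$valid]), 8)
  expect_equal(sum(labels[sp$train]), 24)
  expect_error(split_dataset(5, labels = rep(TRUE, 5), stratified = TRUE),
               "stratification")
})

test_that("same-padding 2D U-Net preserves the input resolution", {
  m <- build_model(model_spec("unet2d", input_size = 256), seed = 0)
  expect_equal(m$output_size, c(256L, 256L))
  conv_rows <- m$description[m$description$type == "conv", ]
  expect_true(all(vapply(strsplit(conv_rows$out_size, "x"),
                         function(s) length(unique(s)) == 1, logical(1))))
})

test_that("valid-padding 3D U-Net shapes match the independent recurrence", {
  # independent per-layer arithmetic: two 3^3 valid convolutions per level
  # (-2 each), 2x pooling thrice, then up-convolutions doubling the size
  s <- 132
  for (lv in 1:3) s <- (s - 4) / 2              # analysis path
  s <- s - 4                                    # bottleneck convolutions
  for (lv in 1:3) s <- 2 * s - 4                # synthesis path
  expect_equal(s, 44)

  m <- build_model(model_spec("unet3d"), seed = 0)
  expect_equal(m$output_size, c(44L, 44L, 44L))
  # spot-check intermediate sizes along the analysis path
  d <- m$description
  expect_equal(d$out_size[d$name == "enc1_conv2"], "128x128x128")
  expect_equal(d$out_size[d$name == "enc3_conv2"], "26x26x26")
  expect_equal(d$out_size[d$name == "bottom_conv2"], "9x9x9")

  expect_error(build_model(model_spec("unet3d", input_size = 20)),
               "valid padding|pool")
})

test_that("adjacent-slice input only changes the first convolution", {
  f <- unet_filters(8, 4)
  m1 <- build_model(model_spec("unet2d", filters = f, input_size = 64),
                    seed = 0)
  m5 <- build_model(model_spec("unet2d", filters = f, input_channels = 5,
                               input_size = 64), seed = 0)
  expect_equal(m5$spec$input_channels, 5L)  # a = 2 slices per side
  expect_equal(m5$description$out_size, m1$description$out_size)
  d_params <- m5$description$params - m1$description$params
  expect_equal(sum(d_params != 0), 1)
  expect_equal(which(d_params != 0), 1L)
  expect_equal(d_params[1], 9 * 4 * 8)  # 4 extra input channels
})

test_that("parameter counts match the per-layer hand oracle", {
  # tiny 2D U-Net, filters (2, 4, 8), 1 input channel
  m <- build_model(model_spec("unet2d", filters = c(2, 4, 8),
                              input_size = 16), seed = 0)
  conv <- function(cin, cout, k = 3) k * k * cin * cout + cout
  up <- function(cin, cout) 4 * cin * cout + cout
  oracle <- conv(1, 2) + conv(2, 2) +      # encoder 1
    conv(2, 4) + conv(4, 4) +              # encoder 2
    conv(4, 8) + conv(8, 8) +              # bottleneck
    up(8, 4) + conv(8, 4) + conv(4, 4) +   # decoder 2
    up(4, 2) + conv(4, 2) + conv(2, 2) +   # decoder 1
    conv(2, 2, k = 1)                      # classifier
  expect_equal(m$n_params, oracle)

  # tiny SegNet, base 1: 13 encoder convs (VGG plan), mirrored decoder in
  # which each stage's last conv steps down to the previous stage's width
  ms <- build_model(model_spec("segnet2d", filters = segnet_filters(1),
                               input_size = 32), seed = 0)
  f <- segnet_filters(1)
  enc_in <- c(1, f[-13])
  enc <- sum(9 * enc_in * f + f) + sum(2 * f)
  dec_in <-  c(8, 8, 8, 8, 8, 8, 4, 4, 4, 2, 2, 1, 1)  # dec13 ... dec1
  dec_out <- c(8, 8, 8, 8, 8, 4, 4, 4, 2, 2, 1, 1, 1)
  dec <- sum(9 * dec_in * dec_out + dec_out) + sum(2 * dec_out)
  cls <- 1 * f[1] * 2 + 2
  expect_equal(ms$n_params, enc + dec + cls)

  # tiny 3D U-Net, one level, base 2
  m3 <- build_model(model_spec("unet3d", filters = c(2), input_size = 20),
                    seed = 0)
  c3 <- function(cin, cout) 27 * cin * cout + cout
  bn <- function(c) 2 * c
  up3 <- function(cin, cout) 8 * cin * cout + cout
  oracle3 <- c3(1, 2) + bn(2) + c3(2, 4) + bn(4) +
    c3(4, 4) + bn(4) + c3(4, 8) + bn(8) +
    up3(8, 8) + c3(12, 4) + bn(4) + c3(4, 4) + bn(4) +
    (1 * 4 * 2 + 2)
  expect_equal(m3$n_params, oracle3)
})

test_that("patch sampling is exhaustive, bounded and reproducible", {
  set.seed(2)
  vol <- volume(array(rnorm(40^3), c(40, 40, 40)))
  msk <- binary_mask(array(FALSE, c(40, 40, 40)))

  exact <- sample_patches(vol, msk, patch_spec(3, 40), seed = 0)
  expect_length(exact, 3)
  for (p in exact) {
    expect_equal(p$corner, c(0L, 0L, 0L))
    expect_equal(p$x, vol$data)
  }

  a <- sample_patches(vol, msk, patch_spec(10, 16), seed = 5)
  b <- sample_patches(vol, msk, patch_spec(10, 16), seed = 5)
  expect_identical(lapply(a, `[[`, "corner"), lapply(b, `[[`, "corner"))

  expect_error(sample_patches(vol, msk, patch_spec(1, 64), seed = 0),
               "smaller")

  # the volumetric protocol: 64 patches of 132^3 from a 160^3 volume
  big <- volume(array(0, c(160, 160, 160)))
  bigm <- binary_mask(array(FALSE, c(160, 160, 160)))
  ps <- sample_patches(big, bigm, patch_spec(64, 132), seed = 1)
  corners <- do.call(rbind, lapply(ps, `[[`, "corner"))
  expect_true(all(corners >= 0 & corners <= 28))
  expect_length(ps, 64)
  # mask patches cropped to a valid-padding output region
  ps2 <- sample_patches(volume(array(0, c(140, 140, 140))),
                        binary_mask(array(FALSE, c(140, 140, 140))),
                        patch_spec(2, 132), seed = 1, valid_margin = 44)
  expect_equal(dim(ps2[[1]]$y), c(44L, 44L, 44L))
})

test_that("learning-rate schedules follow the stated decay semantics", {
  cfg3d <- train_config(learning_rate = 5e-4,
                        schedule = list(factor = 5, period = 5))
  expect_equal(canalseg:::epoch_lr(cfg3d, 1), 5e-4)
  expect_equal(canalseg:::epoch_lr(cfg3d, 5), 5e-4)
  expect_equal(canalseg:::epoch_lr(cfg3d, 6), 1e-4)   # decayed by 5 after 5
  expect_equal(canalseg:::epoch_lr(cfg3d, 11), 2e-5)

  cfg2d <- train_config(learning_rate = 1e-4, decay = 5e-4)
  expect_equal(canalseg:::epoch_lr(cfg2d, 1), 1e-4)
  expect_equal(canalseg:::epoch_lr(cfg2d, 3), 1e-4 / (1 + 5e-4 * 2))
})

test_that("training with zero epochs leaves the parameter fingerprint unchanged", {
  m <- build_model(model_spec("unet2d", filters = c(2, 4, 8),
                              input_size = 16), seed = 1)
  before <- param_fingerprint(m)
  out <- train_model(m, list(), train_config(epochs = 0))
  expect_identical(param_fingerprint(out$model), before)
  expect_equal(out$steps, 0L)
})

test_that("backpropagated gradients match numerical differentiation", {
  set.seed(6)
  m <- build_model(model_spec("unet2d", filters = c(2, 4), input_size = 8,
                              batch_norm = TRUE), seed = 6)
  x <- array(rnorm(64), c(8, 8, 1))
  y <- matrix(runif(64) > 0.7, 8, 8)
  w <- manual_weights(c(background = 1, canal = 3))
  lossfun <- function() {
    fw <- canalseg:::net_forward(m, list(x), train = TRUE)
    canalseg:::batch_loss_grad(fw$vals[[m$out]], list(y), w)$loss
  }
  canalseg:::zero_grads(m)
  fw <- canalseg:::net_forward(m, list(x), train = TRUE)
  lg <- canalseg:::batch_loss_grad(fw$vals[[m$out]], list(y), w)
  canalseg:::net_backward(m, fw, lg$dscores)
  eps <- 1e-6
  for (lname in names(m$layers)) {
    lay <- m$layers[[lname]]
    for (p in lay$param_names) {
      g <- lay[[paste0("d", p)]]
      i <- sample(length(g), 1)
      v0 <- lay[[p]][i]
      lay[[p]][i] <- v0 + eps; lp <- lossfun()
      lay[[p]][i] <- v0 - eps; lm <- lossfun()
      lay[[p]][i] <- v0
      num <- (lp - lm) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-3,
                   label = paste("grad", lname, p))
    }
  }
})

test_that("a short seeded run reduces the training loss", {
  set.seed(8)
  # toy task: bright blob on dark background
  mk <- function() {
    x <- array(rnorm(256, 0, 0.1), c(16, 16, 1))
    y <- matrix(FALSE, 16, 16)
    ci <- sample(5:12, 2)
    y[ci[1] + (-2:2), ci[2] + (-2:2)] <- TRUE
    x[, , 1][y] <- x[, , 1][y] + 1
    list(x = x, y = y)
  }
  data <- replicate(8, mk(), simplify = FALSE)
  m <- build_model(model_spec("unet2d", filters = c(4, 8), input_size = 16,
                              batch_norm = TRUE), seed = 8)
  fit <- train_model(m, data, train_config(learning_rate = 3e-3, epochs = 15,
                                           batch_size = 4, seed = 8))
  h <- fit$history$train_loss
  expect_lt(h[length(h)], h[1])
  expect_true(all(is.finite(h)))
})

test_that("best-on-validation selection restores the best checkpoint", {
  set.seed(12)
  mk <- function() {
    x <- array(rnorm(256, 0, 0.1), c(16, 16, 1))
    y <- matrix(FALSE, 16, 16); y[6:10, 6:10] <- TRUE
    x[, , 1][y] <- x[, , 1][y] + 1
    list(x = x, y = y)
  }
  data <- replicate(6, mk(), simplify = FALSE)
  m <- build_model(model_spec("unet2d", filters = c(2, 4), input_size = 16,
                              batch_norm = TRUE), seed = 12)
  fit <- train_model(m, data[1:4], train_config(learning_rate = 2e-3,
                                                epochs = 6, batch_size = 2,
                                                seed = 12),
                     valid = data[5:6])
  best <- min(fit$history$valid_loss, na.rm = TRUE)
  got <- canalseg:::eval_loss(fit$model, data[5:6],
                              manual_weights(c(background = 1, canal = 1)))
  expect_equal(got, best, tolerance = 1e-8)
})

test_that("encoder weight loading validates names and dimensions", {
  m <- build_model(model_spec("unet2d", filters = c(2, 4), input_size = 8),
                   seed = 0)
  f <- file.path(tempdir(), "w.rds")
  W <- array(1, dim(m$layers$enc1_conv1$W))
  saveRDS(list(enc1_conv1.W = W), f)
  m2 <- load_encoder_weights(m, f)
  expect_true(all(m2$layers$enc1_conv1$W == 1))
  saveRDS(list(enc1_conv1.W = array(1, c(2, 2, 1, 2))), f)
  expect_error(load_encoder_weights(m, f), "mismatch")
  expect_error(load_encoder_weights(m, file.path(tempdir(), "no.rds")),
               "not found")
})
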