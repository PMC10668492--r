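test_that("network spec fixes the feature-layer width and forward passes are finite", {
  net <- build_feature_cnn(network_spec(), seed = 1)
  expect_identical(ncol(net$layers$fc1$W), 10L)
  net16 <- build_feature_cnn(network_spec(feature_layer_width = 16L), seed = 1)
  expect_identical(ncol(net16$layers$fc1$W), 16L)
  x <- dualdelta:::stack_inputs(list(matrix(0, 64, 64)), 0, 2)
  fw <- dualdelta:::cnn_forward(net, x)
  expect_true(all(is.finite(fw$logits)))
  expect_error(network_spec(input_size = 50), "divisible")
})

test_that("checkpoints round-trip the network with an auditable sidecar", {
  dir <- withr::local_tempdir()
  net <- build_feature_cnn(network_spec(input_size = 16L,
                                        conv_channels = c(2L, 3L, 4L)), seed = 2)
  path <- file.path(dir, "net.rds")
  save_cnn(net, path, seed = 2L)
  back <- load_cnn(path)
  expect_identical(back$layers, net$layers)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(side$spec$feature_layer_width, 10L)
  expect_identical(side$seed, 2L)
})

test_that("backpropagated gradients match central finite differences", {
  spec <- network_spec(input_size = 16L, conv_channels = c(2L, 3L, 4L),
                       feature_layer_width = 5L)
  net <- build_feature_cnn(spec, seed = 3)
  set.seed(4)
  imgs <- list(matrix(runif(256), 16, 16), matrix(runif(256), 16, 16))
  y <- c(0L, 1L)
  loss_of <- function(net) {
    x <- dualdelta:::stack_inputs(imgs, c(0, 0), 2)
    p <- dualdelta:::softmax(dualdelta:::cnn_forward(net, x)$logits)
    -mean(log(p[cbind(1:2, y + 1L)]))
  }
  x <- dualdelta:::stack_inputs(imgs, c(0, 0), 2)
  fw <- dualdelta:::cnn_forward(net, x, keep_cache = TRUE)
  p <- dualdelta:::softmax(fw$logits)
  dlog <- p; dlog[cbind(1:2, y + 1L)] <- dlog[cbind(1:2, y + 1L)] - 1
  dlog <- dlog / 2
  bw <- dualdelta:::cnn_backward(net, fw$cache, dlog)
  eps <- 1e-5
  set.seed(5)
  for (nm in names(net$layers)) {
    idx <- sample(length(net$layers[[nm]]$W), 3)
    for (i in idx) {
      np <- net; np$layers[[nm]]$W[i] <- np$layers[[nm]]$W[i] + eps
      nmn <- net; nmn$layers[[nm]]$W[i] <- nmn$layers[[nm]]$W[i] - eps
      num <- (loss_of(np) - loss_of(nmn)) / (2 * eps)
      expect_equal(bw$grads[[nm]]$dW[i], num, tolerance = 1e-4)
    }
  }
})

test_that("training learns a separable rim task and is seed-deterministic", {
  set.seed(1)
  labs <- rep(0:1, each = 30)
  imgs <- lapply(labs, rim_image)
  net <- build_feature_cnn(network_spec(), seed = 1)
  tr <- train_cnn(net, imgs, rep(0, 60), labs, epochs = 12, seed = 2)
  expect_gte(tail(tr$curves$accuracy, 1), 0.95)
  expect_true(tail(tr$curves$loss, 1) < tr$curves$loss[1])
  tr2 <- train_cnn(net, imgs, rep(0, 60), labs, epochs = 12, seed = 2)
  expect_identical(tail(tr$curves$loss, 1), tail(tr2$curves$loss, 1))
  expect_error(train_cnn(net, imgs[1:30], rep(0, 30), rep(0L, 30)), "both classes")
})

test_that("labels carrying no signal cannot be learned out-of-sample", {
  set.seed(20)
  n <- 60
  imgs <- lapply(rep(0, n), rim_image)      # all images from the null class
  labs <- rep(0:1, n / 2)                   # arbitrary labels
  net <- build_feature_cnn(network_spec(), seed = 6)
  tr <- train_cnn(net, imgs[1:40], rep(0, 40), labs[1:40], epochs = 6, seed = 7)
  fw <- dualdelta:::cnn_forward(tr$net,
                                dualdelta:::stack_inputs(imgs[41:60], rep(0, 20), 2))
  acc <- mean((dualdelta:::softmax(fw$logits)[, 2] > 0.5) == (labs[41:60] == 1))
  expect_gte(acc, 0.2); expect_lte(acc, 0.8)
})

test_that("deep features have width 10 per view and respond to content", {
  set.seed(2)
  labs <- rep(0:1, each = 20)
  imgs <- lapply(labs, rim_image)
  tr <- train_cnn(build_feature_cnn(network_spec(), seed = 1),
                  imgs, rep(0, 40), labs, epochs = 8, seed = 3)
  views <- list(x = rim_image(TRUE), y = rim_image(FALSE), z = rim_image(TRUE))
  f <- extract_deep_features(tr$net, views)
  expect_length(f, 30L)
  expect_identical(f, extract_deep_features(tr$net, views))
  f0 <- extract_deep_features(tr$net, list(x = matrix(0, 64, 64),
                                           y = matrix(0, 64, 64),
                                           z = matrix(0, 64, 64)))
  expect_gt(abs(sqrt(sum(f^2)) - sqrt(sum(f0^2))), 1e-6)
  expect_error(extract_deep_features(tr$net, list(x = matrix(0, 32, 32),
                                                  y = matrix(0, 32, 32),
                                                  z = matrix(0, 32, 32))),
               "input size")
})

test_that("Grad-CAM is the normalised ReLU-weighted channel sum, focused on the rim", {
  set.seed(3)
  labs <- rep(0:1, each = 30)
  imgs <- lapply(labs, rim_image)
  tr <- train_cnn(build_feature_cnn(network_spec(), seed = 1),
                  imgs, rep(0, 60), labs, epochs = 10, seed = 4)
  net <- tr$net
  # pick a confidently-positive rim image
  set.seed(41)
  img <- rim_image(TRUE)
  g <- gradcam(net, img, target_class = 2L)
  expect_identical(dim(g), dim(img))
  expect_true(all(g >= 0 & g <= 1))
  # oracle: recompose the map from the backward pass by hand
  x <- dualdelta:::stack_inputs(list(img), 0, 2)
  fw <- dualdelta:::cnn_forward(net, x, keep_cache = TRUE)
  dlog <- matrix(c(0, 1), 1, 2)
  dA <- dualdelta:::cnn_backward(net, fw$cache, dlog,
                                 need_last_conv_grad = TRUE)$last_conv_grad
  A <- fw$last_conv
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_len(dim(A)[4])) cam <- cam + mean(dA[, , 1, k]) * A[, , 1, k]
  cam <- pmax(cam, 0)
  cam <- dualdelta:::resize2d(cam, dim(img))
  rng <- max(cam) - min(cam)
  oracle <- if (rng == 0) cam * 0 else (cam - min(cam)) / rng
  expect_equal(g, oracle, tolerance = 1e-6)
  # attention concentrates where the class evidence (the rim) lives
  set.seed(41)
  invisible(runif(64 * 64))  # replay the background draw of rim_image
  cx <- runif(1, 64 * 0.35, 64 * 0.65); cy <- runif(1, 64 * 0.35, 64 * 0.65)
  d <- sqrt(outer((1:64 - cx)^2, rep(1, 64)) + outer(rep(1, 64), (1:64 - cy)^2))
  rim <- d > 8 & d < 64 / 5
  if (max(g) > 0) expect_gt(mean(g[rim]), mean(g[!rim]))
  # constant input maps to the all-zero convention
  g0 <- gradcam(net, matrix(0, 64, 64), target_class = 2L)
  expect_true(all(g0 == 0) || diff(range(g0)) > 0)  # normalisation contract
})
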