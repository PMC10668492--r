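# A compact AlexNet-inspired CNN (3 conv blocks + a narrow fully-connected
# feature layer + a 2-way head), implemented directly on BLAS matrix
# operations (im2col convolution). Activations are stored as 4-D arrays
# (H, W, N, C) so that im2col gathers flatten to (H*W*N) x (k*k*C) matrices.
# All randomness is seeded; training and inference are deterministic.

#' Specification of the delta-image feature network
#'
#' @param input_size square input side in pixels (default 64; 227 mirrors the
#'   classic AlexNet input profile).
#' @param in_channels input channels; the default 2 is the delta image plus a
#'   constant view-tag channel, letting one shared network serve the three
#'   orthogonal views.
#' @param conv_channels output channels of the three conv blocks
#'   (3 x 3 kernels, stride 1, each followed by ReLU and 2 x 2 max-pooling).
#' @param feature_layer_width neurons of the fully-connected feature layer —
#'   the per-view deep-feature dimension (default 10).
#' @param n_classes classifier head width (binary by default).
#' @return list of class `network_spec`.
#' @export
network_spec <- function(input_size = 64L, in_channels = 2L,
                         conv_channels = c(8L, 16L, 32L),
                         feature_layer_width = 10L, n_classes = 2L) {
  if (input_size %% 8 != 0) stop("input_size must be divisible by 8 (three 2x2 pools)")
  structure(list(input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 conv_channels = as.integer(conv_channels),
                 feature_layer_width = as.integer(feature_layer_width),
                 n_classes = as.integer(n_classes)),
            class = "network_spec")
}

#' Build (initialise) the feature CNN
#'
#' @param spec a [network_spec()].
#' @param seed initialisation seed.
#' @return list of class `feature_cnn` holding the weight tensors; the
#'   penultimate (feature) layer has exactly `spec$feature_layer_width` units.
#' @export
build_feature_cnn <- function(spec = network_spec(), seed = 1L) {
  set.seed(seed)
  he <- function(fan_in, n) matrix(rnorm(fan_in * n, 0, sqrt(2 / fan_in)), fan_in, n)
  cc <- c(spec$in_channels, spec$conv_channels)
  layers <- list()
  for (i in 1:3) {
    k <- 9L * cc[i]
    layers[[paste0("conv", i)]] <- list(W = he(k, cc[i + 1]), b = numeric(cc[i + 1]))
  }
  side <- spec$input_size / 8L
  flat <- side * side * spec$conv_channels[3]
  layers$fc1 <- list(W = he(flat, spec$feature_layer_width),
                     b = numeric(spec$feature_layer_width))
  layers$fc2 <- list(W = he(spec$feature_layer_width, spec$n_classes),
                     b = numeric(spec$n_classes))
  structure(list(spec = spec, layers = layers), class = "feature_cnn")
}

#' @export
print.feature_cnn <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b), numeric(1)))
  cat("feature_cnn:", x$spec$input_size, "x", x$spec$input_size, "input,",
      paste(x$spec$conv_channels, collapse = "-"), "conv channels,",
      x$spec$feature_layer_width, "feature units,", np, "parameters\n")
  invisible(x)
}

# ---- layer primitives on (H, W, N, C) arrays ----

im2col <- function(x) {
  d <- dim(x)  # H W N C
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  pad <- array(0, c(H + 2L, W + 2L, N, C))
  pad[2:(H + 1), 2:(W + 1), , ] <- x
  cols <- matrix(0, H * W * N, 9L * C)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    sl <- pad[(1L + di):(H + di), (1L + dj):(W + dj), , , drop = FALSE]
    cols[, (k * C + 1L):((k + 1L) * C)] <- matrix(sl, H * W * N, C)
    k <- k + 1L
  }
  cols
}

col2im_grad <- function(dcols, H, W, N, C) {
  dpad <- array(0, c(H + 2L, W + 2L, N, C))
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    blk <- array(dcols[, (k * C + 1L):((k + 1L) * C)], c(H, W, N, C))
    dpad[(1L + di):(H + di), (1L + dj):(W + dj), , ] <-
      dpad[(1L + di):(H + di), (1L + dj):(W + dj), , ] + blk
    k <- k + 1L
  }
  dpad[2:(H + 1), 2:(W + 1), , , drop = FALSE]
}

conv_forward <- function(x, layer) {
  d <- dim(x)
  cols <- im2col(x)
  out_mat <- sweep(cols %*% layer$W, 2, layer$b, `+`)
  out <- array(out_mat, c(d[1], d[2], d[3], ncol(layer$W)))
  list(out = out, cols = cols, in_dim = d)
}

conv_backward <- function(dout, cache, layer) {
  d <- cache$in_dim
  dmat <- matrix(dout, d[1] * d[2] * d[3], ncol(layer$W))
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- tcrossprod(dmat, layer$W)
  dx <- col2im_grad(dcols, d[1], d[2], d[3], d[4])
  list(dx = dx, dW = dW, db = db)
}

relu_forward <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_backward <- function(dout, cache) dout * cache$mask

pool_forward <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  s <- list(x[i1, j1, , , drop = FALSE], x[i2, j1, , , drop = FALSE],
            x[i1, j2, , , drop = FALSE], x[i2, j2, , , drop = FALSE])
  out <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  # route gradient to the first slot attaining the max
  m1 <- s[[1]] == out
  m2 <- s[[2]] == out & !m1
  m3 <- s[[3]] == out & !m1 & !m2
  m4 <- !(m1 | m2 | m3)
  list(out = out, masks = list(m1, m2, m3, m4), in_dim = d)
}

pool_backward <- function(dout, cache) {
  d <- cache$in_dim
  dx <- array(0, d)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  dx[i1, j1, , ] <- dout * cache$masks[[1]]
  dx[i2, j1, , ] <- dx[i2, j1, , , drop = FALSE] + dout * cache$masks[[2]]
  dx[i1, j2, , ] <- dx[i1, j2, , , drop = FALSE] + dout * cache$masks[[3]]
  dx[i2, j2, , ] <- dx[i2, j2, , , drop = FALSE] + dout * cache$masks[[4]]
  dx
}

flatten_forward <- function(x) {
  d <- dim(x)
  xp <- aperm(x, c(1, 2, 4, 3))       # H W C N
  list(out = t(matrix(xp, d[1] * d[2] * d[4], d[3])), in_dim = d)  # N x D
}

flatten_backward <- function(dout, cache) {
  d <- cache$in_dim
  xp <- array(t(dout), c(d[1], d[2], d[4], d[3]))
  aperm(xp, c(1, 2, 4, 3))
}

fc_forward <- function(x, layer) list(out = sweep(x %*% layer$W, 2, layer$b, `+`), x = x)
fc_backward <- function(dout, cache, layer) {
  list(dx = tcrossprod(dout, layer$W), dW = crossprod(cache$x, dout), db = colSums(dout))
}

# full forward pass; x is (H, W, N, C)
cnn_forward <- function(net, x, keep_cache = FALSE) {
  L <- net$layers
  c1 <- conv_forward(x, L$conv1); r1 <- relu_forward(c1$out); p1 <- pool_forward(r1$out)
  c2 <- conv_forward(p1$out, L$conv2); r2 <- relu_forward(c2$out); p2 <- pool_forward(r2$out)
  c3 <- conv_forward(p2$out, L$conv3); r3 <- relu_forward(c3$out); p3 <- pool_forward(r3$out)
  fl <- flatten_forward(p3$out)
  f1 <- fc_forward(fl$out, L$fc1); rf <- relu_forward(f1$out)
  f2 <- fc_forward(rf$out, L$fc2)
  out <- list(logits = f2$out, features = rf$out, last_conv = r3$out)
  if (keep_cache)
    out$cache <- list(c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2,
                      c3 = c3, r3 = r3, p3 = p3, fl = fl, f1 = f1, rf = rf, f2 = f2)
  out
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# backward from softmax cross-entropy; returns weight grads and optionally
# the gradient at the last conv activation (for Grad-CAM)
cnn_backward <- function(net, cache, dlogits, need_last_conv_grad = FALSE) {
  L <- net$layers
  g2 <- fc_backward(dlogits, cache$f2, L$fc2)
  drf <- relu_backward(g2$dx, cache$rf)
  g1 <- fc_backward(drf, cache$f1, L$fc1)
  dfl <- flatten_backward(g1$dx, cache$fl)
  dp3 <- pool_backward(dfl, cache$p3)
  if (need_last_conv_grad) {
    return(list(last_conv_grad = dp3))
  }
  dr3 <- relu_backward(dp3, cache$r3)
  g3 <- conv_backward(dr3, cache$c3, L$conv3)
  dp2 <- pool_backward(g3$dx, cache$p2)
  dr2 <- relu_backward(dp2, cache$r2)
  gc2 <- conv_backward(dr2, cache$c2, L$conv2)
  dp1 <- pool_backward(gc2$dx, cache$p1)
  dr1 <- relu_backward(dp1, cache$r1)
  gc1 <- conv_backward(dr1, cache$c1, L$conv1)
  list(grads = list(conv1 = gc1[c("dW", "db")], conv2 = gc2[c("dW", "db")],
                    conv3 = g3[c("dW", "db")], fc1 = g1[c("dW", "db")],
                    fc2 = g2[c("dW", "db")]))
}

# stack a list of matrices (+ per-image constant tag channel) into (H,W,N,C)
stack_inputs <- function(images, view_tags, in_channels) {
  H <- nrow(images[[1]]); W <- ncol(images[[1]]); N <- length(images)
  x <- array(0, c(H, W, N, in_channels))
  for (i in seq_len(N)) {
    x[, , i, 1] <- images[[i]]
    if (in_channels >= 2) x[, , i, 2] <- view_tags[i]
  }
  x
}

view_tag_value <- function(axis) c(x = 0, y = 0.5, z = 1)[[axis]]

#' Train the feature CNN on delta images
#'
#' Mini-batch SGD with momentum on a softmax cross-entropy loss with
#' inverse-frequency class weights. Runs are deterministic for a fixed seed.
#'
#' @param net a `feature_cnn` from [build_feature_cnn()].
#' @param images list of input matrices (values in [0, 1], side
#'   `spec$input_size`).
#' @param view_tags numeric vector, the constant second-channel tag of each
#'   image (see [view_tag_value()]); ignored for single-channel specs.
#' @param labels integer 0/1 vector, one per image; both classes must occur.
#' @param epochs,lr,momentum,batch_size optimiser settings (defaults 20 /
#'   0.01 / 0.9 / 32).
#' @param seed shuffling seed.
#' @param verbose print per-epoch loss/accuracy.
#' @return list: `net` (trained), `curves` (data frame epoch, loss, accuracy).
#' @export
train_cnn <- function(net, images, view_tags = NULL, labels, epochs = 20,
                      lr = 0.01, momentum = 0.9, batch_size = 32L, seed = 1L,
                      verbose = FALSE) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("train_cnn: need both classes present")
  n <- length(images)
  if (is.null(view_tags)) view_tags <- rep(0, n)
  cw <- n / (2 * pmax(table(factor(labels, levels = 0:1)), 1))
  wts <- as.numeric(cw[as.character(labels)])
  vel <- lapply(net$layers, function(l) list(W = l$W * 0, b = l$b * 0))
  set.seed(seed)
  curves <- data.frame(epoch = integer(0), loss = numeric(0), accuracy = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    tot_loss <- 0; tot_correct <- 0; tot_w <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      x <- stack_inputs(images[idx], view_tags[idx], net$spec$in_channels)
      fw <- cnn_forward(net, x, keep_cache = TRUE)
      p <- softmax(fw$logits)
      y <- labels[idx]
      w <- wts[idx]
      bl <- -sum(w * log(p[cbind(seq_along(y), y + 1L)] + 1e-12)) / sum(w)
      tot_loss <- tot_loss + bl * sum(w); tot_w <- tot_w + sum(w)
      tot_correct <- tot_correct + sum((p[, 2] > 0.5) == (y == 1))
      dlog <- p
      dlog[cbind(seq_along(y), y + 1L)] <- dlog[cbind(seq_along(y), y + 1L)] - 1
      dlog <- dlog * w / sum(w)
      bw <- cnn_backward(net, fw$cache, dlog)
      for (nm in names(net$layers)) {
        vel[[nm]]$W <- momentum * vel[[nm]]$W - lr * bw$grads[[nm]]$dW
        vel[[nm]]$b <- momentum * vel[[nm]]$b - lr * bw$grads[[nm]]$db
        net$layers[[nm]]$W <- net$layers[[nm]]$W + vel[[nm]]$W
        net$layers[[nm]]$b <- net$layers[[nm]]$b + vel[[nm]]$b
      }
    }
    curves <- rbind(curves, data.frame(epoch = ep, loss = tot_loss / tot_w,
                                       accuracy = tot_correct / n))
    if (verbose)
      message(sprintf("epoch %2d  loss %.4f  acc %.3f", ep,
                      tot_loss / tot_w, tot_correct / n))
  }
  list(net = net, curves = curves)
}

#' Extract the per-view deep-feature vector of a delta-image set
#'
#' Forward-passes each of the three per-axis delta images through the trained
#' network and concatenates the activations of the feature layer: 10 values
#' per view, 30 per subject at defaults. Deterministic at inference.
#'
#' @param net trained `feature_cnn`.
#' @param dset a `delta_image_set` (or a named list of x/y/z matrices).
#' @return named numeric vector of length `3 * feature_layer_width`
#'   (`dl.x.f01`, ...).
#' @export
extract_deep_features <- function(net, dset) {
  imgs <- if (inherits(dset, "delta_image_set")) dset$images else dset
  axes <- c("x", "y", "z")
  stopifnot(all(axes %in% names(imgs)))
  sz <- net$spec$input_size
  out <- unlist(lapply(axes, function(a) {
    img <- imgs[[a]]
    if (!all(dim(img) == c(sz, sz)))
      stop("extract_deep_features: image size differs from the network input size")
    x <- stack_inputs(list(img), view_tag_value(a), net$spec$in_channels)
    as.numeric(cnn_forward(net, x)$features)
  }))
  names(out) <- as.vector(t(outer(axes, seq_len(net$spec$feature_layer_width),
                                  function(a, i) sprintf("dl.%s.f%02d", a, i))))
  out
}

#' Save / load a network checkpoint
#'
#' Weights go to an RDS checkpoint; a human-readable JSON sidecar
#' (`<path>.json`) records the architecture spec, a hash of the weights and
#' an optional training seed, so checkpoints are auditable without loading
#' them.
#'
#' @param net a `feature_cnn`.
#' @param path checkpoint path (`.rds`).
#' @param seed optional training seed recorded in the sidecar.
#' @return `save_cnn` returns the path invisibly; `load_cnn` the network.
#' @export
save_cnn <- function(net, path, seed = NULL) {
  stopifnot(inherits(net, "feature_cnn"))
  saveRDS(net, path, version = 2)
  jsonlite::write_json(
    list(spec = unclass(net$spec), weight_hash = object_hash(net$layers),
         seed = seed,
         package_version = as.character(utils::packageVersion("dualdelta"))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "feature_cnn"))
  net
}

#' Grad-CAM attention map for one input image
#'
#' Gradient-weighted class-activation mapping on the final conv layer:
#' channel weights are the spatial means of the class-score gradient, the map
#' is the ReLU of the weighted channel sum, bilinearly upsampled to the input
#' size and min-max normalised to [0, 1]. A constant map normalises to all
#' zeros (convention).
#'
#' @param net trained `feature_cnn`.
#' @param image input matrix (side `input_size`, values in [0, 1]).
#' @param target_class class index (1 or 2) whose score is explained.
#' @param view_tag constant tag channel value.
#' @return matrix of the input spatial size with values in [0, 1].
#' @export
gradcam <- function(net, image, target_class = 2L, view_tag = 0) {
  x <- stack_inputs(list(image), view_tag, net$spec$in_channels)
  fw <- cnn_forward(net, x, keep_cache = TRUE)
  dlog <- matrix(0, 1, net$spec$n_classes)
  dlog[1, target_class] <- 1
  bg <- cnn_backward(net, fw$cache, dlog, need_last_conv_grad = TRUE)
  dA <- bg$last_conv_grad  # gradient w.r.t. the post-ReLU last conv activations
  A <- fw$last_conv
  nk <- dim(A)[4]
  alpha <- vapply(seq_len(nk), function(k) mean(dA[, , 1, k]), numeric(1))
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_len(nk)) cam <- cam + alpha[k] * A[, , 1, k]
  cam <- pmax(cam, 0)
  cam <- resize2d(cam, dim(image))
  rng <- max(cam) - min(cam)
  if (rng == 0) return(cam * 0)
  (cam - min(cam)) / rng
}
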