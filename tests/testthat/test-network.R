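# Classifier bundle forward pass, class-activation attention, and the joint
# loss components.

test_that("im2col convolution matches a nested-loop oracle", {
  set.seed(1)
  g <- gazecam:::conv_layer_geom(8, 8, 2, 3)
  layer <- list(W = matrix(rnorm(18 * 3), 18, 3), b = rnorm(3))
  x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  out <- gazecam:::conv_forward(layer, g, x)$out
  xp <- array(0, c(10, 10, 2, 2)); xp[2:9, 2:9, , ] <- x
  orc <- array(0, dim(out))
  for (bt in 1:2) for (oc in 1:3) for (oh in 1:4) for (ow in 1:4) {
    acc <- layer$b[oc]
    for (ch in 1:2) for (dc in 0:2) for (dr in 0:2)
      acc <- acc + xp[2 * oh - 1 + dr, 2 * ow - 1 + dc, ch, bt] *
        layer$W[dr + 1 + dc * 3 + (ch - 1) * 9, oc]
    orc[oh, ow, oc, bt] <- max(acc, 0)
  }
  expect_equal(out, orc, tolerance = 1e-12)
})

test_that("forward pass implements GAP plus affine head exactly", {
  b <- tiny_backbone(input_size = 32, channels = c(4, 8), num_classes = 3,
                     seed = 2)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  fw <- forward_bundle(b, img)
  gap_oracle <- apply(fw$fmap[, , , 1], 3, mean)
  expect_equal(as.vector(fw$gap), gap_oracle, tolerance = 1e-12)
  expect_equal(as.vector(fw$logits),
               as.vector(b$head_w %*% gap_oracle + b$head_b),
               tolerance = 1e-12)
  # zero image through a zero-initialized head: logits equal the bias
  b0 <- b; b0$head_w[] <- 0; b0$head_b <- c(0.3, -0.1, 2)
  fw0 <- forward_bundle(b0, img)
  expect_equal(as.vector(fw0$logits), c(0.3, -0.1, 2), tolerance = 1e-12)
  expect_error(forward_bundle(b, array(0, c(16, 16, 3))), "32 x 32")
  # deterministic in eval: two passes identical
  expect_identical(fw$logits, forward_bundle(b, img)$logits)
})

test_that("network attention matches the triple-loop CAM oracle", {
  set.seed(3)
  b <- tiny_backbone(num_classes = 3, seed = 3)
  b$head_w <- matrix(rnorm(3 * 8), 3, 8)
  for (rep in 1:5) {
    fm <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
    k <- sample(1:3, 1)
    att <- network_attention(fm, b, k, 4, 4)   # same-size resize is identity
    raw <- oracle_cam_raw(fm, b$head_w[k, ])
    expect_lt(max(abs(att$values - 1 / (1 + exp(-raw))) /
                    pmax(abs(1 / (1 + exp(-raw))), 1e-12)), 1e-6)
  }
  expect_error(network_attention(array(0, c(4, 4, 8)), b, 7, 4, 4), "range")
})

test_that("degenerate CAM cases follow the sigmoid", {
  b <- tiny_backbone(num_classes = 2, seed = 4)
  b$head_w <- matrix(-abs(rnorm(2 * 8)), 2, 8)   # all weights non-positive
  fm <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  att <- network_attention(fm, b, 1, 8, 8)
  expect_equal(att$values, matrix(0.5, 8, 8))
  # one positive unit weight on a constant-1 channel: sigmoid(1) everywhere
  b$head_w[2, ] <- c(1, rep(-1, 7))
  fm1 <- array(0, c(4, 4, 8)); fm1[, , 1] <- 1
  att1 <- network_attention(fm1, b, 2, 4, 4)
  expect_equal(att1$values, matrix(1 / (1 + exp(-1)), 4, 4), tolerance = 1e-12)
})

test_that("pre-sigmoid attention is linear in the feature map", {
  set.seed(8)
  b <- tiny_backbone(num_classes = 3, seed = 8)
  b$head_w <- matrix(rnorm(3 * 8), 3, 8)
  logit <- function(p) log(p / (1 - p))
  for (rep in 1:5) {
    f1 <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
    f2 <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
    r1 <- logit(network_attention(f1, b, 2, 4, 4)$values)
    r2 <- logit(network_attention(f2, b, 2, 4, 4)$values)
    r12 <- logit(network_attention(f1 + f2, b, 2, 4, 4)$values)
    expect_equal(r12, r1 + r2, tolerance = 1e-6)
  }
})

test_that("relu placement option changes only the rectification point", {
  set.seed(9)
  b <- tiny_backbone(num_classes = 3, seed = 9)
  b$head_w <- matrix(rnorm(3 * 8), 3, 8)
  fm <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  aw <- network_attention(fm, b, 1, 4, 4, relu_on = "weights")$values
  am <- network_attention(fm, b, 1, 4, 4, relu_on = "map")$values
  raw_m <- pmax(matrix(fm, 16, 8) %*% b$head_w[1, ], 0)
  expect_equal(as.vector(am), as.vector(1 / (1 + exp(-raw_m))),
               tolerance = 1e-12)
  # rectifying the map guarantees attention >= 0.5; rectified weights do so
  # only for nonnegative feature maps (the post-ReLU case in the model)
  expect_true(all(am >= 0.5))
  expect_false(identical(am, aw))
})

test_that("bilinear resize operator is a partition of unity", {
  R <- gazecam:::bilinear_resize_matrix(8, 8, 64, 64)
  expect_equal(rowSums(R), rep(1, 64 * 64), tolerance = 1e-12)
  expect_equal(resize_bilinear(matrix(3.7, 8, 8), 32, 32),
               matrix(3.7, 32, 32), tolerance = 1e-12)
  # same-size resize is the identity
  m <- matrix(rnorm(36), 6, 6)
  expect_equal(resize_bilinear(m, 6, 6), m, tolerance = 1e-12)
})

test_that("cross entropy matches the softmax log-loss", {
  expect_equal(cross_entropy(c(0, 0, 0), 2), log(3), tolerance = 1e-12)
  expect_lt(cross_entropy(c(50, 0, 0), 1), 1e-12)
  set.seed(10)
  for (rep in 1:20) {
    z <- rnorm(3, sd = 3); k <- sample(1:3, 1)
    p <- exp(z) / sum(exp(z))
    expect_equal(cross_entropy(z, k), -log(p[k]), tolerance = 1e-8)
    # invariance to adding a constant to all logits
    expect_equal(cross_entropy(z + 17.3, k), cross_entropy(z, k),
                 tolerance = 1e-8)
  }
  expect_error(cross_entropy(c(0, 0), 5), "range")
  # batch form
  L <- matrix(c(0, 0, 0, 10, 0, 0), 3, 2)
  expect_equal(cross_entropy(L, c(1, 1)), c(log(3), cross_entropy(c(10, 0, 0), 1)))
})

test_that("attention MSE is the pixel mean of squared differences", {
  a <- matrix(runif(64), 8, 8)
  expect_equal(attention_mse(a, a), 0)
  expect_equal(attention_mse(a, a + 0.5), 0.25, tolerance = 1e-12)
  set.seed(11)
  b <- matrix(runif(64), 8, 8)
  orc <- 0
  for (i in 1:8) for (j in 1:8) orc <- orc + (a[i, j] - b[i, j])^2
  expect_equal(attention_mse(a, b), orc / 64, tolerance = 1e-10)
  expect_identical(attention_mse(a, b), attention_mse(b, a))
  expect_error(attention_mse(a, matrix(0, 4, 4)), "shape")
})

test_that("total loss is the unweighted sum with optional lambda", {
  expect_equal(total_loss(0, 0), 0)
  expect_equal(total_loss(1.0986, 0.25), 1.3486)
  expect_equal(total_loss(0.7, 0.2, lambda = 0), 0.7)
  expect_equal(total_loss(0.7, 0.2, lambda = 3), 1.3)
  expect_error(total_loss(-1, 0), "ce")
})

test_that("training gradients agree with finite differences", {
  d <- small_dataset()
  bd <- tiny_backbone(num_classes = 3, seed = 13)
  Rz <- gazecam:::bilinear_resize_matrix(8, 8, 64, 64)
  xb <- d$images[, , , 1:2, drop = FALSE]
  gb <- d$gaze_maps[, , 1:2]
  lb <- d$labels[1:2] + 1L
  res <- gazecam:::gazecam_batch_grads(bd, xb, lb, gb, 1, "predicted",
                                       "weights", Rz, t(Rz))
  lossfun <- function(bun) {
    fw <- forward_bundle(bun, xb)
    ce <- mean(cross_entropy(fw$logits, lb))
    cls <- max.col(t(fw$logits), ties.method = "first")
    att <- network_attention(fw$fmap, bun, cls, 64, 64)
    mse <- mean(vapply(1:2, function(k)
      mean((att[, , k] - (1 + gb[, , k]) / 2)^2), numeric(1)))
    ce + mse
  }
  eps <- 1e-5
  nonzero <- 0
  for (nm in c("W1", "W2", "W3", "head_w")) {
    g <- res$grads[[nm]]
    i <- which.max(abs(g))
    p <- gazecam:::bundle_params(bd)
    p[[nm]][i] <- p[[nm]][i] + eps
    up <- lossfun(gazecam:::set_bundle_params(bd, p))
    p[[nm]][i] <- p[[nm]][i] - 2 * eps
    dn <- lossfun(gazecam:::set_bundle_params(bd, p))
    fd <- (up - dn) / (2 * eps)
    expect_equal(g[i], fd, tolerance = 1e-4)
    if (abs(g[i]) > 1e-10) nonzero <- nonzero + 1
  }
  # gradient flows into the feature extractor when lambda > 0
  expect_gte(nonzero, 3)
})
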