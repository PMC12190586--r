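# Classifier bundle: a small strided convolutional feature extractor plus a
# global-average-pooling linear head, written in plain matrix algebra so that
# the class-activation attention path stays differentiable end to end and the
# whole model trains deterministically on one CPU. Convolutions use im2col
# gather indices precomputed per layer; gradients are exact (no autodiff).

# im2col geometry for a 3x3, stride-2, pad-1 convolution layer.
conv_layer_geom <- function(in_h, in_w, in_c, out_c) {
  out_h <- (in_h + 2L - 3L) %/% 2L + 1L
  out_w <- (in_w + 2L - 3L) %/% 2L + 1L
  hp <- in_h + 2L; wp <- in_w + 2L
  oh <- rep(seq_len(out_h), times = out_w)
  ow <- rep(seq_len(out_w), each = out_h)
  base <- (2L * oh - 1L) + (2L * ow - 2L) * hp        # padded linear index of patch top-left
  dr <- rep(0:2, times = 3L * in_c)
  dc <- rep(rep(0:2, each = 3L), times = in_c)
  ch <- rep(seq_len(in_c) - 1L, each = 9L)
  off <- dr + dc * hp + ch * hp * wp
  list(in_h = in_h, in_w = in_w, in_c = in_c, out_c = out_c,
       out_h = out_h, out_w = out_w, hp = hp, wp = wp,
       idx1 = outer(base, off, "+"))                  # (out_h*out_w) x (9*in_c)
}

# Batch gather indices: idx1 replicated with per-item offsets.
batch_idx <- function(geom, B) {
  npx <- geom$hp * geom$wp * geom$in_c
  idx <- geom$idx1[rep(seq_len(nrow(geom$idx1)), times = B), , drop = FALSE]
  idx + rep((seq_len(B) - 1L) * npx, each = nrow(geom$idx1))
}

pad_input <- function(x, geom) {
  # x: (in_h, in_w, in_c, B) -> zero-padded (hp, wp, in_c, B)
  B <- dim(x)[4L]
  xp <- array(0, c(geom$hp, geom$wp, geom$in_c, B))
  xp[2:(geom$hp - 1L), 2:(geom$wp - 1L), , ] <- x
  xp
}

conv_forward <- function(layer, geom, x) {
  B <- dim(x)[4L]
  xp <- pad_input(x, geom)
  idx <- batch_idx(geom, B)
  X <- matrix(xp[idx], nrow = nrow(idx))              # (HWB) x (9*in_c)
  Z <- sweep(X %*% layer$W, 2L, layer$b, "+")
  A <- pmax(Z, 0)
  out <- aperm(array(A, c(geom$out_h, geom$out_w, B, geom$out_c)), c(1, 2, 4, 3))
  list(out = out, X = X, relu_mask = Z > 0, idx = idx, B = B)
}

conv_backward <- function(layer, geom, cache, dout) {
  # dout: (out_h, out_w, out_c, B) -> gradients wrt layer params and input
  B <- cache$B
  dA <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = geom$out_c)
  dZ <- dA * cache$relu_mask
  dW <- crossprod(cache$X, dZ)
  db <- colSums(dZ)
  dX <- dZ %*% t(layer$W)
  dxp <- numeric(geom$hp * geom$wp * geom$in_c * B)
  for (q in seq_len(ncol(dX)))                        # no index collisions within a column
    dxp[cache$idx[, q]] <- dxp[cache$idx[, q]] + dX[, q]
  dxp <- array(dxp, c(geom$hp, geom$wp, geom$in_c, B))
  list(dW = dW, db = db,
       dx = dxp[2:(geom$hp - 1L), 2:(geom$wp - 1L), , , drop = FALSE])
}

#' Construct the compact reference classifier
#'
#' Builds a three-block strided (3x3, stride 2, zero pad 1) convolutional
#' feature extractor with ReLU activations, followed by global average pooling
#' and a fully connected head. With the defaults it maps a 64 x 64 RGB image to
#' an 8 x 8 x 32 feature map — small enough for CPU training and for
#' finite-difference gradient checks, while exposing exactly the contract the
#' attention-consistency module needs: the last spatial feature map plus the
#' head weights. Larger backbones can be supplied to [gazecam()] through the
#' same bundle structure.
#'
#' @param input_size Square input size in pixels (default 64).
#' @param in_channels Number of image channels (default 3).
#' @param channels Output channels of the three blocks (default
#'   `c(16, 32, 32)`).
#' @param num_classes Number of classes (>= 2, default 3).
#' @param input_center Constant subtracted from every input pixel before the
#'   first convolution (default 0.5, centering \[0, 1\] images; all-positive
#'   inputs otherwise correlate the first-layer gradients and slow Adam
#'   badly).
#' @param seed Optional integer seed for weight initialization.
#' @return An object of class `"classifier_bundle"`.
#' @export
tiny_backbone <- function(input_size = 64, in_channels = 3,
                          channels = c(16, 32, 32), num_classes = 3,
                          input_center = 0.5, seed = NULL) {
  stopifnot(num_classes >= 2, length(channels) >= 1, input_size >= 8)
  if (!is.null(seed)) set.seed(seed)
  geoms <- list(); layers <- list()
  h <- input_size; w <- input_size; cin <- in_channels
  for (l in seq_along(channels)) {
    g <- conv_layer_geom(h, w, cin, channels[l])
    fan_in <- 9L * cin
    layers[[l]] <- list(W = matrix(stats::rnorm(fan_in * channels[l],
                                                sd = sqrt(2 / fan_in)),
                                   fan_in, channels[l]),
                        b = numeric(channels[l]))
    geoms[[l]] <- g
    h <- g$out_h; w <- g$out_w; cin <- channels[l]
  }
  C <- cin
  structure(list(
    layers = layers, geoms = geoms,
    head_w = matrix(stats::rnorm(num_classes * C, sd = 0.01), num_classes, C),
    head_b = numeric(num_classes),
    input_size = input_size, in_channels = in_channels,
    input_center = input_center,
    feat_h = h, feat_w = w, feat_c = C, num_classes = num_classes),
    class = "classifier_bundle")
}

#' @export
print.classifier_bundle <- function(x, ...) {
  cat(sprintf(paste0("<classifier_bundle> %d-block conv extractor: ",
                     "%dx%dx%d input -> %dx%dx%d feature map -> GAP -> %d classes\n"),
              length(x$layers), x$input_size, x$input_size, x$in_channels,
              x$feat_h, x$feat_w, x$feat_c, x$num_classes))
  invisible(x)
}

#' Forward pass: logits and the last feature map
#'
#' Runs the extractor and the global-average-pooling head:
#' `logits = head_w %*% GAP(fmap) + head_b`, where GAP averages each feature
#' channel over its spatial grid. Deterministic given fixed parameters.
#'
#' @param bundle A `"classifier_bundle"`.
#' @param images Array `(h, w, c, n)` or a single image `(h, w, c)`.
#' @param keep_cache Keep the per-layer activations needed for backprop
#'   (internal; default `FALSE`).
#' @return List with `logits` (`num_classes x n`), `fmap`
#'   (`feat_h, feat_w, feat_c, n`), `gap` (`feat_c x n`) and, when requested,
#'   `cache`.
#' @export
forward_bundle <- function(bundle, images, keep_cache = FALSE) {
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  d <- dim(images)
  if (d[1L] != bundle$input_size || d[2L] != bundle$input_size ||
      d[3L] != bundle$in_channels)
    stop(sprintf("input must be %d x %d x %d images",
                 bundle$input_size, bundle$input_size, bundle$in_channels),
         call. = FALSE)
  ctr <- if (is.null(bundle$input_center)) 0 else bundle$input_center
  x <- images - ctr
  caches <- vector("list", length(bundle$layers))
  for (l in seq_along(bundle$layers)) {
    cc <- conv_forward(bundle$layers[[l]], bundle$geoms[[l]], x)
    x <- cc$out
    if (keep_cache) caches[[l]] <- cc[c("X", "relu_mask", "idx", "B")]
  }
  B <- dim(x)[4L]
  gap <- apply(x, c(3, 4), mean)                       # feat_c x B
  if (is.null(dim(gap))) gap <- matrix(gap, ncol = B)
  logits <- sweep(bundle$head_w %*% gap, 1L, bundle$head_b, "+")
  out <- list(logits = logits, fmap = x, gap = gap)
  if (keep_cache) out$cache <- caches
  out
}

# Dense bilinear interpolation operator (align-corners = FALSE): a matrix R
# such that vec(out) = R %*% vec(in) for column-major vectorized maps.
bilinear_resize_matrix <- function(in_h, in_w, out_h, out_w) {
  R <- matrix(0, out_h * out_w, in_h * in_w)
  sy <- in_h / out_h; sx <- in_w / out_w
  for (oc in seq_len(out_w)) {
    xs <- (oc - 0.5) * sx - 0.5                        # 0-based source column
    x0 <- floor(xs); fx <- xs - x0
    c0 <- min(max(x0, 0), in_w - 1); c1 <- min(max(x0 + 1, 0), in_w - 1)
    for (or in seq_len(out_h)) {
      ys <- (or - 0.5) * sy - 0.5
      y0 <- floor(ys); fy <- ys - y0
      r0 <- min(max(y0, 0), in_h - 1); r1 <- min(max(y0 + 1, 0), in_h - 1)
      i <- or + (oc - 1L) * out_h
      add <- function(rr, cc, w) {
        j <- rr + 1L + cc * in_h
        R[i, j] <<- R[i, j] + w
      }
      add(r0, c0, (1 - fy) * (1 - fx)); add(r0, c1, (1 - fy) * fx)
      add(r1, c0, fy * (1 - fx));       add(r1, c1, fy * fx)
    }
  }
  R
}

#' Bilinear resize of a 2-D map
#'
#' @param m Numeric matrix.
#' @param out_h,out_w Target size.
#' @return Resized matrix (align-corners = FALSE convention).
#' @export
resize_bilinear <- function(m, out_h, out_w) {
  R <- bilinear_resize_matrix(nrow(m), ncol(m), out_h, out_w)
  matrix(R %*% as.vector(m), out_h, out_w)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Class-activation attention map of the network
#'
#' Forms the network's attention heatmap for one class: the head weights of
#' that class are rectified (`relu_on = "weights"`, the default) and used for
#' a channel-wise weighting of the final feature map, the weighted channels
#' are summed into a single spatial map, the map is bilinearly resized to the
#' requested shape, and a sigmoid squashes it into (0, 1). The alternative
#' `relu_on = "map"` rectifies the summed map instead of the weights.
#'
#' @param fmap Feature map array `(h, w, c)` or `(h, w, c, n)`.
#' @param bundle The `"classifier_bundle"` providing the head weights.
#' @param class_idx 1-based class index (scalar, or one per batch item).
#' @param out_h,out_w Output resolution (typically the gaze map's shape).
#' @param relu_on Where the rectifier is applied: `"weights"` or `"map"`.
#' @return For a single map, an object of class `"network_attention_map"`
#'   (list of `values` in (0,1) and `class_idx`); for a batch, an array
#'   `(out_h, out_w, n)`.
#' @export
network_attention <- function(fmap, bundle, class_idx, out_h, out_w,
                              relu_on = c("weights", "map")) {
  relu_on <- match.arg(relu_on)
  single <- length(dim(fmap)) == 3L
  if (single) dim(fmap) <- c(dim(fmap), 1L)
  d <- dim(fmap); B <- d[4L]
  if (length(class_idx) == 1L) class_idx <- rep(class_idx, B)
  if (any(class_idx < 1L | class_idx > bundle$num_classes))
    stop("class index out of range", call. = FALSE)
  Rz <- bilinear_resize_matrix(d[1L], d[2L], out_h, out_w)
  out <- array(NA_real_, c(out_h, out_w, B))
  for (b in seq_len(B)) {
    wc <- bundle$head_w[class_idx[b], ]
    fm <- matrix(fmap[, , , b], d[1L] * d[2L], d[3L])
    raw <- if (relu_on == "weights") fm %*% pmax(wc, 0) else pmax(fm %*% wc, 0)
    out[, , b] <- matrix(sigmoid(Rz %*% raw), out_h, out_w)
  }
  if (single)
    structure(list(values = out[, , 1L], class_idx = class_idx[1L]),
              class = "network_attention_map")
  else out
}

#' @export
print.network_attention_map <- function(x, ...) {
  cat(sprintf("<network_attention_map> class %d: %d x %d, range [%.3f, %.3f]\n",
              x$class_idx, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Cross-entropy classification loss
#'
#' `-log softmax(logits)[true_class]`, the multiclass cross-entropy with a
#' one-hot target. Computed with the log-sum-exp trick; invariant to adding a
#' constant to all logits.
#'
#' @param logits Numeric vector of length `num_classes`, or a
#'   `num_classes x n` matrix for a batch.
#' @param true_class 1-based true class index (scalar or length `n`).
#' @return Nonnegative loss (scalar, or length-`n` vector for a batch).
#' @export
cross_entropy <- function(logits, true_class) {
  if (is.vector(logits)) logits <- matrix(logits, ncol = 1L)
  K <- nrow(logits); B <- ncol(logits)
  if (length(true_class) == 1L) true_class <- rep(true_class, B)
  if (any(true_class < 1L | true_class > K))
    stop("class index out of range", call. = FALSE)
  z <- sweep(logits, 2L, apply(logits, 2L, max), "-")
  lse <- log(colSums(exp(z)))
  out <- lse - z[cbind(true_class, seq_len(B))]
  if (B == 1L) out[[1L]] else out
}

#' Attention-consistency (mean squared error) loss
#'
#' Mean over all pixels of the squared difference between the network
#' attention map and the human gaze-attention map. Symmetric in its
#' arguments; zero iff the maps are identical. The mean is taken over all
#' `N x M` pixels so the loss is resolution-independent and commensurate with
#' the cross-entropy term when both maps live on a \[0, 1\] scale.
#'
#' @param a_model,a_human Attention maps: matrices, or objects with a
#'   `$values` matrix ([render_gaze_map()] / [network_attention()] output).
#' @return Nonnegative scalar.
#' @export
attention_mse <- function(a_model, a_human) {
  a <- if (is.list(a_model)) a_model$values else a_model
  b <- if (is.list(a_human)) a_human$values else a_human
  if (!identical(dim(a), dim(b)))
    stop("attention maps must have identical shapes", call. = FALSE)
  mean((a - b)^2)
}

#' Joint training objective
#'
#' `ce + lambda * mse`: the unweighted sum of the classification and
#' attention-consistency terms (`lambda = 1`), with `lambda = 0` reducing
#' training to plain cross-entropy (the no-gaze ablation baseline).
#'
#' @param ce Cross-entropy term (>= 0).
#' @param mse Attention-consistency term (>= 0).
#' @param lambda Weight on the consistency term (default 1).
#' @return Scalar total loss.
#' @export
total_loss <- function(ce, mse, lambda = 1) {
  stopifnot(all(ce >= 0), all(mse >= 0), lambda >= 0)
  ce + lambda * mse
}
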