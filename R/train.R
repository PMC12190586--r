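#' Training control parameters
#'
#' Collects the optimization protocol: Adam with initial learning rate 0.001,
#' cosine-annealing warm restarts (first cycle 10 epochs, cycle length
#' doubling thereafter), training/validation batch sizes 8/16, and up to 150
#' epochs with best-validation-accuracy checkpointing. These defaults are the
#' package's reference protocol; shrink `max_epochs` for quick experiments.
#'
#' @param lr Initial (maximum) learning rate.
#' @param lr_min Learning rate floor of each cosine cycle (default 0).
#' @param t0 Length of the first annealing cycle in epochs.
#' @param t_mult Multiplicative cycle-length growth factor (>= 1).
#' @param batch_train,batch_val Mini-batch sizes for training and validation.
#' @param max_epochs Maximum number of epochs (no early stopping; the best
#'   validation checkpoint is returned).
#' @param augment Named logical flags `flip_lr`, `flip_ud`, `rotate` enabling
#'   the geometric augmentations (right-angle rotations).
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @param class_weights Optional per-class cross-entropy weights (default
#'   unweighted).
#' @param cam_class Which class's head weights drive the attention map during
#'   training: the `"predicted"` class (argmax of the logits; default) or the
#'   `"true"` label.
#' @param relu_on Rectifier placement in the attention module (see
#'   [network_attention()]).
#' @param verbose Print one line per epoch.
#' @return A list of class `"gazecam_control"`.
#' @export
gazecam_control <- function(lr = 0.001, lr_min = 0, t0 = 10, t_mult = 2,
                            batch_train = 8, batch_val = 16, max_epochs = 150,
                            augment = c(flip_lr = TRUE, flip_ud = TRUE,
                                        rotate = TRUE),
                            beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                            class_weights = NULL,
                            cam_class = c("predicted", "true"),
                            relu_on = c("weights", "map"),
                            verbose = FALSE) {
  stopifnot(lr > 0, t0 >= 1, t_mult >= 1, batch_train >= 1, batch_val >= 1,
            max_epochs >= 1, lr_min >= 0, lr_min <= lr)
  structure(list(lr = lr, lr_min = lr_min, t0 = t0, t_mult = t_mult,
                 batch_train = batch_train, batch_val = batch_val,
                 max_epochs = max_epochs, augment = augment,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 class_weights = class_weights,
                 cam_class = match.arg(cam_class),
                 relu_on = match.arg(relu_on),
                 verbose = isTRUE(verbose)),
            class = "gazecam_control")
}

#' Cosine-annealing warm-restart learning rate
#'
#' Within a cycle of length `T_i` the learning rate follows
#' `lr_min + (lr - lr_min) * (1 + cos(pi * t / T_i)) / 2`, starting at `lr`
#' (cos 0 = 1) and annealing to `lr_min` (cos pi = -1); cycles restart with
#' length multiplied by `t_mult`. With the defaults (`t0 = 10`,
#' `t_mult = 2`) restarts occur at epochs 10, 30, 70, ... The scheduler is
#' stepped once per epoch; fractional `epoch_progress` gives the within-epoch
#' position if finer stepping is wanted.
#'
#' @param epoch_progress Nonnegative position in epochs (0 = start of
#'   training).
#' @param control A [gazecam_control()] object.
#' @return Learning rate at that position.
#' @export
scheduler_lr <- function(epoch_progress, control) {
  stopifnot(epoch_progress >= 0)
  t <- epoch_progress; Ti <- control$t0
  while (t >= Ti) {
    t <- t - Ti
    Ti <- Ti * control$t_mult
  }
  control$lr_min + (control$lr - control$lr_min) * (1 + cos(pi * t / Ti)) / 2
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

apply_geom <- function(x, flip_lr, flip_ud, rot_k) {
  # x: matrix or (h, w, c) array; rot_k quarter-turns clockwise
  f <- function(m) {
    if (flip_lr) m <- m[, ncol(m):1, drop = FALSE]
    if (flip_ud) m <- m[nrow(m):1, , drop = FALSE]
    if (rot_k > 0) for (i in seq_len(rot_k)) m <- rot90cw(m)
    m
  }
  if (is.matrix(x)) return(f(x))
  out <- x
  for (ch in seq_len(dim(x)[3L])) out[, , ch] <- f(x[, , ch])
  out
}

#' Jointly augment an image and its gaze map
#'
#' Samples one geometric transform — horizontal flip with probability 0.5,
#' vertical flip with probability 0.5, and a rotation drawn uniformly from
#' {0, 90, 180, 270} degrees — and applies the same transform to both the
#' image and its gaze-attention map, keeping them spatially registered.
#' Right-angle rotations are used so the gaze map needs no interpolation.
#'
#' @param image Array `(h, w, c)`.
#' @param gaze_map Matrix `(h, w)` or an object with `$values` (may be `NULL`
#'   when training without gaze).
#' @param augment Logical flags as in [gazecam_control()].
#' @param draw Optional explicit draw `list(flip_lr=, flip_ud=, rot_k=)` for
#'   reproducing a specific transform; by default drawn from the current RNG.
#' @return List with the transformed `image`, `gaze_map`, and the `draw` used.
#' @export
augment_pair <- function(image, gaze_map = NULL,
                         augment = c(flip_lr = TRUE, flip_ud = TRUE,
                                     rotate = TRUE),
                         draw = NULL) {
  gm <- if (is.list(gaze_map)) gaze_map$values else gaze_map
  if (!is.null(gm) && !identical(dim(image)[1:2], dim(gm)))
    stop("image and gaze map shapes do not match", call. = FALSE)
  if (is.null(draw)) {
    draw <- list(
      flip_lr = isTRUE(augment[["flip_lr"]]) && stats::runif(1) < 0.5,
      flip_ud = isTRUE(augment[["flip_ud"]]) && stats::runif(1) < 0.5,
      rot_k = if (isTRUE(augment[["rotate"]])) sample.int(4L, 1L) - 1L else 0L)
  }
  if (draw$rot_k %% 2L == 1L && dim(image)[1L] != dim(image)[2L])
    stop("90/270-degree rotation requires square images", call. = FALSE)
  list(image = apply_geom(image, draw$flip_lr, draw$flip_ud, draw$rot_k),
       gaze_map = if (is.null(gm)) NULL else
         apply_geom(gm, draw$flip_lr, draw$flip_ud, draw$rot_k),
       draw = draw)
}

bundle_params <- function(bundle) {
  p <- list()
  for (l in seq_along(bundle$layers)) {
    p[[paste0("W", l)]] <- bundle$layers[[l]]$W
    p[[paste0("b", l)]] <- bundle$layers[[l]]$b
  }
  p$head_w <- bundle$head_w; p$head_b <- bundle$head_b
  p
}

set_bundle_params <- function(bundle, p) {
  for (l in seq_along(bundle$layers)) {
    bundle$layers[[l]]$W <- p[[paste0("W", l)]]
    bundle$layers[[l]]$b <- p[[paste0("b", l)]]
  }
  bundle$head_w <- p$head_w; bundle$head_b <- p$head_b
  bundle
}

# One forward + backward pass over a batch; returns per-sample losses and
# gradients with respect to every bundle parameter.
gazecam_batch_grads <- function(bundle, images, labels1, gaze, lambda,
                                cam_class, relu_on, Rz, Rzt, class_w = NULL) {
  B <- dim(images)[4L]
  fw <- forward_bundle(bundle, images, keep_cache = TRUE)
  K <- bundle$num_classes
  z <- sweep(fw$logits, 2L, apply(fw$logits, 2L, max), "-")
  p <- exp(z); p <- sweep(p, 2L, colSums(p), "/")
  ce_i <- -log(pmax(p[cbind(labels1, seq_len(B))], 1e-300))
  wt <- if (is.null(class_w)) rep(1, B) else class_w[labels1]
  Y <- matrix(0, K, B); Y[cbind(labels1, seq_len(B))] <- 1
  dlogits <- sweep(p - Y, 2L, wt / B, "*")

  d <- dim(fw$fmap); hw <- d[1L] * d[2L]
  dgap <- t(bundle$head_w) %*% dlogits                 # feat_c x B
  dhead_w <- dlogits %*% t(fw$gap)
  dhead_b <- rowSums(dlogits)
  dfmap <- array(0, d)
  for (b in seq_len(B))
    dfmap[, , , b] <- rep(dgap[, b] / hw, each = hw)

  mse_i <- numeric(B)
  if (lambda > 0) {
    pred1 <- max.col(t(fw$logits), ties.method = "first")
    cls <- if (cam_class == "true") labels1 else pred1
    NM <- nrow(Rz)
    for (b in seq_len(B)) {
      wc <- bundle$head_w[cls[b], ]
      wp <- pmax(wc, 0)
      fm <- matrix(fw$fmap[, , , b], hw, d[3L])
      raw <- if (relu_on == "weights") fm %*% wp else pmax(fm %*% wc, 0)
      s <- as.vector(sigmoid(Rz %*% raw))
      # range-match the gaze target to the sigmoid's reachable output: the
      # rectified CAM yields raw >= 0, hence s in [0.5, 1); supervising
      # toward (1 + h)/2 makes the optimum attainable and keeps the
      # consistency gradient from flattening the attention map
      hvec <- (1 + as.vector(gaze[, , b])) / 2
      mse_i[b] <- mean((s - hvec)^2)
      dup <- (lambda * 2 / (NM * B)) * (s - hvec) * s * (1 - s)
      draw <- Rzt %*% dup                              # hw x 1
      if (relu_on == "weights") {
        dfmap[, , , b] <- dfmap[, , , b] +
          array(as.vector(draw %*% matrix(wp, 1L)), d[1:3])
        dwp <- crossprod(fm, draw)
        dhead_w[cls[b], ] <- dhead_w[cls[b], ] +
          as.vector(dwp) * (wc > 0)
      } else {
        mask <- as.numeric(fm %*% wc > 0)
        dr <- as.vector(draw) * mask
        dfmap[, , , b] <- dfmap[, , , b] +
          array(as.vector(dr %*% matrix(wc, 1L)), d[1:3])
        dhead_w[cls[b], ] <- dhead_w[cls[b], ] + as.vector(crossprod(fm, dr))
      }
    }
  }

  grads <- list(head_w = dhead_w, head_b = dhead_b)
  dout <- dfmap
  for (l in rev(seq_along(bundle$layers))) {
    bw <- conv_backward(bundle$layers[[l]], bundle$geoms[[l]],
                        fw$cache[[l]], dout)
    grads[[paste0("W", l)]] <- bw$dW
    grads[[paste0("b", l)]] <- bw$db
    dout <- bw$dx
  }
  list(grads = grads, ce = ce_i, mse = mse_i, logits = fw$logits)
}

predict_labels1 <- function(bundle, images, batch = 16L) {
  n <- dim(images)[4L]
  out <- integer(n)
  for (s in seq(1L, n, by = batch)) {
    e <- min(s + batch - 1L, n)
    lg <- forward_bundle(bundle, images[, , , s:e, drop = FALSE])$logits
    out[s:e] <- max.col(t(lg), ties.method = "first")
  }
  out
}

#' Fit a gaze-supervised attention classifier
#'
#' Trains a convolutional classifier whose class-activation attention is
#' regularized toward human gaze-attention maps. Each mini-batch minimizes
#' the joint objective `CE + lambda_gaze * MSE`, where CE is the
#' classification cross-entropy and MSE the mean squared error between the
#' network's sigmoid-activated class-activation map (resized to the gaze
#' map's shape) and the max-normalized gaze map. `lambda_gaze = 0` is the
#' no-gaze ablation baseline. Optimization uses Adam under a cosine-annealing
#' warm-restart schedule; after every epoch the validation accuracy is
#' evaluated and the parameters achieving the best value are kept.
#'
#' @param data A `"polyp_data"` object (see [synthesize_polyp_data()]) or any
#'   list with `images` `(h, w, c, n)`, integer `labels` (0-based), `split`
#'   (`"train"/"val"/"test"` per image), `image_id`, and — required when
#'   `lambda_gaze > 0` — `gaze_maps` `(h, w, n)`.
#' @param lambda_gaze Weight of the attention-consistency term (default 1).
#' @param control A [gazecam_control()] object.
#' @param backbone Optional `"classifier_bundle"` to start from; by default a
#'   [tiny_backbone()] matched to the image size is initialized.
#' @param seed Integer seed governing weight initialization, data order and
#'   augmentation draws; runs are bit-reproducible given the same seed
#'   (single-threaded).
#' @return An object of class `"gazecam"`: the best-validation bundle, the
#'   per-epoch `history` data frame (`epoch`, `lr`, `ce`, `mse`, `total`,
#'   `val_acc`), `best_val_acc`, and the fitting configuration.
#' @seealso [predict.gazecam()], [evaluate_model()], [network_attention()]
#' @export
gazecam <- function(data, lambda_gaze = 1, control = gazecam_control(),
                    backbone = NULL, seed = 1L) {
  stopifnot(lambda_gaze >= 0, inherits(control, "gazecam_control"))
  images <- data$images; labels0 <- data$labels; split <- data$split
  stopifnot(length(dim(images)) == 4L,
            length(labels0) == dim(images)[4L],
            length(split) == dim(images)[4L])
  K <- max(length(unique(labels0)), max(labels0) + 1L, 2L)
  tr <- which(split == "train"); va <- which(split == "val")
  if (length(tr) == 0L) stop("no training images in 'data'", call. = FALSE)
  if (length(va) == 0L) va <- tr  # degenerate but usable for smoke runs
  if (lambda_gaze > 0) {
    if (is.null(data$gaze_maps))
      stop("lambda_gaze > 0 requires gaze maps for all training images",
           call. = FALSE)
    miss <- tr[apply(data$gaze_maps[, , tr, drop = FALSE], 3L,
                     function(m) anyNA(m))]
    if (length(miss))
      stop(sprintf("missing gaze map for image(s): %s",
                   paste(data$image_id[miss], collapse = ", ")), call. = FALSE)
  }

  set.seed(seed)
  if (is.null(backbone))
    backbone <- tiny_backbone(input_size = dim(images)[1L],
                              in_channels = dim(images)[3L], num_classes = K)
  bundle <- backbone
  img_h <- dim(images)[1L]; img_w <- dim(images)[2L]
  Rz <- bilinear_resize_matrix(bundle$feat_h, bundle$feat_w, img_h, img_w)
  Rzt <- t(Rz)
  class_w <- control$class_weights
  if (!is.null(class_w)) stopifnot(length(class_w) == K)

  params <- bundle_params(bundle)
  mstate <- lapply(params, function(x) x * 0)
  vstate <- mstate
  step <- 0L
  hist <- data.frame(epoch = integer(), lr = numeric(), ce = numeric(),
                     mse = numeric(), total = numeric(), val_acc = numeric())
  best <- list(acc = -Inf, params = params, epoch = 0L)

  for (epoch in seq_len(control$max_epochs)) {
    lr <- scheduler_lr(epoch - 1L, control)
    ord <- sample(tr)
    ce_sum <- 0; mse_sum <- 0; tot_sum <- 0; n_seen <- 0L
    for (s in seq(1L, length(ord), by = control$batch_train)) {
      bi <- ord[s:min(s + control$batch_train - 1L, length(ord))]
      B <- length(bi)
      xb <- array(NA_real_, c(img_h, img_w, dim(images)[3L], B))
      gb <- if (lambda_gaze > 0) array(0, c(img_h, img_w, B)) else
        array(0, c(img_h, img_w, B))
      for (j in seq_len(B)) {
        gm <- if (lambda_gaze > 0) data$gaze_maps[, , bi[j]] else NULL
        au <- augment_pair(images[, , , bi[j]], gm, control$augment)
        xb[, , , j] <- au$image
        if (!is.null(au$gaze_map)) gb[, , j] <- au$gaze_map
      }
      res <- gazecam_batch_grads(bundle, xb, labels0[bi] + 1L, gb,
                                 lambda_gaze, control$cam_class,
                                 control$relu_on, Rz, Rzt, class_w)
      step <- step + 1L
      b1 <- control$beta1; b2 <- control$beta2
      for (nm in names(params)) {
        g <- res$grads[[nm]]
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g^2
        mh <- mstate[[nm]] / (1 - b1^step)
        vh <- vstate[[nm]] / (1 - b2^step)
        params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + control$eps)
      }
      bundle <- set_bundle_params(bundle, params)
      ce_sum <- ce_sum + sum(res$ce)
      mse_sum <- mse_sum + sum(res$mse)
      tot_sum <- tot_sum + sum(total_loss(res$ce, res$mse, lambda_gaze))
      n_seen <- n_seen + B
    }
    pv <- predict_labels1(bundle, images[, , , va, drop = FALSE],
                          control$batch_val)
    val_acc <- mean(pv == labels0[va] + 1L)
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   ce = ce_sum / n_seen,
                                   mse = mse_sum / n_seen,
                                   total = tot_sum / n_seen,
                                   val_acc = val_acc))
    if (val_acc > best$acc)
      best <- list(acc = val_acc, params = params, epoch = epoch)
    if (control$verbose)
      cat(sprintf("epoch %3d  lr %.5f  ce %.4f  mse %.5f  val_acc %.3f\n",
                  epoch, lr, ce_sum / n_seen, mse_sum / n_seen, val_acc))
  }

  structure(list(bundle = set_bundle_params(bundle, best$params),
                 final_bundle = bundle,
                 history = hist, best_val_acc = best$acc,
                 best_epoch = best$epoch, lambda_gaze = lambda_gaze,
                 control = control, seed = seed,
                 num_classes = K, img_size = img_h),
            class = "gazecam")
}

#' @export
print.gazecam <- function(x, ...) {
  cat(sprintf(paste0("<gazecam> %d-class gaze-supervised classifier ",
                     "(lambda_gaze = %g)\n"), x$num_classes, x$lambda_gaze))
  cat(sprintf("  trained %d epochs; best validation accuracy %.4f (epoch %d)\n",
              nrow(x$history), x$best_val_acc, x$best_epoch))
  invisible(x)
}

#' @export
summary.gazecam <- function(object, ...) {
  print(object)
  h <- object$history
  cat("  final epoch losses: ce", sprintf("%.4f", h$ce[nrow(h)]),
      " mse", sprintf("%.5f", h$mse[nrow(h)]), "\n")
  invisible(object$history)
}

#' @export
coef.gazecam <- function(object, ...) {
  list(head_weights = object$bundle$head_w, head_bias = object$bundle$head_b)
}

#' Predict classes, probabilities, or attention maps
#'
#' @param object A fitted [gazecam()] model.
#' @param newdata A `"polyp_data"` object or an image array `(h, w, c, n)` /
#'   `(h, w, c)`.
#' @param type `"class"` (0-based labels), `"prob"` (`n x K` softmax matrix),
#'   or `"attention"` (array `(h, w, n)` of sigmoid class-activation maps at
#'   image resolution, for the predicted class).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.gazecam <- function(object, newdata,
                            type = c("class", "prob", "attention"), ...) {
  type <- match.arg(type)
  images <- if (is.list(newdata)) newdata$images else newdata
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  n <- dim(images)[4L]; bundle <- object$bundle
  bs <- object$control$batch_val
  if (type == "attention")
    att <- array(NA_real_, c(object$img_size, object$img_size, n))
  probs <- matrix(NA_real_, n, bundle$num_classes)
  for (s in seq(1L, n, by = bs)) {
    e <- min(s + bs - 1L, n)
    fw <- forward_bundle(bundle, images[, , , s:e, drop = FALSE])
    z <- sweep(fw$logits, 2L, apply(fw$logits, 2L, max), "-")
    p <- exp(z); p <- sweep(p, 2L, colSums(p), "/")
    probs[s:e, ] <- t(p)
    if (type == "attention") {
      cls <- max.col(t(fw$logits), ties.method = "first")
      att[, , s:e] <- network_attention(fw$fmap, bundle, cls,
                                        object$img_size, object$img_size,
                                        object$control$relu_on)
    }
  }
  switch(type,
         class = max.col(probs, ties.method = "first") - 1L,
         prob = probs,
         attention = att)
}

#' Plot the training history of a fitted model
#'
#' Two panels: training loss components per epoch, and validation accuracy
#' with the best checkpoint marked.
#'
#' @param x A fitted [gazecam()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gazecam <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$total, type = "l", xlab = "epoch", ylab = "loss",
                 main = "training loss", ...)
  graphics::lines(h$epoch, h$ce, lty = 2)
  graphics::legend("topright", c("total", "CE"), lty = c(1, 2), bty = "n")
  graphics::plot(h$epoch, h$val_acc, type = "l", xlab = "epoch",
                 ylab = "validation accuracy", main = "validation", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}
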