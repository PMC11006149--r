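# Built-in tiny CNN and the g()/h() feature-model adapter.
#
# The network is implemented directly in R with im2col convolutions so the
# whole pipeline runs on one CPU with no external deep-learning runtime.
# Internal activation layout throughout: [P, n, C] where P = H*W spatial
# positions in column-major order (pos = row + (col-1)*H), n = batch, C =
# channels. Convolutions are stride 1 with zero padding preserving the
# spatial size (7x7 for the fixed front end, 3x3 for the depthwise blocks).

conv_geom <- function(H, W, kh = 3L, pad = 1L) {
  Hp <- H + 2L * pad
  pos_r <- rep(seq_len(H), times = W)
  pos_c <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, kh * kh)
  o <- 0L
  for (dc in seq_len(kh) - 1L) for (dr in seq_len(kh) - 1L) {
    o <- o + 1L
    idx[, o] <- (pos_r + dr) + (pos_c + dc - 1L) * Hp
  }
  inner <- as.vector(outer(pad + seq_len(H), (pad + seq_len(W) - 1L) * Hp, `+`))
  list(P = H * W, Pp = Hp * (W + 2L * pad), idx = idx, inner = inner,
       n_off = kh * kh)
}

pool_geom <- function(H, W) {
  br <- rep(seq_len(H %/% 2L), times = W %/% 2L)
  bc <- rep(seq_len(W %/% 2L), each = H %/% 2L)
  list(p = list(
    (2L * br - 1L) + (2L * bc - 2L) * H,
    (2L * br)      + (2L * bc - 2L) * H,
    (2L * br - 1L) + (2L * bc - 1L) * H,
    (2L * br)      + (2L * bc - 1L) * H),
    Pout = (H %/% 2L) * (W %/% 2L))
}

conv_fwd <- function(x, W, b, g, cache = FALSE) {
  n <- dim(x)[2]; Cin <- dim(x)[3]; Cout <- ncol(W)
  xp <- array(0, c(g$Pp, n, Cin))
  xp[g$inner, , ] <- x
  out <- matrix(rep(b, each = g$P * n), g$P * n, Cout)
  Xo <- if (cache) vector("list", g$n_off)
  for (o in seq_len(g$n_off)) {
    xo <- xp[g$idx[, o], , , drop = FALSE]
    dim(xo) <- c(g$P * n, Cin)
    if (cache) Xo[[o]] <- xo
    out <- out + xo %*% W[((o - 1L) * Cin + 1L):(o * Cin), , drop = FALSE]
  }
  dim(out) <- c(g$P, n, Cout)
  list(out = out, Xo = Xo, n = n, Cin = Cin)
}

conv_bwd <- function(dY, W, g, fw, need_dx = TRUE) {
  n <- fw$n; Cin <- fw$Cin; Cout <- ncol(W)
  dY_mat <- dY
  dim(dY_mat) <- c(g$P * n, Cout)
  dW <- matrix(0, nrow(W), Cout)
  db <- colSums(dY_mat)
  dxp <- if (need_dx) array(0, c(g$Pp, n, Cin))
  for (o in seq_len(g$n_off)) {
    rows <- ((o - 1L) * Cin + 1L):(o * Cin)
    dW[rows, ] <- crossprod(fw$Xo[[o]], dY_mat)
    if (need_dx) {
      dxo <- dY_mat %*% t(W[rows, , drop = FALSE])
      dim(dxo) <- c(g$P, n, Cin)
      # for a fixed offset the position -> pixel map is injective, so
      # plain indexed addition accumulates correctly
      dxp[g$idx[, o], , ] <- dxp[g$idx[, o], , , drop = FALSE] + dxo
    }
  }
  list(dW = dW, db = db,
       dx = if (need_dx) dxp[g$inner, , , drop = FALSE])
}

pool_fwd <- function(x, pg) {
  parts <- lapply(pg$p, function(ix) x[ix, , , drop = FALSE])
  out <- pmax(parts[[1]], parts[[2]], parts[[3]], parts[[4]])
  list(out = out, parts = parts)
}

pool_bwd <- function(dY, pg, fw, dims) {
  dx <- array(0, dims)
  taken <- array(FALSE, dim(dY))
  for (k in 1:4) {
    mk <- (fw$parts[[k]] == fw$out) & !taken   # ties routed to first cell
    taken <- taken | mk
    dx[pg$p[[k]], , ] <- dY * mk
  }
  dx
}

#' Architecture of the built-in CNN
#'
#' Three 3x3 convolution blocks, then a 2x2 max-pool, global average
#' pooling and a linear two-class head. Block 1 is a fixed bank of
#' oriented grating filters (a deterministic Gabor-style front end with
#' orientations evenly spaced over 180 degrees and alternating fine/coarse
#' periods); blocks 2 and 3 are trainable depthwise 3x3 convolutions, so
#' every kernel of the designated layer refines one oriented texture
#' channel. This gives the tiny network the texture-selective kernels that
#' large pretrained classifiers exhibit, at desk scale. The post-ReLU maps
#' of block 3 are the designated feature-extraction layer, with side
#' `input_size / 4`.
#'
#' @param n_kernels number of kernels (oriented channels) at the
#'   designated layer.
#' @param periods grating periods (pixels) alternated across the filter
#'   bank.
#' @param input_size square input side in pixels; must be divisible by 8.
#' @return object of class `arch_config`.
#' @export
arch_config <- function(n_kernels = 16, periods = c(5, 3), input_size = 64) {
  stopifnot(n_kernels >= 2, length(periods) >= 1, all(periods >= 2))
  if (input_size %% 8 != 0 || input_size < 16)
    stopf("input_size must be >= 16 and divisible by 8")
  structure(list(n_kernels = as.integer(n_kernels),
                 periods = as.numeric(periods),
                 input_size = as.integer(input_size)),
            class = "arch_config")
}

# fixed oriented grating filters with a Gaussian envelope: zero-mean,
# L2-normalized; angle (k-1) * pi / K, period alternating through `periods`
gabor_bank <- function(n_kernels, periods, kh = 7L) {
  half <- (kh - 1L) / 2L
  W <- matrix(0, kh * kh, n_kernels)
  xy <- expand.grid(y = -half:half, x = -half:half)  # column-major order
  env <- exp(-(xy$x^2 + xy$y^2) / (2 * (half / 1.2)^2))
  for (k in seq_len(n_kernels)) {
    theta <- (k - 1) * pi / n_kernels
    p <- periods[(k - 1) %% length(periods) + 1]
    w <- env * cos(2 * pi * (cos(theta) * xy$x + sin(theta) * xy$y) / p)
    w <- w - mean(w)
    W[, k] <- w / sqrt(sum(w^2))
  }
  W
}

model_geometry <- function(arch) {
  s <- arch$input_size
  list(g1 = conv_geom(s, s, kh = 7L, pad = 3L), pg1 = pool_geom(s, s),
       g2 = conv_geom(s / 2, s / 2),    pg2 = pool_geom(s / 2, s / 2),
       g3 = conv_geom(s / 4, s / 4),    pg3 = pool_geom(s / 4, s / 4),
       map_size = as.integer(s / 4))
}

# W1 is the fixed filter bank; dw2/dw3 are depthwise (per-channel) 3x3
# weights initialized near an averaging filter
init_params <- function(arch) {
  K <- arch$n_kernels
  list(W1 = gabor_bank(K, arch$periods), b1 = rep(0, K),
       dw2 = matrix(1 / 9 + stats::rnorm(9 * K, 0, 0.05), 9, K),
       b2 = rep(0, K),
       dw3 = matrix(1 / 9 + stats::rnorm(9 * K, 0, 0.05), 9, K),
       b3 = rep(0, K),
       Wl = matrix(stats::rnorm(2 * K, 0, sqrt(1 / K)), K, 2), bl = rep(0, 2))
}

# depthwise 3x3 convolution: each channel convolved with its own kernel
dwconv_fwd <- function(x, W, b, g, cache = FALSE) {
  n <- dim(x)[2]; K <- dim(x)[3]
  xp <- array(0, c(g$Pp, n, K))
  xp[g$inner, , ] <- x
  out <- array(rep(b, each = g$P * n), c(g$P, n, K))
  Xo <- if (cache) vector("list", 9L)
  wrow <- function(o) array(rep(W[o, ], each = g$P * n), c(g$P, n, K))
  for (o in 1:9) {
    xo <- xp[g$idx[, o], , , drop = FALSE]
    if (cache) Xo[[o]] <- xo
    out <- out + xo * wrow(o)
  }
  list(out = out, Xo = Xo, n = n, K = K)
}

dwconv_bwd <- function(dY, W, g, fw, need_dx = TRUE) {
  n <- fw$n; K <- fw$K
  dW <- matrix(0, 9, K)
  db <- colSums(dY, dims = 2)
  dxp <- if (need_dx) array(0, c(g$Pp, n, K))
  for (o in 1:9) {
    dW[o, ] <- colSums(fw$Xo[[o]] * dY, dims = 2)
    if (need_dx) {
      wo <- array(rep(W[o, ], each = g$P * n), c(g$P, n, K))
      dxp[g$idx[, o], , ] <- dxp[g$idx[, o], , , drop = FALSE] + dY * wo
    }
  }
  list(dW = dW, db = db,
       dx = if (need_dx) dxp[g$inner, , , drop = FALSE])
}

# images: phantom_dataset, array [n,H,W], or single matrix -> array
as_image_array <- function(images) {
  if (inherits(images, "phantom_dataset")) return(images$images)
  if (is.matrix(images)) {
    arr <- array(0, c(1L, nrow(images), ncol(images)))
    arr[1, , ] <- images
    return(arr)
  }
  stopifnot(is.array(images), length(dim(images)) == 3)
  images
}

images_to_x <- function(images, input_size) {
  arr <- as_image_array(images)
  if (dim(arr)[2] != input_size || dim(arr)[3] != input_size)
    stopf("images are %dx%d but the model expects %dx%d",
          dim(arr)[2], dim(arr)[3], input_size, input_size)
  x <- aperm(arr, c(2, 3, 1))
  dim(x) <- c(input_size * input_size, dim(arr)[1], 1L)
  x
}

# fixed front end: filter bank conv + ReLU + pool; output [P/4, n, K]
cnn_frontend <- function(model, x) {
  p <- model$params; gm <- model$geom
  c1 <- conv_fwd(x, p$W1, p$b1, gm$g1, cache = FALSE)
  pool_fwd(pmax(c1$out, 0), gm$pg1)$out
}

# trainable back end from the front-end output; mask_keep is a logical
# K-vector applied to the designated layer's maps (the hook between g and h);
# drop_scale is a numeric K-vector used only during training (channel
# dropout with inverted scaling)
cnn_backend <- function(model, pl1, mask_keep = NULL, cache = FALSE,
                        drop_scale = NULL) {
  p <- model$params; gm <- model$geom
  c2 <- dwconv_fwd(pl1, p$dw2, p$b2, gm$g2, cache)
  a2 <- pmax(c2$out, 0)
  pl2 <- pool_fwd(a2, gm$pg2)
  c3 <- dwconv_fwd(pl2$out, p$dw3, p$b3, gm$g3, cache)
  a3 <- pmax(c3$out, 0)                      # designated layer g(x)
  f <- a3
  if (!is.null(mask_keep) && !all(mask_keep)) f[, , !mask_keep] <- 0
  if (!is.null(drop_scale))
    f <- f * array(rep(drop_scale, each = dim(f)[1] * dim(f)[2]), dim(f))
  pl3 <- pool_fwd(f, gm$pg3)
  gap <- colMeans(pl3$out)                   # [n, K]
  if (is.null(dim(gap))) gap <- matrix(gap, nrow = 1)
  feat <- if (isTRUE(model$head_norm)) l2_normalize_rows(gap) else gap
  logits <- sweep(feat %*% p$Wl, 2, p$bl, `+`)
  list(logits = logits, a3 = a3,
       cache = if (cache) list(c2 = c2, pl2 = pl2, c3 = c3, pl3 = pl3,
                               gap = gap))
}

# row-wise L2 normalization of pooled features; the refit head classifies
# the relative activation pattern, so deleting zero-weight channels only
# rescales the pattern and cannot flip a decision
l2_normalize_rows <- function(x) x / (sqrt(rowSums(x^2)) + 1e-8)

# full forward pass
cnn_forward <- function(model, x, mask_keep = NULL, cache = FALSE) {
  cnn_backend(model, cnn_frontend(model, x), mask_keep = mask_keep,
              cache = cache)
}

cnn_backward <- function(model, fw, dlogits, drop_scale = NULL) {
  p <- model$params; gm <- model$geom; cc <- fw$cache
  n <- nrow(dlogits); K <- model$arch$n_kernels
  grads <- list()
  grads$Wl <- crossprod(cc$gap, dlogits)
  grads$bl <- colSums(dlogits)
  dgap <- dlogits %*% t(p$Wl)
  P3 <- gm$pg3$Pout
  dpl3 <- array(rep(as.vector(dgap) / P3, each = P3), c(P3, n, K))
  df <- pool_bwd(dpl3, gm$pg3, cc$pl3, dim(fw$a3))
  if (!is.null(drop_scale))
    df <- df * array(rep(drop_scale, each = dim(df)[1] * dim(df)[2]),
                     dim(df))
  da3 <- df * (cc$c3$out > 0)
  b3 <- dwconv_bwd(da3, p$dw3, gm$g3, cc$c3)
  grads$dw3 <- b3$dW; grads$b3 <- b3$db
  dpl2 <- pool_bwd(b3$dx, gm$pg2, cc$pl2, c(gm$g2$P, n, K))
  da2 <- dpl2 * (cc$c2$out > 0)
  b2 <- dwconv_bwd(da2, p$dw2, gm$g2, cc$c2, need_dx = FALSE)
  grads$dw2 <- b2$dW; grads$b2 <- b2$db
  # block 1 is the fixed filter bank: no gradient
  grads
}

softmax_probs <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Train the built-in tiny CNN on a phantom dataset
#'
#' Trains by mini-batch Adam on softmax cross-entropy with a fixed seed and
#' epoch budget; fully deterministic given `(dataset, arch, seed)`. Either
#' an internal stratified split (`val_fraction`) or an explicit
#' `val_dataset` provides the validation accuracy reported in the model's
#' `train_report`.
#'
#' @param dataset a balanced `phantom_dataset`.
#' @param arch an [arch_config()].
#' @param seed integer seed controlling initialization and batch order.
#' @param epochs,batch_size,lr optimizer budget and step size.
#' @param weight_decay decoupled (AdamW-style) decay on the linear head;
#'   drives the weights of task-irrelevant kernels toward zero.
#' @param dropout per-batch channel dropout probability at the designated
#'   layer during training (inverted scaling).
#' @param sparse_head refit the linear head after backprop as a
#'   thresholded diagonal-LDA readout of the pooled features. Kernels
#'   whose class separation is negligible get exactly-zero head weights,
#'   so muting them leaves predictions unchanged — the class-wise
#'   activation sparsity that kernel-relevance experiments rely on.
#' @param head_min_effect minimum per-kernel class contrast (between-class
#'   mean separation over the pooled mean energy) below which a kernel's
#'   head weight is set to zero.
#' @param val_fraction fraction per class held out for validation when
#'   `val_dataset` is NULL.
#' @param val_dataset optional separate `phantom_dataset` for validation.
#' @param min_val_acc abort threshold: training that ends below this
#'   validation accuracy raises an error with diagnostics.
#' @return object of class `feature_model`.
#' @export
train_tiny_cnn <- function(dataset, arch = arch_config(), seed = 1L,
                           epochs = 20L, batch_size = 32L, lr = 3e-3,
                           weight_decay = 0.1, dropout = 0,
                           sparse_head = TRUE, head_min_effect = 0.25,
                           val_fraction = 0.2,
                           val_dataset = NULL, min_val_acc = 0.7) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  labels <- dataset$labels
  if (sum(labels == 0) != sum(labels == 1))
    stopf("training dataset must be class-balanced")
  if (dim(dataset$images)[2] != arch$input_size)
    stopf("dataset images are %dx%d but arch expects %dx%d",
          dim(dataset$images)[2], dim(dataset$images)[3],
          arch$input_size, arch$input_size)
  set.seed(seed)
  geom <- model_geometry(arch)
  params <- init_params(arch)
  model <- structure(list(params = params, arch = arch, geom = geom,
                          n_kernels = arch$n_kernels,
                          layer_id = "conv3_post_relu",
                          map_size = geom$map_size),
                     class = "feature_model")

  n <- length(labels)
  if (is.null(val_dataset)) {
    val_idx <- c(sample(which(labels == 0), round(val_fraction * sum(labels == 0))),
                 sample(which(labels == 1), round(val_fraction * sum(labels == 1))))
    train_idx <- setdiff(seq_len(n), val_idx)
  } else {
    train_idx <- seq_len(n)
    val_idx <- integer(0)
  }
  x_all <- images_to_x(dataset, arch$input_size)
  y_all <- labels

  # the filter-bank front end is fixed, so its output is computed once
  P1 <- geom$pg1$Pout
  pl1_all <- array(0, c(P1, n, arch$n_kernels))
  for (start in seq(1, n, by = 128)) {
    ii <- start:min(start + 127, n)
    pl1_all[, ii, ] <- cnn_frontend(model, x_all[, ii, , drop = FALSE])
  }

  m_state <- lapply(params, function(w) w * 0)
  v_state <- lapply(params, function(w) w * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0L
  losses <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    order_idx <- sample(train_idx)
    ep_loss <- 0
    for (start in seq(1, length(order_idx), by = batch_size)) {
      bi <- order_idx[start:min(start + batch_size - 1, length(order_idx))]
      yb <- y_all[bi]
      # channel dropout on the designated layer (as dropout in the head of
      # standard image classifiers): the head learns not to depend on any
      # fixed subset of kernels, which is what makes muting meaningful
      keep <- stats::runif(arch$n_kernels) > dropout
      if (!any(keep)) keep[sample.int(arch$n_kernels, 1)] <- TRUE
      drop_scale <- keep / (1 - dropout)
      fw <- cnn_backend(model, pl1_all[, bi, , drop = FALSE], cache = TRUE,
                        drop_scale = drop_scale)
      probs <- softmax_probs(fw$logits)
      onehot <- cbind(yb == 0, yb == 1) * 1
      ep_loss <- ep_loss - sum(log(pmax(probs[cbind(seq_along(bi), yb + 1)], 1e-12)))
      dlogits <- (probs - onehot) / length(bi)
      grads <- cnn_backward(model, fw, dlogits, drop_scale = drop_scale)
      t_step <- t_step + 1L
      for (nm in names(grads)) {
        m_state[[nm]] <- beta1 * m_state[[nm]] + (1 - beta1) * grads[[nm]]
        v_state[[nm]] <- beta2 * v_state[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- m_state[[nm]] / (1 - beta1^t_step)
        vhat <- v_state[[nm]] / (1 - beta2^t_step)
        # decoupled weight decay on the head drives the weights of
        # task-irrelevant kernels to zero, so muting them is near-neutral
        wd <- if (nm == "Wl") lr * weight_decay else 0
        model$params[[nm]] <- model$params[[nm]] * (1 - wd) -
          lr * mhat / (sqrt(vhat) + eps)
      }
      # the depthwise blocks are constrained to nonnegative (smoothing)
      # weights, so each kernel's map remains a local average of its
      # oriented-energy channel and stays spatially faithful
      model$params$dw2 <- pmax(model$params$dw2, 0)
      model$params$dw3 <- pmax(model$params$dw3, 0)
    }
    losses[epoch] <- ep_loss / length(order_idx)
  }

  if (sparse_head) {
    # refit the classifier head as a thresholded diagonal-LDA readout of
    # the pooled per-kernel features (shrunken-centroid style). Kernels
    # whose between-class mean separation is below `head_min_effect`
    # times the largest separation get exactly-zero weight, so muting
    # them provably cannot move a prediction; the rest are weighted by
    # separation over within-class variance with the intercept at the
    # balanced midpoint. Deterministic given the training data — this is
    # the adapter's stand-in for sparsity-promoting training of the head.
    gap <- cnn_backend(model, pl1_all[, train_idx, , drop = FALSE],
                       cache = TRUE)$cache$gap
    y_tr <- y_all[train_idx]
    mu0 <- colMeans(gap[y_tr == 0, , drop = FALSE])
    mu1 <- colMeans(gap[y_tr == 1, , drop = FALSE])
    v0 <- apply(gap[y_tr == 0, , drop = FALSE], 2, stats::var)
    v1 <- apply(gap[y_tr == 1, , drop = FALSE], 2, stats::var)
    sep <- mu1 - mu0
    # scale-free class contrast per kernel, plus a small absolute floor:
    # a kernel is read out only if its activation energy changes
    # macroscopically between the classes
    contrast <- abs(sep) / (0.5 * (mu0 + mu1) + 0.05)
    keep <- contrast >= head_min_effect &
      abs(sep) >= 0.05 * max(abs(sep))
    w <- ifelse(keep, sep / (0.5 * (v0 + v1) + 1e-6), 0)
    b <- -sum(w * (mu0 + mu1) / 2)
    model$params$Wl <- cbind(-w / 2, w / 2)
    model$params$bl <- c(-b / 2, b / 2)
  }

  pred_all <- max.col(cnn_backend(model, pl1_all)$logits,
                      ties.method = "first") - 1L
  train_acc <- mean(pred_all[train_idx] == y_all[train_idx])
  if (is.null(val_dataset)) {
    val_acc <- if (length(val_idx))
      mean(pred_all[val_idx] == y_all[val_idx])
    else NA_real_
  } else {
    val_acc <- mean(cnn_predict(model, val_dataset) == val_dataset$labels)
  }
  model$train_report <- list(seed = seed, epochs = epochs, lr = lr,
                             batch_size = batch_size,
                             n_train = length(train_idx),
                             n_val = if (is.null(val_dataset)) length(val_idx)
                                     else length(val_dataset$labels),
                             train_accuracy = train_acc,
                             val_accuracy = val_acc,
                             final_loss = losses[epochs], losses = losses)
  if (!is.na(val_acc) && val_acc < min_val_acc)
    stopf(paste0("training did not converge: validation accuracy %.3f < %.2f ",
                 "(train accuracy %.3f, final loss %.4f; consider more epochs ",
                 "or stronger texture contrast)"),
          val_acc, min_val_acc, train_acc, losses[epochs])
  model
}

#' @export
print.feature_model <- function(x, ...) {
  cat(sprintf("feature_model: %d kernels at %s (maps %dx%d), input %dx%d\n",
              x$n_kernels, x$layer_id, x$map_size, x$map_size,
              x$arch$input_size, x$arch$input_size))
  if (!is.null(x$train_report))
    cat(sprintf("  train acc %.3f, validation acc %.3f\n",
                x$train_report$train_accuracy, x$train_report$val_accuracy))
  invisible(x)
}

# internal: predictions from an [P, n, 1] batch, chunked to bound memory
predict_images <- function(model, x, mask_keep = NULL, chunk = 128L) {
  n <- dim(x)[2]
  out <- integer(n)
  for (start in seq(1, n, by = chunk)) {
    ii <- start:min(start + chunk - 1, n)
    fw <- cnn_forward(model, x[, ii, , drop = FALSE], mask_keep = mask_keep)
    out[ii] <- max.col(fw$logits, ties.method = "first") - 1L
  }
  out
}

#' Extract per-kernel activation maps at the designated layer
#'
#' The g() half of the adapter: returns the post-ReLU activation matrices of
#' every kernel at the model's designated feature-extraction layer, one 2-D
#' map per (image, kernel). Has no side effects on the model.
#'
#' @param model a `feature_model`.
#' @param images a `phantom_dataset`, an `n x H x W` array, or one matrix.
#' @return object of class `activation_set`: list with `activations`
#'   (array `n x K x h x w`), `image_ids`, `layer_id`, `map_size`.
#' @export
extract_activations <- function(model, images, chunk = 128L) {
  stopifnot(inherits(model, "feature_model"))
  x <- images_to_x(images, model$arch$input_size)
  n <- dim(x)[2]; K <- model$n_kernels; ms <- model$map_size
  acts <- array(0, c(n, K, ms, ms))
  for (start in seq(1, n, by = chunk)) {
    ii <- start:min(start + chunk - 1, n)
    fw <- cnn_forward(model, x[, ii, , drop = FALSE])
    a <- aperm(fw$a3, c(2, 3, 1))        # [n_chunk, K, Pm]
    dim(a) <- c(length(ii), K, ms, ms)
    acts[ii, , , ] <- a
  }
  structure(list(activations = acts, image_ids = seq_len(n),
                 layer_id = model$layer_id, map_size = ms),
            class = "activation_set")
}

#' @export
print.activation_set <- function(x, ...) {
  d <- dim(x$activations)
  cat(sprintf("activation_set: %d images x %d kernels, maps %dx%d (%s)\n",
              d[1], d[2], d[3], d[4], x$layer_id))
  invisible(x)
}

#' Kernel masks for muting or activate-only experiments
#'
#' `mute` replaces the listed kernels' feature maps with zeros before the
#' classifier head; `activate_only` keeps only the listed kernels (i.e.
#' mutes the complement). `activate_only(S)` is by construction identical
#' to `mute(complement(S))`.
#'
#' @param kernels integer kernel ids (1-based).
#' @param mode `"mute"` or `"activate_only"`.
#' @param n_kernels total kernels at the designated layer.
#' @return object of class `kernel_mask`.
#' @export
kernel_mask <- function(kernels, mode = c("mute", "activate_only"),
                        n_kernels) {
  mode <- match.arg(mode)
  kernels <- as.integer(kernels)
  if (length(kernels) && (min(kernels) < 1 || max(kernels) > n_kernels))
    stopf("kernel ids must be in 1..%d", n_kernels)
  structure(list(mode = mode, kernels = sort(unique(kernels)),
                 n_kernels = as.integer(n_kernels)),
            class = "kernel_mask")
}

mask_keep_vector <- function(mask, n_kernels) {
  if (is.null(mask)) return(NULL)
  stopifnot(inherits(mask, "kernel_mask"))
  if (mask$n_kernels != n_kernels)
    stopf("mask is for %d kernels, model has %d", mask$n_kernels, n_kernels)
  keep <- rep(TRUE, n_kernels)
  if (mask$mode == "mute") keep[mask$kernels] <- FALSE
  else keep <- seq_len(n_kernels) %in% mask$kernels
  keep
}

#' Class predictions under a kernel mask
#'
#' Runs the full network with the masked kernels' feature maps replaced by
#' zeros between g() and h(). An empty mute mask reproduces the unmasked
#' predictions exactly. Masking is stateless.
#'
#' @param model a `feature_model`.
#' @param images images accepted by [extract_activations()].
#' @param mask a [kernel_mask()] or NULL for the plain forward pass.
#' @return integer vector of 0/1 predictions.
#' @export
predict_masked <- function(model, images, mask = NULL) {
  keep <- mask_keep_vector(mask, model$n_kernels)
  x <- images_to_x(images, model$arch$input_size)
  predict_images(model, x, mask_keep = keep)
}

#' Plain CNN predictions h(g(x))
#'
#' @inheritParams predict_masked
#' @return integer vector of 0/1 predictions.
#' @export
cnn_predict <- function(model, images) predict_masked(model, images, NULL)

#' Classifier-head predictions from stored activations
#'
#' The h() half of the adapter: applies the head (max-pool, global average
#' pool, linear layer) to an [extract_activations()] result, optionally
#' under a kernel mask. Identical to [predict_masked()] on the same images;
#' used by the ablation experiments to avoid recomputing g().
#'
#' @param model a `feature_model`.
#' @param activations an `activation_set` from this model.
#' @param mask a [kernel_mask()] or NULL.
#' @return integer vector of 0/1 predictions.
#' @export
predict_from_activations <- function(model, activations, mask = NULL) {
  stopifnot(inherits(activations, "activation_set"))
  keep <- mask_keep_vector(mask, model$n_kernels)
  acts <- activations$activations
  n <- dim(acts)[1]; K <- dim(acts)[2]; ms <- dim(acts)[3]
  if (K != model$n_kernels)
    stopf("activation set has %d kernels, model has %d", K, model$n_kernels)
  f <- aperm(acts, c(3, 4, 1, 2))
  dim(f) <- c(ms * ms, n, K)
  if (!is.null(keep) && !all(keep)) f[, , !keep] <- 0
  pl <- pool_fwd(f, model$geom$pg3)
  gap <- colMeans(pl$out)
  if (is.null(dim(gap))) gap <- matrix(gap, nrow = 1)
  feat <- if (isTRUE(model$head_norm)) l2_normalize_rows(gap) else gap
  logits <- sweep(feat %*% model$params$Wl, 2, model$params$bl, `+`)
  max.col(logits, ties.method = "first") - 1L
}

#' Save / load a feature model checkpoint
#'
#' @param model a `feature_model`.
#' @param path checkpoint file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "feature_model"))
  saveRDS(list(params = model$params, arch = model$arch,
               head_norm = isTRUE(model$head_norm),
               train_report = model$train_report), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  geom <- model_geometry(obj$arch)
  structure(list(params = obj$params, arch = obj$arch, geom = geom,
                 n_kernels = obj$arch$n_kernels,
                 layer_id = "conv3_post_relu", map_size = geom$map_size,
                 head_norm = isTRUE(obj$head_norm),
                 train_report = obj$train_report),
            class = "feature_model")
}

#' Export activations to disk
#'
#' Writes the activation array as a flat binary container of doubles plus
#' an index CSV (`image_id`, `kernel_id`) describing row order; maps are
#' stored row-block-wise in image-major, kernel-minor order.
#'
#' @param activations an `activation_set`.
#' @param prefix output path prefix; writes `<prefix>.bin` and
#'   `<prefix>_index.csv`.
#' @export
export_activations <- function(activations, prefix) {
  stopifnot(inherits(activations, "activation_set"))
  d <- dim(activations$activations)
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(aperm(activations$activations, c(4, 3, 2, 1))), con)
  idx <- expand.grid(kernel_id = seq_len(d[2]), image_id = seq_len(d[1]))
  utils::write.csv(idx[, c("image_id", "kernel_id")],
                   paste0(prefix, "_index.csv"), row.names = FALSE)
  invisible(prefix)
}
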