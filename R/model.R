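# A small trainable heatmap pose network.
#
# Architecture: conv3x3(1->C) + ReLU, avgpool2, conv3x3(C->C) + ReLU,
# avgpool2, channel normalization (running stats, freezable), conv3x3(C->C)
# + ReLU, conv1x1(C->K logits). One score map per super-set keypoint at 1/4
# input resolution; probabilities come from a softmax across keypoint
# channels per pixel (not a spatial softmax). Forward/backward are written
# with im2col and BLAS matrix products; training uses Adam with step decay.

# ---- low-level layers ------------------------------------------------------

im2col3 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  xp <- array(0, c(H + 2, W + 2, C))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  cols <- matrix(0, H * W, 9 * C)
  j <- 0
  for (dx in 0:2) for (dy in 0:2) {
    j <- j + 1
    slab <- xp[dy + seq_len(H), dx + seq_len(W), , drop = FALSE]
    cols[, ((j - 1) * C + 1):(j * C)] <- matrix(slab, H * W, C)
  }
  cols
}

col2im3 <- function(dcols, H, W, C) {
  dxp <- array(0, c(H + 2, W + 2, C))
  j <- 0
  for (dx in 0:2) for (dy in 0:2) {
    j <- j + 1
    blk <- array(dcols[, ((j - 1) * C + 1):(j * C)], c(H, W, C))
    dxp[dy + seq_len(H), dx + seq_len(W), ] <-
      dxp[dy + seq_len(H), dx + seq_len(W), , drop = FALSE] + blk
  }
  dxp[2:(H + 1), 2:(W + 1), , drop = FALSE]
}

conv3_fwd <- function(x, W4, b) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; Cout <- length(b)
  cols <- im2col3(x)
  Wmat <- matrix(aperm(W4, c(3, 1, 2, 4)), 9 * Cin, Cout)
  out <- cols %*% Wmat
  out <- sweep(out, 2, b, "+")
  list(y = array(out, c(H, W, Cout)), cols = cols, Wmat = Wmat)
}

conv3_bwd <- function(cache, x_dim, dY) {
  H <- x_dim[1]; W <- x_dim[2]; Cin <- x_dim[3]
  Cout <- dim(dY)[3]
  dmat <- matrix(dY, H * W, Cout)
  dW <- crossprod(cache$cols, dmat)                    # (9C) x Cout
  dW4 <- aperm(array(dW, c(Cin, 3, 3, Cout)), c(2, 3, 1, 4))
  db <- colSums(dmat)
  dcols <- dmat %*% t(cache$Wmat)
  dx <- col2im3(dcols, H, W, Cin)
  list(dW = dW4, db = db, dx = dx)
}

conv1_fwd <- function(x, Wm, b) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  xm <- matrix(x, H * W, Cin)
  out <- sweep(xm %*% Wm, 2, b, "+")
  list(y = array(out, c(H, W, ncol(Wm))), xm = xm)
}

conv1_bwd <- function(cache, x_dim, Wm, dY) {
  H <- x_dim[1]; W <- x_dim[2]
  dmat <- matrix(dY, H * W, dim(dY)[3])
  list(dW = crossprod(cache$xm, dmat), db = colSums(dmat),
       dx = array(dmat %*% t(Wm), x_dim))
}

relu_fwd <- function(x) pmax(x, 0)

avgpool2_fwd <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  y <- (x[seq(1, H, 2), , , drop = FALSE] +
        x[seq(2, H, 2), , , drop = FALSE]) / 2
  (y[, seq(1, W, 2), , drop = FALSE] +
   y[, seq(2, W, 2), , drop = FALSE]) / 2
}

avgpool2_bwd <- function(dY, x_dim) {
  ri <- rep(seq_len(dim(dY)[1]), each = 2)
  ci <- rep(seq_len(dim(dY)[2]), each = 2)
  dY[ri, ci, , drop = FALSE] / 4
}

# Per-channel normalization with running statistics (batch-norm style over
# the pixels of the current image). `update_stats = FALSE` uses the stored
# running statistics (the frozen mode used during video adaptation).
cnorm_fwd <- function(x, gamma, beta, running, update_stats,
                      momentum = 0.1, eps = 1e-5) {
  C <- dim(x)[3]; N <- dim(x)[1] * dim(x)[2]
  xm <- matrix(x, N, C)
  if (update_stats) {
    mu <- colMeans(xm)
    va <- colMeans(sweep(xm, 2, mu)^2)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * va
  } else {
    mu <- running$mean
    va <- running$var
  }
  xhat <- sweep(sweep(xm, 2, mu), 2, sqrt(va + eps), "/")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = array(y, dim(x)), xhat = xhat, mu = mu, va = va,
       running = running, batch_stats = update_stats, eps = eps)
}

cnorm_bwd <- function(cache, x_dim, gamma, dY) {
  N <- x_dim[1] * x_dim[2]; C <- x_dim[3]
  dy <- matrix(dY, N, C)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  inv_sd <- 1 / sqrt(cache$va + cache$eps)
  dxhat <- sweep(dy, 2, gamma, "*")
  if (cache$batch_stats) {
    dx <- sweep(dxhat - matrix(colMeans(dxhat), N, C, byrow = TRUE) -
                  cache$xhat *
                  matrix(colMeans(dxhat * cache$xhat), N, C, byrow = TRUE),
                2, inv_sd, "*")
  } else {
    dx <- sweep(dxhat, 2, inv_sd, "*")
  }
  list(dgamma = dgamma, dbeta = dbeta, dx = array(dx, x_dim))
}

# ---- model -----------------------------------------------------------------

#' Create a toy heatmap pose network
#'
#' @param keypoints Super-set keypoint names: one output channel each.
#' @param channels Width of the convolutional trunk.
#' @param seed Seed for weight initialization (He-normal).
#' @param stride Output stride (fixed at 4 by the two pooling stages).
#' @param max_input_height Inputs taller than this are resized to this
#'   height preserving aspect ratio before the forward pass.
#' @param peak_radius Default target disk radius (map cells) for training.
#' @return An object of class `pose_model`.
#' @export
toy_pose_model <- function(keypoints, channels = 12, seed = 1, stride = 4,
                           max_input_height = 400, peak_radius = 1) {
  stopifnot(length(keypoints) >= 1, channels >= 1)
  K <- length(keypoints)
  he <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)),
                                     dims)
  params <- withr::with_seed(seed, list(
    W1 = he(c(3, 3, 1, channels), 9),
    b1 = rep(0, channels),
    W2 = he(c(3, 3, channels, channels), 9 * channels),
    b2 = rep(0, channels),
    gamma = rep(1, channels),
    beta = rep(0, channels),
    W3 = he(c(3, 3, channels, channels), 9 * channels),
    b3 = rep(0, channels),
    W4 = matrix(rnorm(channels * K, 0, sqrt(2 / channels)), channels, K),
    b4 = rep(0, K)
  ))
  structure(
    list(params = params,
         running = list(mean = rep(0, channels), var = rep(1, channels)),
         config = list(keypoints = keypoints, channels = channels,
                       stride = stride, max_input_height = max_input_height,
                       peak_radius = peak_radius, seed = seed),
         history = tibble::tibble(step = integer(), loss = numeric())),
    class = "pose_model"
  )
}

#' @export
print.pose_model <- function(x, ...) {
  cat(sprintf(
    "<pose_model: %d keypoints, %d channels, stride %d, %d training steps>\n",
    length(x$config$keypoints), x$config$channels, x$config$stride,
    nrow(x$history)))
  invisible(x)
}

# Pad an image matrix (replicating edges) so both sides divide `by`.
pad_to_multiple <- function(img, by = 4) {
  H <- nrow(img); W <- ncol(img)
  H2 <- ceiling(H / by) * by
  W2 <- ceiling(W / by) * by
  if (H2 > H) img <- img[c(seq_len(H), rep(H, H2 - H)), , drop = FALSE]
  if (W2 > W) img <- img[, c(seq_len(W), rep(W, W2 - W)), drop = FALSE]
  img
}

prep_input <- function(img) {
  x <- (pad_to_multiple(img, 4) - 0.5) * 2
  array(x, c(dim(x), 1))
}

forward_pose <- function(model, x, update_stats = FALSE,
                         keep_cache = FALSE) {
  p <- model$params
  c1 <- conv3_fwd(x, p$W1, p$b1); a1 <- relu_fwd(c1$y)
  p1 <- avgpool2_fwd(a1)
  c2 <- conv3_fwd(p1, p$W2, p$b2); a2 <- relu_fwd(c2$y)
  p2 <- avgpool2_fwd(a2)
  nz <- cnorm_fwd(p2, p$gamma, p$beta, model$running, update_stats)
  c3 <- conv3_fwd(nz$y, p$W3, p$b3); a3 <- relu_fwd(c3$y)
  c4 <- conv1_fwd(a3, p$W4, p$b4)
  cache <- if (keep_cache) {
    list(x = x, c1 = c1, a1 = a1, p1 = p1, c2 = c2, a2 = a2, p2 = p2,
         nz = nz, c3 = c3, a3 = a3, c4 = c4)
  }
  list(logits = c4$y, cache = cache, running = nz$running)
}

backward_pose <- function(model, cache, dlogits) {
  p <- model$params
  g4 <- conv1_bwd(cache$c4, dim(cache$a3), p$W4, dlogits)
  da3 <- g4$dx * (cache$c3$y > 0)
  g3 <- conv3_bwd(cache$c3, dim(cache$nz$y), da3)
  gn <- cnorm_bwd(cache$nz, dim(cache$p2), p$gamma, g3$dx)
  dp2 <- avgpool2_bwd(gn$dx, dim(cache$a2))
  da2 <- dp2 * (cache$c2$y > 0)
  g2 <- conv3_bwd(cache$c2, dim(cache$p1), da2)
  dp1 <- avgpool2_bwd(g2$dx, dim(cache$a1))
  da1 <- dp1 * (cache$c1$y > 0)
  g1 <- conv3_bwd(cache$c1, dim(cache$x), da1)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       gamma = gn$dgamma, beta = gn$dbeta,
       W3 = g3$dW, b3 = g3$db, W4 = g4$dW, b4 = g4$db)
}

# ---- training --------------------------------------------------------------

#' Training configuration
#'
#' @param steps Number of optimization steps (one sampled image each).
#' @param lr Initial Adam learning rate; decays by `lr_factor` at the
#'   fractions of training in `lr_milestones` (step-decay schedule).
#' @param seed RNG seed controlling sampling and any augmentation.
#' @param loss A [loss_spec()].
#' @param batch_size Images whose gradients are averaged per step.
#' @param peak_radius Target disk radius in map cells.
#' @param freeze_norm_stats Keep normalization running statistics fixed.
#' @param lr_milestones,lr_factor Step-decay schedule.
#' @return A list of class `train_config`.
#' @export
train_config <- function(steps = 300, lr = 1e-4, seed = 1,
                         loss = loss_spec(), batch_size = 1,
                         peak_radius = 1, freeze_norm_stats = FALSE,
                         lr_milestones = c(0.7, 0.9), lr_factor = 0.3) {
  stopifnot(steps >= 1, lr > 0, batch_size >= 1)
  structure(list(steps = as.integer(steps), lr = lr, seed = seed,
                 loss = loss, batch_size = as.integer(batch_size),
                 peak_radius = peak_radius,
                 freeze_norm_stats = isTRUE(freeze_norm_stats),
                 lr_milestones = lr_milestones, lr_factor = lr_factor),
            class = "train_config")
}

# Precompute padded inputs and heatmap targets for every image.
prepare_training_set <- function(model, images, annotations) {
  vocab <- attr(annotations, "keypoints") %||%
    unique(annotations$keypoint)
  if (!identical(vocab, model$config$keypoints)) {
    abort(paste0(
      "vocabulary mismatch between model and dataset; project the dataset ",
      "into the model's super-set space first (see match_keypoints() for ",
      "automatic alignment)"))
  }
  ids <- intersect(names(images), unique(annotations$image_id))
  if (length(ids) == 0) abort("empty dataset")
  lapply(ids, function(id) {
    x <- prep_input(images[[id]])
    ann <- annotations[annotations$image_id == id, ]
    ann <- ann[match(vocab, ann$keypoint), ]
    list(id = id, x = x,
         ann = ann,
         map_shape = c(dim(x)[1] / model$config$stride,
                       dim(x)[2] / model$config$stride))
  })
}

#' Train a pose model with the masked loss
#'
#' Runs Adam on the keypoint-gradient-masked loss over a merged
#' super-set-space dataset. Reproducible per seed; the loss history is
#' recorded per step and appended to the model.
#'
#' @param model A [toy_pose_model()].
#' @param images Named list of grayscale image matrices.
#' @param annotations Projected-annotation tibble covering the same image
#'   ids, in the model's super-set vocabulary.
#' @param config A [train_config()].
#' @return The trained `pose_model` (weights, running statistics, and
#'   `history` updated).
#' @export
train_pose_model <- function(model, images, annotations,
                             config = train_config()) {
  data <- prepare_training_set(model, images, annotations)
  targets <- lapply(data, function(d)
    render_targets(d$ann, d$map_shape, peak_radius = config$peak_radius,
                   stride = model$config$stride))
  n <- length(data)
  opt <- list(m = NULL, v = NULL, t = 0)
  hist_step <- integer(config$steps)
  hist_loss <- numeric(config$steps)
  step0 <- nrow(model$history)
  milestones <- ceiling(config$lr_milestones * config$steps)

  withr::with_seed(config$seed, {
    for (s in seq_len(config$steps)) {
      idx <- sample.int(n, config$batch_size, replace = TRUE)
      grads <- NULL
      loss_val <- 0
      for (i in idx) {
        fw <- forward_pose(model, data[[i]]$x,
                           update_stats = !config$freeze_norm_stats,
                           keep_cache = TRUE)
        model$running <- fw$running
        batch <- targets[[i]]
        batch$logits <- fw$logits
        loss_val <- loss_val + masked_loss(batch, config$loss)
        dlogits <- masked_loss_logit_grad(fw$logits, batch, config$loss)
        g <- backward_pose(model, fw$cache, dlogits)
        grads <- if (is.null(grads)) g else
          purrr::map2(grads, g, `+`)
      }
      grads <- lapply(grads, function(g) g / length(idx))
      lr <- config$lr * config$lr_factor^sum(s >= milestones)
      upd <- adam_step(model$params, grads, opt, lr)
      model$params <- upd$params
      opt <- upd$opt
      hist_step[s] <- step0 + s
      hist_loss[s] <- loss_val / length(idx)
    }
  })
  model$history <- dplyr::bind_rows(
    model$history, tibble::tibble(step = hist_step, loss = hist_loss))
  model
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.null(opt$m)) {
    opt$m <- lapply(params, function(p) p * 0)
    opt$v <- lapply(params, function(p) p * 0)
  }
  opt$t <- opt$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

# ---- inference -------------------------------------------------------------

#' Decode score maps to keypoint coordinates
#'
#' Per-channel argmax with a deterministic tie-break (lowest (y, x) in
#' 0-based coordinates); confidence is the peak score. With `refine`,
#' coordinates are the score-weighted centroid of the 3x3 cell
#' neighborhood around the peak.
#'
#' @param probs rows x cols x K score array.
#' @param stride Map-to-image upsampling factor.
#' @param refine Sub-cell refinement flag.
#' @param keypoints Optional channel names.
#' @return Tibble: `keypoint`, `x`, `y` (input-image pixels),
#'   `confidence`.
#' @export
decode_heatmaps <- function(probs, stride = 4, refine = TRUE,
                            keypoints = NULL) {
  K <- dim(probs)[3]
  nr <- dim(probs)[1]; nc <- dim(probs)[2]
  keypoints <- keypoints %||% dimnames(probs)[[3]] %||%
    paste0("kp", seq_len(K))
  out <- vector("list", K)
  half <- (stride - 1) / 2
  for (k in seq_len(K)) {
    m <- probs[, , k]
    idx <- which.max(t(m))            # row-major: lowest (y, x) wins ties
    ry <- ceiling(idx / nc)
    rx <- idx - (ry - 1) * nc
    conf <- m[ry, rx]
    cy <- ry - 1; cx <- rx - 1        # 0-based cell coords
    if (refine) {
      ys <- max(1, ry - 1):min(nr, ry + 1)
      xs <- max(1, rx - 1):min(nc, rx + 1)
      wgt <- m[ys, xs, drop = FALSE]
      wsum <- sum(wgt)
      if (wsum > 0) {
        cy <- sum((ys - 1) * rowSums(wgt)) / wsum
        cx <- sum((xs - 1) * colSums(wgt)) / wsum
      }
    }
    out[[k]] <- tibble::tibble(keypoint = keypoints[k],
                               x = cx * stride + half,
                               y = cy * stride + half,
                               confidence = conf)
  }
  dplyr::bind_rows(out)
}

#' Run pose inference on one image
#'
#' Applies the input resize rule (images taller than the model's
#' `max_input_height` are resized to it, preserving aspect ratio), pads to
#' the network stride, decodes the channel-softmax score maps, and maps
#' coordinates back to the original image space.
#'
#' @param model A trained [toy_pose_model()].
#' @param image Grayscale matrix in `[0, 1]`.
#' @param refine Sub-cell peak refinement.
#' @return Tibble: `keypoint`, `x`, `y`, `confidence` (original pixels).
#' @export
infer_pose <- function(model, image, refine = TRUE) {
  H0 <- nrow(image); W0 <- ncol(image)
  img <- image
  if (H0 > model$config$max_input_height) {
    img <- resize_image(image, model$config$max_input_height)
  }
  Hr <- nrow(img); Wr <- ncol(img)
  x <- prep_input(img)
  fw <- forward_pose(model, x, update_stats = FALSE)
  probs <- softmax_over_keypoints(fw$logits)
  preds <- decode_heatmaps(probs, stride = model$config$stride,
                           refine = refine,
                           keypoints = model$config$keypoints)
  preds$x <- rescale_coords(preds$x, Wr, W0)
  preds$y <- rescale_coords(preds$y, Hr, H0)
  preds
}

#' @export
predict.pose_model <- function(object, newdata, ...) {
  if (is.matrix(newdata)) return(infer_pose(object, newdata, ...))
  purrr::imap_dfr(newdata, function(img, id)
    dplyr::mutate(infer_pose(object, img, ...), image_id = id,
                  .before = 1))
}

#' Save / load a pose model checkpoint
#'
#' Single-file archive holding config, weights, running statistics and
#' training history.
#'
#' @param model A `pose_model`.
#' @param path Checkpoint file.
#' @return `path` invisibly / the restored `pose_model`.
#' @export
save_pose_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_pose_model
#' @export
load_pose_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "pose_model"))
  m
}
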