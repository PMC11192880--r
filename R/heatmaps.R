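# Heatmap targets, keypoint gradient masks, and the masked loss family.
#
# The gradient mask n_k is a property of the annotation's visibility flag
# alone: n_k = 0 exactly when flag = -1 (keypoint not defined in the source
# dataset). Flags 0 and 1 (defined but unlabeled / labeled-invisible) keep
# n_k = 1 with an all-zero target map: masking those too would stop the
# model from learning to assign low scores at occluded keypoints.

#' Loss specification
#'
#' Two masked families are available: `"masked-lz"` (elementwise L_z on
#' the softmax probabilities; z = 2 is squared error) and `"masked-ce"`
#' (cross-entropy on positive target cells). The L2 family is the
#' package default for training its toy models: with the channel softmax,
#' cross-entropy supervises only positive target cells, so background
#' probability mass is unconstrained and a channel can develop confident
#' spurious peaks; the squared loss drives background toward the uniform
#' floor 1/M while leaving masked keypoints untouched.
#'
#' @param family `"masked-lz"` or `"masked-ce"`.
#' @param z Exponent for the L_z family: 2 for squared error, 1 for L1.
#' @return An object of class `loss_spec`.
#' @export
loss_spec <- function(family = c("masked-lz", "masked-ce"), z = 2) {
  family <- match.arg(family)
  if (!z %in% c(1, 2)) abort("z must be 1 or 2")
  structure(list(family = family, z = z), class = "loss_spec")
}

#' Render heatmap targets and gradient masks for one image
#'
#' Targets are binary disks: t_k(i, j) = 1 for map cells within
#' `peak_radius` of the keypoint, 0 elsewhere. Keypoints with flag 0 or 1
#' produce all-zero targets but stay unmasked; flag -1 sets the gradient
#' mask n_k to 0. Keypoints landing outside the map after downscaling are
#' clamped to the border with a warning.
#'
#' @param annotation Projected-annotation tibble rows for one image
#'   (columns `keypoint`, `x`, `y`, `flag`), ordered by the super-set.
#' @param map_shape `c(rows, cols)` of the score map.
#' @param peak_radius Disk radius in map cells (0 = single cell).
#' @param stride Image-to-map downscale factor.
#' @return A list of class `heatmap_batch`: `targets` (rows x cols x K
#'   array in {0,1}), `mask` (length-K 0/1 vector), `keypoints`.
#' @export
render_targets <- function(annotation, map_shape, peak_radius = 1,
                           stride = 4) {
  stopifnot(all(c("keypoint", "x", "y", "flag") %in% names(annotation)))
  if (any(annotation$flag %in% c(1L, 2L) &
          !(is.finite(annotation$x) & is.finite(annotation$y)))) {
    abort("flags 1/2 require finite coordinates")
  }
  nr <- map_shape[1]; nc <- map_shape[2]
  K <- nrow(annotation)
  targets <- array(0, dim = c(nr, nc, K))
  mask <- as.numeric(annotation$flag != -1L)
  cy <- (annotation$y + 0.5) / stride - 0.5   # 0-based map coords
  cx <- (annotation$x + 0.5) / stride - 0.5
  rr <- matrix(rep(0:(nr - 1), times = nc), nr, nc)
  cc <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  clamped <- FALSE
  for (k in seq_len(K)) {
    if (annotation$flag[k] != 2L) next
    yk <- cy[k]; xk <- cx[k]
    if (yk < 0 || yk > nr - 1 || xk < 0 || xk > nc - 1) {
      clamped <- TRUE
      yk <- min(max(yk, 0), nr - 1)
      xk <- min(max(xk, 0), nc - 1)
    }
    d2 <- (rr - yk)^2 + (cc - xk)^2
    disk <- d2 <= peak_radius^2
    if (!any(disk)) {  # radius smaller than cell spacing: nearest cell
      disk <- d2 == min(d2)
      disk <- disk & cumsum(disk) == 1
    }
    targets[, , k][disk] <- 1
  }
  if (clamped) warn("keypoint outside score map after downscaling; clamped")
  structure(list(targets = targets, mask = mask,
                 keypoints = annotation$keypoint),
            class = "heatmap_batch")
}

#' Softmax across keypoint channels
#'
#' Converts logits to probabilities per pixel across all M keypoint
#' channels (including masked ones), so that scores sum to 1 at every
#' pixel. This is a channel softmax, not the spatial softmax most pose
#' codebases use. Overflow is handled by max subtraction.
#'
#' @param logits rows x cols x M array (finite).
#' @return Array of the same shape with per-pixel channel sums equal to 1.
#' @export
softmax_over_keypoints <- function(logits) {
  stopifnot(length(dim(logits)) == 3, all(is.finite(logits)))
  mx <- apply(logits, c(1, 2), max)
  e <- exp(logits - as.vector(mx))
  s <- apply(e, c(1, 2), sum)
  e / as.vector(s)
}

# Pull (probs, targets, mask) out of a heatmap_batch, deriving probs from
# logits when needed.
batch_pt <- function(batch) {
  p <- batch$probs
  if (is.null(p)) {
    if (is.null(batch$logits)) abort("heatmap batch has neither probs nor logits")
    p <- softmax_over_keypoints(batch$logits)
  }
  t <- batch$targets
  if (!identical(dim(p), dim(t))) abort("probability/target shape mismatch")
  if (length(batch$mask) != dim(t)[3]) abort("mask length != keypoint count")
  list(p = p, t = t, n = batch$mask)
}

#' Masked L_z heatmap loss
#'
#' `sum_k sum_ij n_k * |p_k(i,j) - t_k(i,j)|^z`: keypoints with mask 0
#' contribute exactly 0 regardless of their predictions.
#'
#' @param batch A `heatmap_batch` with `probs` (or `logits`), `targets`,
#'   `mask`.
#' @param spec A [loss_spec()], or `z` directly.
#' @return Non-negative scalar.
#' @export
masked_lz_loss <- function(batch, spec = loss_spec("masked-lz", z = 2)) {
  if (is.numeric(spec)) spec <- loss_spec("masked-lz", z = spec)
  if (!spec$z %in% c(1, 2)) abort("z must be 1 or 2")
  pt <- batch_pt(batch)
  per_k <- apply(abs(pt$p - pt$t)^spec$z, 3, sum)
  sum(pt$n * per_k)
}

#' Masked cross-entropy heatmap loss
#'
#' `-sum_k sum_ij n_k * t_k(i,j) * log p_k(i,j)`: zero-target pixels and
#' masked keypoints contribute 0. Probabilities are clamped at `eps`
#' where a positive target meets p = 0 (with a warning).
#'
#' @inheritParams masked_lz_loss
#' @param eps Clamp floor for log.
#' @return Non-negative scalar.
#' @export
masked_ce_loss <- function(batch, eps = 1e-12) {
  pt <- batch_pt(batch)
  pos <- pt$t > 0
  if (any(pt$p[pos] <= 0)) {
    warn("zero probability at a positive target; clamped with epsilon")
  }
  lp <- array(0, dim = dim(pt$p))
  lp[pos] <- log(pmax(pt$p[pos], eps))
  per_k <- apply(pt$t * lp, 3, sum)
  -sum(pt$n * per_k)
}

#' Evaluate a masked loss under a loss specification
#'
#' @inheritParams masked_lz_loss
#' @return Non-negative scalar.
#' @export
masked_loss <- function(batch, spec = loss_spec()) {
  if (spec$family == "masked-ce") masked_ce_loss(batch)
  else masked_lz_loss(batch, spec)
}

# Gradient of the masked loss at the logits (used by the training loop).
# For CE with channel softmax: dL/dl_m = (sum_k a_k) p_m - a_m with
# a_k = n_k t_k. For Lz: chain rule through the softmax Jacobian.
masked_loss_logit_grad <- function(logits, batch, spec = loss_spec()) {
  p <- softmax_over_keypoints(logits)
  t <- batch$targets
  n <- batch$mask
  K <- dim(t)[3]
  a <- t * rep(n, each = dim(t)[1] * dim(t)[2])
  if (spec$family == "masked-ce") {
    asum <- apply(a, c(1, 2), sum)
    g <- p * as.vector(asum) - a
  } else {
    d <- p - t
    dLdp <- if (spec$z == 2) 2 * d else sign(d)
    dLdp <- dLdp * rep(n, each = dim(t)[1] * dim(t)[2])
    dot <- apply(dLdp * p, c(1, 2), sum)
    g <- p * (dLdp - as.vector(dot))
  }
  g
}
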