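#' Weighted input stage
#'
#' The "weighted" part of the weighted CNN: a learnable per-gene weight
#' vector applied entrywise to the expression vector before grid embedding
#' (a 1x1 weighted convolution). `weighted_input_backward()` returns the
#' exact gradients of the stage: `grad_weights = upstream * x` and
#' `grad_x = upstream * w`.
#'
#' @param x Input vector (one sample's gene values).
#' @param gene_weights Weight vector of the same length.
#' @param upstream_grad Gradient flowing back into the stage output.
#' @return `weighted_input_forward()`: the weighted vector.
#'   `weighted_input_backward()`: list with `grad_x` and `grad_weights`.
#' @export
weighted_input_forward <- function(x, gene_weights) {
  if (length(x) != length(gene_weights)) {
    abort("`x` and `gene_weights` must have equal length.")
  }
  x * gene_weights
}

#' @rdname weighted_input_forward
#' @export
weighted_input_backward <- function(x, gene_weights, upstream_grad) {
  if (length(x) != length(gene_weights) || length(x) != length(upstream_grad)) {
    abort("`x`, `gene_weights` and `upstream_grad` must have equal length.")
  }
  list(grad_x = upstream_grad * gene_weights, grad_weights = upstream_grad * x)
}

as_maps <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

as_kernels <- function(k) {
  if (is.matrix(k)) array(k, dim = c(dim(k), 1L, 1L)) else k
}

# im2col over a batch array h x w x C x B: column (ki, kj, c) holds the
# input values seen by that kernel offset at every output position of every
# sample; rows ordered (oi, oj, b) column-major to match R array flattening.
im2col4 <- function(x, kh, kw) {
  d <- dim(x)
  h <- d[1]; w <- d[2]; C <- d[3]; B <- d[4]
  oh <- h - kh + 1L
  ow <- w - kw + 1L
  out <- matrix(0, nrow = oh * ow * B, ncol = kh * kw * C)
  col <- 0L
  for (c in seq_len(C)) {
    for (kj in seq_len(kw)) {
      for (ki in seq_len(kh)) {
        col <- col + 1L
        out[, ki + (kj - 1L) * kh + (c - 1L) * kh * kw] <-
          x[ki:(ki + oh - 1L), kj:(kj + ow - 1L), c, , drop = FALSE]
      }
    }
  }
  out
}

conv_fwd_batch <- function(x, kernels, biases, activation = "relu") {
  d <- dim(x)
  kd <- dim(kernels)
  if (kd[1] > d[1] || kd[2] > d[2]) {
    abort(sprintf(
      "kernel (%dx%d) larger than input (%dx%d).", kd[1], kd[2], d[1], d[2]
    ))
  }
  if (kd[3] != d[3]) abort("kernel input-channel count does not match input maps.")
  oh <- d[1] - kd[1] + 1L
  ow <- d[2] - kd[2] + 1L
  xc <- im2col4(x, kd[1], kd[2])
  W <- matrix(kernels, nrow = kd[1] * kd[2] * kd[3])
  pre_flat <- xc %*% W
  # rows of pre_flat are (oi, oj, b); fold bias in per output map
  pre_flat <- sweep(pre_flat, 2, biases, `+`)
  out_flat <- if (activation == "relu") pmax(pre_flat, 0) else pre_flat
  # reorder (oi,oj,b) x cout -> oh x ow x cout x B
  arr <- array(out_flat, dim = c(oh, ow, d[4], kd[4]))
  out <- aperm(arr, c(1, 2, 4, 3))
  list(
    out = out, xcol = xc, pre_flat = pre_flat, in_dim = d, k_dim = kd,
    kernels = kernels, activation = activation
  )
}

conv_bwd_batch <- function(dout, cache) {
  d <- cache$in_dim
  kd <- cache$k_dim
  oh <- d[1] - kd[1] + 1L
  ow <- d[2] - kd[2] + 1L
  # dout: oh x ow x cout x B -> rows (oi,oj,b) x cout
  dflat <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = kd[4])
  if (cache$activation == "relu") dflat <- dflat * (cache$pre_flat > 0)
  W <- matrix(cache$kernels, nrow = kd[1] * kd[2] * kd[3])
  dW <- crossprod(cache$xcol, dflat)
  db <- colSums(dflat)
  dxc <- dflat %*% t(W)
  dx <- array(0, dim = d)
  col <- 0L
  for (c in seq_len(kd[3])) {
    for (kj in seq_len(kd[2])) {
      for (ki in seq_len(kd[1])) {
        col <- ki + (kj - 1L) * kd[1] + (c - 1L) * kd[1] * kd[2]
        dx[ki:(ki + oh - 1L), kj:(kj + ow - 1L), c, ] <-
          dx[ki:(ki + oh - 1L), kj:(kj + ow - 1L), c, , drop = FALSE] +
          array(dxc[, col], dim = c(oh, ow, 1L, d[4]))
      }
    }
  }
  list(dx = dx, dkernels = array(dW, dim = kd), dbiases = db)
}

#' Convolution layer forward pass
#'
#' Valid (no-padding) cross-correlation of the input maps with a stack of
#' kernels, summed over input maps, plus a per-output-map bias, followed by
#' a ReLU (switchable to identity). Output spatial size is
#' `input - kernel + 1`.
#'
#' @param input_maps A `h x w` matrix (single map) or `h x w x C` array.
#' @param kernels A `k x k` matrix (single in/out map) or
#'   `k x k x C_in x C_out` array.
#' @param biases Numeric vector, one bias per output map.
#' @param activation `"relu"` (default) or `"identity"`.
#' @return A `oh x ow x C_out` array of output feature maps.
#' @export
conv_forward <- function(input_maps, kernels, biases = 0,
                         activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  x <- as_maps(input_maps)
  k <- as_kernels(kernels)
  x4 <- array(x, dim = c(dim(x), 1L))
  if (length(biases) == 1L) biases <- rep(biases, dim(k)[4])
  res <- conv_fwd_batch(x4, k, biases, activation)
  array(res$out, dim = dim(res$out)[1:3])
}

pool_fwd_batch <- function(x, pool) {
  if (pool == 1L) {
    return(list(out = x, pool = 1L))
  }
  d <- dim(x)
  h <- d[1]; w <- d[2]
  r1 <- seq(1L, h, by = 2L)
  c1 <- seq(1L, w, by = 2L)
  r2 <- pmin(r1 + 1L, h)
  c2 <- pmin(c1 + 1L, w)
  A1 <- x[r1, c1, , , drop = FALSE]
  A2 <- x[r2, c1, , , drop = FALSE]
  A3 <- x[r1, c2, , , drop = FALSE]
  A4 <- x[r2, c2, , , drop = FALSE]
  out <- pmax(A1, A2, A3, A4)
  list(
    out = out, pool = 2L, in_dim = d,
    r1 = r1, r2 = r2, c1 = c1, c2 = c2,
    A1 = A1, A2 = A2, A3 = A3, A4 = A4
  )
}

pool_bwd_batch <- function(dout, cache) {
  if (cache$pool == 1L) {
    return(dout)
  }
  d <- cache$in_dim
  od <- dim(dout)
  oh <- od[1]; ow <- od[2]; C <- od[3]; B <- od[4]
  out <- pmax(cache$A1, cache$A2, cache$A3, cache$A4)
  # first candidate attaining the block maximum receives the gradient
  k1 <- cache$A1 == out
  k2 <- !k1 & cache$A2 == out
  k3 <- !k1 & !k2 & cache$A3 == out
  dims <- od
  R1 <- array(cache$r1, dim = dims)
  R2 <- array(cache$r2, dim = dims)
  C1 <- array(rep(cache$c1, each = oh), dim = dims)
  C2 <- array(rep(cache$c2, each = oh), dim = dims)
  rows <- ifelse(k1 | k3, R1, R2)
  cols <- ifelse(k1 | k2, C1, C2)
  ch <- array(rep(seq_len(C), each = oh * ow), dim = dims)
  bb <- array(rep(seq_len(B), each = oh * ow * C), dim = dims)
  lin <- rows + (cols - 1L) * d[1] + (ch - 1L) * d[1] * d[2] +
    (bb - 1L) * d[1] * d[2] * d[3]
  dx <- array(0, dim = d)
  dx[as.vector(lin)] <- as.vector(dout)
  dx
}

#' Max-pooling layer forward pass
#'
#' Blockwise maximum over `pool x pool` windows. A 1x1 pool is the
#' identity. Odd trailing rows/columns form partial blocks that are pooled
#' rather than dropped, so the output spatial size is
#' `ceiling(input / pool)` and no edge information is discarded.
#'
#' @param maps A `h x w` matrix or `h x w x C` array.
#' @param pool Window side, 1 or 2.
#' @return The pooled matrix/array (same number of maps).
#' @export
maxpool_forward <- function(maps, pool = 2) {
  if (!pool %in% c(1, 2)) abort("`pool` must be 1 or 2.")
  x <- as_maps(maps)
  if (length(x) == 0L) abort("empty feature map.")
  x4 <- array(x, dim = c(dim(x), 1L))
  res <- pool_fwd_batch(x4, as.integer(pool))
  out <- array(res$out, dim = dim(res$out)[1:3])
  if (is.matrix(maps)) out[, , 1] else out
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Dense layer with softmax output
#'
#' The classification head: logits `x_i = sum_j w_ij y_j + b_i` followed by
#' a max-subtraction-stabilized softmax, so extreme logits cannot overflow
#' and the class scores always sum to 1.
#'
#' @param features Numeric vector (one sample) or matrix (samples in rows).
#' @param weights Weight matrix, `n_features x n_classes`.
#' @param bias Numeric vector, one entry per class.
#' @return Class probabilities; vector for vector input, matrix with one
#'   row per sample otherwise.
#' @export
dense_softmax_forward <- function(features, weights, bias) {
  vec <- !is.matrix(features)
  f <- if (vec) matrix(features, nrow = 1) else features
  if (ncol(f) != nrow(weights)) abort("feature/weight shape mismatch.")
  if (length(bias) != ncol(weights)) abort("bias/weight shape mismatch.")
  p <- softmax_rows(sweep(f %*% weights, 2, bias, `+`))
  if (vec) drop(p) else p
}
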