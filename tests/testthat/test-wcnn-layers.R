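test_that("gene grids are ceil-square, row-major, zero-padded", {
  g4 <- gene_grid(4)
  expect_equal(c(g4$height, g4$width, g4$pad_count), c(2, 2, 0))
  expect_equal(grid_embed(1:4, g4), matrix(c(1, 3, 2, 4), 2)) # row-major

  g5 <- gene_grid(5)
  expect_equal(c(g5$height, g5$width, g5$pad_count), c(3, 2, 1))
  m <- grid_embed(c(10, 20, 30, 40, 50), g5)
  expect_equal(m[3, 2], 0) # padded trailing cell

  # round trip for random vectors over assorted grid shapes
  set.seed(2)
  for (G in c(1, 5, 9, 17, 30)) {
    gg <- gene_grid(G)
    x <- rnorm(G)
    expect_identical(grid_unembed(grid_embed(x, gg), gg), x)
  }
  expect_error(grid_embed(1:3, g4), "does not match grid gene count")
})

test_that("the weighted input stage multiplies entrywise with exact gradients", {
  expect_equal(weighted_input_forward(c(2, 3), c(1, 1)), c(2, 3))
  expect_equal(weighted_input_forward(c(2, 3), c(0, 0)), c(0, 0))
  expect_equal(weighted_input_forward(c(2, 3), c(0.5, 2)), c(1, 6))
  expect_error(weighted_input_forward(1:3, 1:2), "equal length")

  bw <- weighted_input_backward(c(2, 3), c(0.5, 2), c(0, 0))
  expect_equal(bw$grad_x, c(0, 0))
  expect_equal(bw$grad_weights, c(0, 0))
  bw1 <- weighted_input_backward(c(2, 3), c(1, 1), c(4, 5))
  expect_equal(bw1$grad_x, c(4, 5)) # identity Jacobian at unit weights

  # central-difference oracle on random 8-vectors
  set.seed(9)
  x <- rnorm(8)
  w <- rnorm(8)
  u <- rnorm(8)
  bwr <- weighted_input_backward(x, w, u)
  h <- 1e-6
  num_w <- vapply(1:8, function(i) {
    wp <- w
    wp[i] <- wp[i] + h
    wm <- w
    wm[i] <- wm[i] - h
    sum(u * (weighted_input_forward(x, wp) - weighted_input_forward(x, wm))) / (2 * h)
  }, numeric(1))
  expect_equal(bwr$grad_weights, num_w, tolerance = 1e-6)
})

test_that("convolution matches hand values and the naive-loop reference", {
  # 1x1 unit kernel is the identity (pre-activation)
  x <- matrix(c(-1, 2, 3, -4), 2)
  out <- conv_forward(x, matrix(1), 0, activation = "identity")
  expect_equal(out[, , 1], x)

  # all-ones 5x5 input and kernel, bias 2 -> 25 + 2
  ones <- matrix(1, 5, 5)
  expect_equal(as.vector(conv_forward(ones, ones, 2)), 27)

  set.seed(14)
  for (i in 1:20) {
    h <- sample(5:9, 1)
    w <- sample(5:9, 1)
    ci <- sample(1:3, 1)
    co <- sample(1:3, 1)
    kk <- sample(1:3, 1)
    xx <- array(rnorm(h * w * ci), c(h, w, ci))
    kern <- array(rnorm(kk * kk * ci * co), c(kk, kk, ci, co))
    b <- rnorm(co)
    expect_lt(max(abs(conv_forward(xx, kern, b) - naive_conv(xx, kern, b))), 1e-12)
  }

  expect_error(conv_forward(matrix(1, 3, 3), matrix(1, 5, 5), 0), "larger than input")
})

test_that("max pooling takes blockwise maxima and keeps partial edge blocks", {
  m <- matrix(c(1, 3, 2, 4), 2)
  expect_equal(as.vector(maxpool_forward(m, 2)), 4)
  expect_equal(maxpool_forward(m, 1), m) # 1x1 pool is the identity

  # 3x3 input: ceil mode keeps the trailing row/column as partial blocks
  m3 <- matrix(1:9, 3, 3)
  p <- maxpool_forward(m3, 2)
  expect_equal(dim(p), c(2L, 2L))
  expect_equal(p, matrix(c(5, 6, 8, 9), 2))
})

test_that("pooling gradients route to block maxima only", {
  set.seed(21)
  x <- array(rnorm(5 * 5 * 2 * 2), c(5, 5, 2, 2))
  fw <- geneflight:::pool_fwd_batch(x, 2L)
  dout <- array(rnorm(length(fw$out)), dim(fw$out))
  dx <- geneflight:::pool_bwd_batch(dout, fw)
  # numeric check: d(sum(dout * pooled))/dx
  h <- 1e-6
  idx <- cbind(
    sample(5, 20, TRUE), sample(5, 20, TRUE),
    sample(2, 20, TRUE), sample(2, 20, TRUE)
  )
  for (r in seq_len(nrow(idx))) {
    xp <- x
    xp[idx[r, , drop = FALSE]] <- xp[idx[r, , drop = FALSE]] + h
    xm <- x
    xm[idx[r, , drop = FALSE]] <- xm[idx[r, , drop = FALSE]] - h
    num <- (sum(dout * geneflight:::pool_fwd_batch(xp, 2L)$out) -
      sum(dout * geneflight:::pool_fwd_batch(xm, 2L)$out)) / (2 * h)
    expect_equal(dx[idx[r, , drop = FALSE]], num, tolerance = 1e-5)
  }
})

test_that("softmax output is stable, normalized and shift-invariant", {
  w <- diag(2)
  expect_equal(dense_softmax_forward(c(0, 0), w, c(0, 0)), c(0.5, 0.5))
  expect_equal(dense_softmax_forward(c(7, 7), w, c(0, 0)), c(0.5, 0.5))
  p <- dense_softmax_forward(c(1000, 0), w, c(0, 0))
  expect_false(any(is.nan(p)))
  expect_equal(p[1], 1, tolerance = 1e-12)

  set.seed(3)
  logits <- matrix(rnorm(40, sd = 200), 20, 2)
  probs <- geneflight:::softmax_rows(logits)
  expect_true(all(abs(rowSums(probs) - 1) < 1e-12))
  expect_true(all(probs >= 0 & probs <= 1))

  expect_error(dense_softmax_forward(1:3, w, c(0, 0)), "shape mismatch")
})
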