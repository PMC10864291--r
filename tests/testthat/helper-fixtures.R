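# Small in-code fixtures shared across test files.

# Expression table with the given per-class sizes and iid N(0,1) genes.
make_noise_table <- function(n0, n1, n_genes, seed = 1) {
  set.seed(seed)
  n <- n0 + n1
  expression_table(
    matrix(rnorm(n * n_genes), nrow = n),
    rep(c("normal", "tumor"), c(n0, n1))
  )
}

# Separable planted problem: `k` informative genes shifted by `effect` in
# the tumor class, remaining genes noise; returns table + planted mask.
make_planted <- function(n0, n1, n_genes, k, effect, seed = 1) {
  gen <- generate_expression(synthetic_spec(
    n_class0 = n0, n_class1 = n1, n_genes = n_genes, n_informative = k,
    effect_size = effect, seed = seed
  ))
  list(data = gen$data, planted = gen$truth$informative)
}

# Mann-Whitney U probability that a positive outscores a negative
# (ties count half): the pairwise-comparison AUC oracle.
auc_mann_whitney <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Quadruple-loop reference convolution, deliberately naive.
naive_conv <- function(x, k, b, activation = "relu") {
  d <- dim(x)
  kd <- dim(k)
  oh <- d[1] - kd[1] + 1
  ow <- d[2] - kd[2] + 1
  out <- array(0, c(oh, ow, kd[4]))
  for (f in seq_len(kd[4])) {
    for (oi in seq_len(oh)) {
      for (oj in seq_len(ow)) {
        s <- b[f]
        for (cc in seq_len(kd[3])) {
          for (ki in seq_len(kd[1])) {
            for (kj in seq_len(kd[2])) {
              s <- s + x[oi + ki - 1, oj + kj - 1, cc] * k[ki, kj, cc, f]
            }
          }
        }
        out[oi, oj, f] <- if (activation == "relu") max(s, 0) else s
      }
    }
  }
  out
}

# Full-network gradient check helper: relative L2 discrepancy between the
# analytic gradient and central finite differences, per parameter group.
wcnn_gradcheck <- function(n_genes = 30, B = 3, h = 1e-5, seed = 11,
                           config = wcnn_config(
                             filters = c(2, 3, 3), hidden_units = 4, seed = 7
                           )) {
  set.seed(seed)
  xm <- matrix(rnorm(B * n_genes), B, n_genes)
  y <- rep_len(c(0L, 1L), B)
  model <- geneflight:::wcnn_init(n_genes, config, c("a", "b"))
  p <- model$params
  # fan-in-scaled init gives O(1) activations, but zero-initialized biases
  # would sit exactly on ReLU kinks; nudge them off with small noise
  for (nm in c("b1", "b2", "b3", "dense_b", "out_b")) {
    p[[nm]] <- p[[nm]] + rnorm(length(p[[nm]]), 0, 0.05)
  }
  lg <- geneflight:::wcnn_loss_grad(p, xm, y, model$grid, config)
  loss_at <- function(pp) {
    geneflight:::wcnn_loss_grad(pp, xm, y, model$grid, config)$loss
  }
  rel <- vapply(names(lg$grads), function(nm) {
    ga <- as.vector(lg$grads[[nm]])
    gn <- vapply(seq_along(ga), function(i) {
      pp <- p
      pp[[nm]][i] <- pp[[nm]][i] + h
      lp <- loss_at(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * h
      (lp - loss_at(pp)) / (2 * h)
    }, numeric(1))
    sqrt(sum((ga - gn)^2)) / max(sqrt(sum(ga^2)) + sqrt(sum(gn^2)), 1e-12)
  }, numeric(1))
  rel
}
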