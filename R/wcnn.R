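#' Weighted CNN configuration
#'
#' Architecture and optimizer settings for the weighted convolutional
#' classifier. The layer stack is fixed in shape — learnable per-gene
#' weighting, 5x5 convolution, 2x2 max pool, 5x5 convolution, 2x2 max pool,
#' 1x1 convolution, 1x1 pool, one hidden dense layer, softmax output — and
#' configurable in width. Training is plain mini-batch SGD on mean
#' cross-entropy.
#'
#' @param filters Integer vector of length 3: kernels per convolution layer.
#' @param hidden_units Units of the hidden dense layer.
#' @param learning_rate SGD learning rate.
#' @param epochs Training epochs (0 returns the initialized model).
#' @param batch_size Mini-batch size.
#' @param activation Convolution/hidden nonlinearity, `"relu"` (default) or
#'   `"identity"`.
#' @param pad_to_min Pad the gene grid up to the 13x13 minimum the conv
#'   stack needs when fewer than 169 genes are supplied (default `TRUE`);
#'   with `FALSE` such inputs are a validation error.
#' @param seed Integer seed for initialization and batch shuffling.
#' @return A validated list of class `wcnn_config`.
#' @export
wcnn_config <- function(filters = c(8, 16, 16), hidden_units = 32,
                        learning_rate = 0.01, epochs = 100, batch_size = 16,
                        activation = c("relu", "identity"),
                        pad_to_min = TRUE, seed = 1) {
  activation <- match.arg(activation)
  if (length(filters) != 3L || any(filters < 1)) {
    abort("`filters` must be three positive kernel counts.")
  }
  check_number(hidden_units, "hidden_units", 1, Inf, integer = TRUE)
  check_number(learning_rate, "learning_rate", 0, Inf, open_lower = TRUE)
  check_number(epochs, "epochs", 0, Inf, integer = TRUE)
  check_number(batch_size, "batch_size", 1, Inf, integer = TRUE)
  structure(
    list(
      filters = as.integer(filters), hidden_units = as.integer(hidden_units),
      learning_rate = learning_rate, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), activation = activation,
      pad_to_min = isTRUE(pad_to_min), seed = as.integer(seed)
    ),
    class = "wcnn_config"
  )
}

# Two 5x5 valid convolutions with ceil-mode 2x2 pools need a 13x13 grid:
# 13 -> 9 -> 5 -> 1 -> 1.
WCNN_MIN_SIDE <- 13L

wcnn_grid <- function(n_genes, config) {
  g <- gene_grid(n_genes)
  if (min(g$height, g$width) < WCNN_MIN_SIDE) {
    if (!config$pad_to_min) {
      abort(sprintf(
        paste0(
          "gene count %d gives a %dx%d grid, too small for the ",
          "5x5 conv / 2x2 pool stack; at least %d genes (13x13 grid) are ",
          "needed. Use pad_to_min = TRUE to zero-pad smaller panels."
        ),
        n_genes, g$height, g$width, WCNN_MIN_SIDE^2
      ))
    }
    g <- gene_grid(n_genes, min_side = WCNN_MIN_SIDE)
  }
  g
}

pooled_size <- function(s) ceiling(s / 2)

wcnn_shapes <- function(grid, config) {
  f <- config$filters
  h1 <- grid$height - 4L; w1 <- grid$width - 4L
  p1h <- pooled_size(h1); p1w <- pooled_size(w1)
  h2 <- p1h - 4L; w2 <- p1w - 4L
  if (h2 < 1L || w2 < 1L) {
    abort("grid too small after the first pool for the second 5x5 convolution.")
  }
  p2h <- pooled_size(h2); p2w <- pooled_size(w2)
  list(
    n_feat = p2h * p2w * f[3],
    conv = list(
      c(5L, 5L, 1L, f[1]),
      c(5L, 5L, f[1], f[2]),
      c(1L, 1L, f[2], f[3])
    )
  )
}

wcnn_init <- function(n_genes, config, levels) {
  grid <- wcnn_grid(n_genes, config)
  shp <- wcnn_shapes(grid, config)
  # fan-in-scaled (He) uniform: a fixed-width small-uniform scheme loses the
  # signal through three conv layers (vanishing activations), so each
  # layer's width is scaled to preserve activation variance
  runit <- function(n, fan_in) {
    lim <- sqrt(6 / fan_in)
    runif(n, -lim, lim)
  }
  fans <- vapply(shp$conv, function(d) prod(d[1:3]), numeric(1))
  params <- with_seed(config$seed, {
    list(
      gene_weights = rep(1, n_genes),
      k1 = array(runit(prod(shp$conv[[1]]), fans[1]), dim = shp$conv[[1]]),
      b1 = numeric(config$filters[1]),
      k2 = array(runit(prod(shp$conv[[2]]), fans[2]), dim = shp$conv[[2]]),
      b2 = numeric(config$filters[2]),
      k3 = array(runit(prod(shp$conv[[3]]), fans[3]), dim = shp$conv[[3]]),
      b3 = numeric(config$filters[3]),
      dense_w = matrix(
        runit(shp$n_feat * config$hidden_units, shp$n_feat),
        nrow = shp$n_feat
      ),
      dense_b = numeric(config$hidden_units),
      out_w = matrix(
        runit(config$hidden_units * 2L, config$hidden_units),
        nrow = config$hidden_units
      ),
      out_b = numeric(2L)
    )
  })
  structure(
    list(
      params = params, grid = grid, config = config,
      label_levels = levels, gene_ids = NULL,
      history = tibble(epoch = integer(), loss = numeric(), accuracy = numeric())
    ),
    class = "wcnn_model"
  )
}

# Forward pass over a batch matrix (samples x genes). Returns class
# probabilities and, when `cache = TRUE`, everything backward needs.
wcnn_forward <- function(params, xm, grid, config, cache = FALSE) {
  act <- config$activation
  xw <- sweep(xm, 2, params$gene_weights, `*`)
  a0 <- grid_embed_batch(xw, grid)
  c1 <- conv_fwd_batch(a0, params$k1, params$b1, act)
  p1 <- pool_fwd_batch(c1$out, 2L)
  c2 <- conv_fwd_batch(p1$out, params$k2, params$b2, act)
  p2 <- pool_fwd_batch(c2$out, 2L)
  c3 <- conv_fwd_batch(p2$out, params$k3, params$b3, act)
  p3 <- pool_fwd_batch(c3$out, 1L)
  B <- nrow(xm)
  feat <- t(matrix(p3$out, ncol = B))
  hpre <- sweep(feat %*% params$dense_w, 2, params$dense_b, `+`)
  hid <- if (act == "relu") pmax(hpre, 0) else hpre
  logits <- sweep(hid %*% params$out_w, 2, params$out_b, `+`)
  probs <- softmax_rows(logits)
  if (!cache) {
    return(list(probs = probs))
  }
  list(
    probs = probs, xm = xm, xw = xw, c1 = c1, p1 = p1, c2 = c2, p2 = p2,
    c3 = c3, p3 = p3, feat = feat, hpre = hpre, hid = hid
  )
}

# Mean cross-entropy loss and exact gradients for every parameter group.
wcnn_loss_grad <- function(params, xm, y01, grid, config) {
  fw <- wcnn_forward(params, xm, grid, config, cache = TRUE)
  B <- nrow(xm)
  act <- config$activation
  yhot <- cbind(y01 == 0L, y01 == 1L) * 1
  eps <- 1e-12
  loss <- -mean(log(rowSums(fw$probs * yhot) + eps))

  dlogits <- (fw$probs - yhot) / B
  g_out_w <- crossprod(fw$hid, dlogits)
  g_out_b <- colSums(dlogits)
  dhid <- dlogits %*% t(params$out_w)
  if (act == "relu") dhid <- dhid * (fw$hpre > 0)
  g_dense_w <- crossprod(fw$feat, dhid)
  g_dense_b <- colSums(dhid)
  dfeat <- dhid %*% t(params$dense_w)

  dp3 <- array(t(dfeat), dim = dim(fw$p3$out))
  dc3 <- pool_bwd_batch(dp3, fw$p3)
  bw3 <- conv_bwd_batch(dc3, fw$c3)
  dp2 <- bw3$dx
  dc2 <- pool_bwd_batch(dp2, fw$p2)
  bw2 <- conv_bwd_batch(dc2, fw$c2)
  dp1 <- bw2$dx
  dc1 <- pool_bwd_batch(dp1, fw$p1)
  bw1 <- conv_bwd_batch(dc1, fw$c1)
  dxw <- grid_unembed_batch(bw1$dx, grid)
  g_gene_w <- unname(colSums(dxw * fw$xm))

  list(
    loss = loss, probs = fw$probs,
    grads = list(
      gene_weights = g_gene_w,
      k1 = bw1$dkernels, b1 = bw1$dbiases,
      k2 = bw2$dkernels, b2 = bw2$dbiases,
      k3 = bw3$dkernels, b3 = bw3$dbiases,
      dense_w = g_dense_w, dense_b = g_dense_b,
      out_w = g_out_w, out_b = g_out_b
    )
  )
}

#' Train the weighted CNN classifier
#'
#' Fits the weighted convolutional network on an expression table by
#' mini-batch stochastic gradient descent on mean cross-entropy, with all
#' gradients computed analytically. Initialization draws every weight from
#' `uniform(-0.05, 0.05)` out of the seeded stream except the gene weights,
#' which start at 1 so the weighted stage begins as an identity (a plain
#' CNN) and learns per-gene importance during training. Input is expected
#' (not enforced) to be Z-score normalized.
#'
#' @param df An expression table (see [expression_table()]), at least two
#'   samples per class.
#' @param config A [wcnn_config()].
#' @return A `wcnn_model` with parameters, the gene grid, the config, and a
#'   per-epoch `history` tibble (`epoch`, `loss`, `accuracy` on the
#'   training data after the epoch's updates).
#' @export
wcnn_train <- function(df, config = wcnn_config()) {
  df <- validate_expression_table(df)
  xm <- expression_matrix(df)
  y01 <- label_codes(df)
  if (any(table(y01) < 2L)) abort("need at least 2 samples per class.")
  model <- wcnn_init(ncol(xm), config, levels(df$label))
  model$gene_ids <- gene_ids(df)
  if (config$epochs == 0L) {
    return(model)
  }
  n <- nrow(xm)
  params <- model$params
  history <- vector("list", config$epochs)
  with_seed(derive_seed(config$seed, "wcnn-sgd"), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      starts <- seq(1L, n, by = config$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        lg <- wcnn_loss_grad(params, xm[idx, , drop = FALSE], y01[idx],
          model$grid, config
        )
        for (nm in names(lg$grads)) {
          params[[nm]] <- params[[nm]] - config$learning_rate * lg$grads[[nm]]
        }
        ep_loss <- ep_loss + lg$loss * length(idx)
      }
      fw <- wcnn_forward(params, xm, model$grid, config)
      acc <- mean((fw$probs[, 2] > fw$probs[, 1]) == (y01 == 1L))
      history[[ep]] <- tibble(
        epoch = ep, loss = ep_loss / n, accuracy = acc
      )
    }
  })
  model$params <- params
  model$history <- dplyr::bind_rows(history)
  model
}

#' Predict with a weighted CNN model
#'
#' @param object A `wcnn_model`.
#' @param new_data An expression table whose genes match the model's.
#' @param ... Unused.
#' @return A tibble with `sample_id`, the predicted class (`.pred_class`,
#'   ties broken toward the first level, class 0), and one probability
#'   column per class level.
#' @export
predict.wcnn_model <- function(object, new_data, ...) {
  new_data <- validate_expression_table(new_data)
  if (!identical(gene_ids(new_data), object$gene_ids)) {
    abort("gene identifiers of `new_data` do not match the trained model.")
  }
  xm <- expression_matrix(new_data)
  fw <- wcnn_forward(object$params, xm, object$grid, object$config)
  lv <- object$label_levels
  pred <- ifelse(fw$probs[, 2] > fw$probs[, 1], lv[2], lv[1])
  out <- tibble(
    sample_id = new_data$sample_id,
    .pred_class = factor(pred, levels = lv)
  )
  out[[paste0(".pred_", lv[1])]] <- fw$probs[, 1]
  out[[paste0(".pred_", lv[2])]] <- fw$probs[, 2]
  out
}

#' @export
print.wcnn_model <- function(x, ...) {
  cat(
    "Weighted CNN classifier\n",
    sprintf("  genes: %d on a %dx%d grid (%d padded cells)\n",
      x$grid$n_genes, x$grid$height, x$grid$width, x$grid$pad_count
    ),
    sprintf("  filters: %s, hidden units: %d\n",
      paste(x$config$filters, collapse = "/"), x$config$hidden_units
    ),
    if (nrow(x$history)) {
      sprintf("  trained %d epochs, final loss %.4f, train accuracy %.4f\n",
        max(x$history$epoch), tail(x$history$loss, 1),
        tail(x$history$accuracy, 1)
      )
    } else "  untrained (initialized only)\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy methods for the weighted CNN
#'
#' `tidy()` returns the learned per-gene importance weights; `glance()` a
#' one-row model summary.
#'
#' @param x A `wcnn_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy wcnn_model
#' @export
tidy.wcnn_model <- function(x, ...) {
  tibble(gene_id = x$gene_ids, gene_weight = x$params$gene_weights)
}

#' @rdname tidy.wcnn_model
#' @method glance wcnn_model
#' @export
glance.wcnn_model <- function(x, ...) {
  tibble(
    n_genes = x$grid$n_genes,
    n_parameters = sum(vapply(x$params, length, integer(1))),
    epochs = nrow(x$history),
    final_loss = if (nrow(x$history)) tail(x$history$loss, 1) else NA_real_,
    train_accuracy = if (nrow(x$history)) tail(x$history$accuracy, 1) else NA_real_
  )
}

#' Plot the training-loss history of a weighted CNN
#'
#' @param object A trained `wcnn_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wcnn_model
#' @export
autoplot.wcnn_model <- function(object, ...) {
  if (!nrow(object$history)) abort("model has no training history.")
  d <- tidyr::pivot_longer(object$history, c("loss", "accuracy"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Weighted CNN training history")
}

#' Serialize a weighted CNN model to JSON
#'
#' Writes configuration, grid, label levels and all parameter arrays (with
#' shapes, full precision) to a single JSON file; [read_wcnn()] restores a
#' bit-exact model.
#'
#' @param model A `wcnn_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_wcnn <- function(model, path) {
  # doubles as %.17g strings: JSON number formatting loses the last bits
  pack <- function(p) {
    list(dim = dim(p) %||% length(p), data = sprintf("%.17g", as.vector(p)))
  }
  obj <- list(
    config = unclass(model$config),
    grid = unclass(model$grid),
    label_levels = model$label_levels,
    gene_ids = model$gene_ids,
    params = lapply(model$params, pack),
    history = model$history
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_wcnn
#' @export
read_wcnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpack <- function(p) {
    v <- as.numeric(p$data)
    if (length(p$dim) > 1L) array(v, dim = p$dim) else v
  }
  params <- lapply(obj$params, unpack)
  params$dense_w <- matrix(params$dense_w, nrow = obj$params$dense_w$dim[1])
  params$out_w <- matrix(params$out_w, nrow = obj$params$out_w$dim[1])
  cfg <- obj$config
  config <- wcnn_config(
    filters = cfg$filters, hidden_units = cfg$hidden_units,
    learning_rate = cfg$learning_rate, epochs = cfg$epochs,
    batch_size = cfg$batch_size, activation = cfg$activation,
    pad_to_min = cfg$pad_to_min, seed = cfg$seed
  )
  grid <- structure(
    list(
      height = as.integer(obj$grid$height), width = as.integer(obj$grid$width),
      pad_count = as.integer(obj$grid$pad_count),
      n_genes = as.integer(obj$grid$n_genes), perm = as.integer(obj$grid$perm)
    ),
    class = "gene_grid"
  )
  structure(
    list(
      params = params, grid = grid, config = config,
      label_levels = obj$label_levels, gene_ids = obj$gene_ids,
      history = as_tibble(obj$history)
    ),
    class = "wcnn_model"
  )
}
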