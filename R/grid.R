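#' Embed a gene vector on a 2D grid
#'
#' Convolutional layers need a spatial arrangement, so the per-sample gene
#' vector is laid out row-major on a near-square grid: `height =
#' ceiling(sqrt(G))`, `width = ceiling(G / height)`, with trailing cells
#' zero-padded. `min_side` can force a larger grid (the fixed
#' conv/pool stack needs at least 13 x 13, i.e. 169 cells).
#'
#' @param n_genes Number of genes `G`.
#' @param min_side Optional minimum for both grid sides.
#' @return A list of class `gene_grid` with `height`, `width`, `pad_count`,
#'   `n_genes`, and `perm`, the column-major-to-row-major index permutation
#'   used internally.
#' @examples
#' gene_grid(5) # 3 x 2, one padded cell
#' @export
gene_grid <- function(n_genes, min_side = NULL) {
  check_number(n_genes, "n_genes", 1, Inf, integer = TRUE)
  h <- ceiling(sqrt(n_genes))
  w <- ceiling(n_genes / h)
  if (!is.null(min_side)) {
    h <- max(h, min_side)
    w <- max(w, min_side)
  }
  # grid cell (r, c) holds gene (r-1)*w + c; perm maps R's column-major
  # cell order to that row-major gene index (0 = padded cell)
  r <- ((seq_len(h * w) - 1L) %% h) + 1L
  cc <- ((seq_len(h * w) - 1L) %/% h) + 1L
  gene <- (r - 1L) * w + cc
  gene[gene > n_genes] <- 0L
  structure(
    list(height = h, width = w, pad_count = h * w - n_genes,
         n_genes = as.integer(n_genes), perm = gene),
    class = "gene_grid"
  )
}

#' @rdname gene_grid
#' @param x Numeric vector of length `n_genes`.
#' @param grid A `gene_grid`.
#' @export
grid_embed <- function(x, grid) {
  if (length(x) != grid$n_genes) {
    abort(sprintf(
      "vector length %d does not match grid gene count %d.",
      length(x), grid$n_genes
    ))
  }
  cells <- numeric(grid$height * grid$width)
  cells[grid$perm > 0L] <- x[grid$perm[grid$perm > 0L]]
  matrix(cells, nrow = grid$height)
}

#' @rdname gene_grid
#' @param m A `height x width` matrix produced by [grid_embed()].
#' @export
grid_unembed <- function(m, grid) {
  if (!all(dim(m) == c(grid$height, grid$width))) {
    abort("matrix dimensions do not match the grid.")
  }
  x <- numeric(grid$n_genes)
  keep <- grid$perm > 0L
  x[grid$perm[keep]] <- m[keep]
  x
}

# Batch version: rows of `xm` (samples x genes) to array h x w x 1 x B.
grid_embed_batch <- function(xm, grid) {
  B <- nrow(xm)
  cells <- matrix(0, nrow = grid$height * grid$width, ncol = B)
  keep <- grid$perm > 0L
  cells[keep, ] <- t(xm[, grid$perm[keep], drop = FALSE])
  array(cells, dim = c(grid$height, grid$width, 1L, B))
}

grid_unembed_batch <- function(arr, grid) {
  B <- dim(arr)[4]
  cells <- matrix(arr, nrow = grid$height * grid$width, ncol = B)
  keep <- grid$perm > 0L
  out <- matrix(0, nrow = B, ncol = grid$n_genes)
  out[, grid$perm[keep]] <- t(cells[keep, , drop = FALSE])
  out
}
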