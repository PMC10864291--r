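#' Specification of a synthetic two-class expression dataset
#'
#' Describes a microarray-like generative world: two unbalanced classes
#' (defaults 70 "normal" and 86 "tumor" samples, the class sizes of the
#' Kent Ridge lung adenocarcinoma set), thousands of genes of which a small
#' planted subset carries a class-conditional mean shift and the rest are
#' pure noise. Informative genes are shifted by `effect_size * noise_sd` in
#' the tumor class and can be equicorrelated within the planted block via a
#' Gaussian copula (one shared factor).
#'
#' @param n_class0,n_class1 Samples per class (class 0 = "normal",
#'   class 1 = "tumor"); defaults 70 and 86.
#' @param n_genes Total gene count; default 2000 (use 7129 for the
#'   full-scale preset).
#' @param n_informative Number of planted informative genes; default 50.
#' @param effect_size Class-1 mean shift in units of `noise_sd`; default 1.
#' @param noise_sd Within-class standard deviation; default 1.
#' @param block_corr Pairwise correlation within the planted block,
#'   in `[0, 1)`; default 0.
#' @param seed Integer seed.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_class0 = 70, n_class1 = 86, n_genes = 2000,
                           n_informative = 50, effect_size = 1,
                           noise_sd = 1, block_corr = 0, seed = 1) {
  check_number(n_class0, "n_class0", 1, Inf, integer = TRUE)
  check_number(n_class1, "n_class1", 1, Inf, integer = TRUE)
  check_number(n_genes, "n_genes", 1, Inf, integer = TRUE)
  check_number(n_informative, "n_informative", 1, n_genes, integer = TRUE)
  check_number(effect_size, "effect_size")
  check_number(noise_sd, "noise_sd", 0, Inf, open_lower = TRUE)
  check_number(block_corr, "block_corr", 0, 1, open_upper = TRUE)
  structure(
    list(
      n_class0 = as.integer(n_class0), n_class1 = as.integer(n_class1),
      n_genes = as.integer(n_genes), n_informative = as.integer(n_informative),
      effect_size = as.numeric(effect_size), noise_sd = as.numeric(noise_sd),
      block_corr = as.numeric(block_corr), seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic two-class expression dataset
#'
#' Draws the dataset described by a [synthetic_spec()]: non-informative
#' genes are `N(0, noise_sd)` identically in both classes; the planted
#' informative genes get a `+effect_size * noise_sd` mean shift in class 1
#' ("tumor") and, when `block_corr > 0`, unit-variance equicorrelated noise
#' built from one shared Gaussian factor
#' (`sqrt(rho) * z_common + sqrt(1-rho) * z_gene`). The baseline level is 0
#' because downstream Z-scoring makes any constant offset irrelevant.
#' Deterministic given `spec$seed`; the planted genes occupy the first
#' `n_informative` positions before a seeded column shuffle.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `data` (an expression table) and `truth`, a tibble
#'   with `gene_id` and logical `informative` marking the planted genes.
#' @export
generate_expression <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  n <- spec$n_class0 + spec$n_class1
  G <- spec$n_genes
  k <- spec$n_informative
  with_seed(spec$seed, {
    labels <- rep(c("normal", "tumor"), c(spec$n_class0, spec$n_class1))
    m <- matrix(rnorm(n * G, 0, spec$noise_sd), nrow = n)
    if (spec$block_corr > 0) {
      rho <- spec$block_corr
      common <- rnorm(n)
      z <- sqrt(rho) * common + sqrt(1 - rho) * matrix(rnorm(n * k), nrow = n)
      m[, seq_len(k)] <- spec$noise_sd * z
    }
    shift <- spec$effect_size * spec$noise_sd
    m[labels == "tumor", seq_len(k)] <- m[labels == "tumor", seq_len(k)] + shift
    informative <- c(rep(TRUE, k), rep(FALSE, G - k))
    ord <- sample.int(G)
    m <- m[, ord, drop = FALSE]
    informative <- informative[ord]
    gene_ids <- paste0("g", sprintf(paste0("%0", nchar(G), "d"), seq_len(G)))
    df <- expression_table(m, labels, gene_ids = gene_ids)
    list(
      data = df,
      truth = tibble(gene_id = gene_ids, informative = informative)
    )
  })
}

#' Write a synthetic dataset to disk
#'
#' Writes the expression matrix and labels in the format [read_expression()]
#' consumes, the planted-gene truth as one-column text, and a JSON manifest
#' holding the generative spec, seed and file checksums.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the paths written.
#' @export
simulate_to_files <- function(spec, dir) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_expression(spec)
  matrix_path <- file.path(dir, "expression.tsv")
  label_path <- file.path(dir, "labels.txt")
  truth_path <- file.path(dir, "informative_genes.txt")
  manifest_path <- file.path(dir, "manifest.json")
  write_expression(gen$data, matrix_path, label_path)
  writeLines(gen$truth$gene_id[gen$truth$informative], truth_path)
  files <- c(matrix = matrix_path, labels = label_path, truth = truth_path)
  jsonlite::write_json(
    list(
      spec = unclass(spec),
      files = as.list(files),
      md5 = as.list(setNames(unname(tools::md5sum(files)), names(files)))
    ),
    manifest_path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(c(files, manifest = manifest_path))
}
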