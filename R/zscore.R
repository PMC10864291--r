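#' Fit per-gene Z-score statistics
#'
#' Computes, for every gene, the mean and standard deviation over samples
#' used by the Z-score transform `v' = (v - mean) / sd`. The default
#' standard deviation is the population form (divisor `n`); `divisor =
#' "n-1"` switches to the sample form. Fit these on training data only and
#' apply them to both partitions so no test-set information leaks into the
#' scaling.
#'
#' @param df An expression table (see [expression_table()]).
#' @param divisor `"n"` (population sd, default) or `"n-1"` (sample sd).
#' @return A tibble with columns `gene_id`, `mean`, `sd`.
#' @examples
#' d <- expression_table(matrix(c(1, 2, 3), ncol = 1), c("a", "b", "a"))
#' zscore_fit(d) # mean 2, population sd sqrt(2/3)
#' @export
zscore_fit <- function(df, divisor = c("n", "n-1")) {
  df <- validate_expression_table(df)
  divisor <- match.arg(divisor)
  m <- expression_matrix(df)
  n <- nrow(m)
  if (n < 2L) abort("Z-score statistics need at least 2 samples.")
  mu <- colMeans(m)
  ss <- colSums(sweep(m, 2, mu)^2)
  s <- sqrt(ss / if (divisor == "n") n else n - 1L)
  tibble(gene_id = colnames(m), mean = unname(mu), sd = unname(s))
}

#' Apply per-gene Z-score statistics
#'
#' Transforms every expression cell by `(v - mean) / sd` using previously
#' fitted statistics. Genes with zero standard deviation (constant in the
#' fitting data) map to 0 everywhere: they carry no information and would
#' otherwise divide by zero.
#'
#' @param df An expression table whose genes match `stats$gene_id` in order.
#' @param stats A statistics tibble from [zscore_fit()].
#' @return The transformed expression table (same shape).
#' @export
zscore_apply <- function(df, stats) {
  df <- validate_expression_table(df)
  g <- gene_ids(df)
  if (!identical(as.character(stats$gene_id), g)) {
    abort("gene identifiers of `stats` do not match the table (same order required).")
  }
  m <- expression_matrix(df)
  sd_safe <- ifelse(stats$sd > 0, stats$sd, 1)
  z <- sweep(sweep(m, 2, stats$mean), 2, sd_safe, `/`)
  z[, stats$sd == 0] <- 0
  df[g] <- as_tibble(z, .name_repair = "minimal")
  df
}

#' @rdname zscore_fit
#' @param path Output/input path for a tab-separated `gene_id`/`mean`/`sd`
#'   table.
#' @param stats A statistics tibble from [zscore_fit()].
#' @export
write_zscore_stats <- function(stats, path) {
  readr::write_tsv(stats, path)
  invisible(path)
}

#' @rdname zscore_fit
#' @export
read_zscore_stats <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    mean = readr::col_double(),
    sd = readr::col_double()
  ))
}
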