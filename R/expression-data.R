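#' Build an expression table from a matrix and labels
#'
#' The canonical container throughout the package is an *expression table*:
#' a tibble with one row per sample, a `sample_id` character column, a
#' two-level factor column `label`, and one numeric column per gene. The
#' first factor level is the class coded 0 (lexicographically smaller label)
#' and the second level the class coded 1, so label coding is deterministic
#' without configuration.
#'
#' @param values Numeric matrix, samples in rows, genes in columns.
#' @param labels Vector with exactly two distinct values, one per sample.
#' @param gene_ids Character vector of unique gene identifiers
#'   (default `g1...gG` or the matrix column names).
#' @param sample_ids Character vector of unique sample identifiers
#'   (default `s1...sN` or the matrix row names).
#' @return A tibble with columns `sample_id`, `label`, then the genes.
#' @examples
#' m <- matrix(rnorm(12), nrow = 3)
#' expression_table(m, c("tumor", "normal", "tumor"))
#' @export
expression_table <- function(values, labels, gene_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- gene_ids %||% colnames(values) %||% paste0("g", seq_len(ncol(values)))
  sample_ids <- sample_ids %||% rownames(values) %||% paste0("s", seq_len(nrow(values)))
  if (length(gene_ids) != ncol(values)) {
    abort("`gene_ids` length must equal the number of genes (matrix columns).")
  }
  if (length(sample_ids) != nrow(values)) {
    abort("`sample_ids` length must equal the number of samples (matrix rows).")
  }
  if (length(labels) != nrow(values)) {
    abort(sprintf(
      "label length %d does not match sample count %d.",
      length(labels), nrow(values)
    ))
  }
  df <- tibble(
    sample_id = as.character(sample_ids),
    label = encode_labels(labels)
  )
  mat <- as_tibble(values, .name_repair = "minimal")
  names(mat) <- as.character(gene_ids)
  out <- dplyr::bind_cols(df, mat)
  validate_expression_table(out)
}

# Map a two-valued vector to a factor whose first level is the
# lexicographically smaller value (class code 0).
encode_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2L) {
    abort(sprintf(
      "labels must contain exactly 2 distinct classes, found %d (%s).",
      length(lv), paste(head(lv, 5), collapse = ", ")
    ))
  }
  factor(as.character(labels), levels = lv)
}

#' Validate an expression table
#'
#' Checks the container invariants: `sample_id` and `label` columns present,
#' unique sample and gene identifiers, numeric gene columns, and a two-level
#' label factor.
#'
#' @param df An expression table.
#' @return `df`, invisibly usable in a pipe.
#' @export
validate_expression_table <- function(df) {
  if (!is.data.frame(df)) abort("expected a data frame.")
  if (!all(c("sample_id", "label") %in% names(df))) {
    abort("expression table needs `sample_id` and `label` columns.")
  }
  if (anyDuplicated(df$sample_id)) abort("duplicated sample_id values.")
  genes <- gene_ids(df)
  if (anyDuplicated(genes)) abort("duplicated gene identifiers.")
  if (!is.factor(df$label) || nlevels(df$label) != 2L) {
    df$label <- encode_labels(df$label)
  }
  bad <- genes[!vapply(df[genes], is.numeric, logical(1))]
  if (length(bad)) {
    abort(sprintf("non-numeric gene columns: %s.", paste(head(bad, 5), collapse = ", ")))
  }
  as_tibble(df)
}

#' @rdname expression_table
#' @param df An expression table.
#' @export
gene_ids <- function(df) setdiff(names(df), c("sample_id", "label"))

#' @rdname expression_table
#' @export
expression_matrix <- function(df) {
  g <- gene_ids(df)
  m <- as.matrix(df[g])
  rownames(m) <- df$sample_id
  m
}

#' @rdname expression_table
#' @export
label_codes <- function(df) as.integer(df$label) - 1L

infer_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# Minimal strict delimited-matrix reader: header line, first column =
# identifiers, every cell numeric. Errors name the offending line or cell,
# which readr's permissive recycling would silently paper over.
read_delim_matrix <- function(path, delim) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) abort(sprintf("'%s': need a header line and at least one data row.", path))
  cells <- strsplit(lines, delim, fixed = TRUE)
  header <- cells[[1]]
  width <- length(header)
  for (i in seq_along(cells)[-1]) {
    if (length(cells[[i]]) != width) {
      abort(sprintf(
        "'%s' line %d: expected %d fields, found %d (ragged row).",
        path, i, width, length(cells[[i]])
      ))
    }
  }
  ids <- vapply(cells[-1], `[[`, character(1), 1L)
  vals <- matrix(NA_real_, nrow = length(ids), ncol = width - 1L)
  for (i in seq_along(ids)) {
    row <- suppressWarnings(as.numeric(cells[[i + 1L]][-1L]))
    bad <- which(is.na(row))
    if (length(bad)) {
      abort(sprintf(
        "'%s' line %d, column '%s': non-numeric value '%s'.",
        path, i + 1L, header[bad[1] + 1L], cells[[i + 1L]][bad[1] + 1L]
      ))
    }
    vals[i, ] <- row
  }
  list(row_ids = ids, col_ids = header[-1L], values = vals)
}

#' Read an expression matrix and labels from delimited text
#'
#' Reads a TSV/CSV matrix with a header row and identifiers in the first
#' column. With `orientation = "genes_as_rows"` the file holds genes in rows
#' and samples in columns and is transposed on read; with
#' `"samples_as_rows"` rows are samples. Labels come either from a one-value-
#' per-line text file or, when samples are rows, from a named column of the
#' matrix file.
#'
#' @param path Path to the delimited matrix.
#' @param orientation `"genes_as_rows"` or `"samples_as_rows"`.
#' @param labels Path to a one-column label file, or (when samples are rows)
#'   the name of the label column inside the matrix file.
#' @param delim Field delimiter; inferred from the extension (`.csv` comma,
#'   otherwise tab) when `NULL`.
#' @return An expression table (see [expression_table()]).
#' @export
read_expression <- function(path,
                            orientation = c("genes_as_rows", "samples_as_rows"),
                            labels,
                            delim = NULL) {
  orientation <- match.arg(orientation)
  delim <- infer_delim(path, delim)
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist.", path))

  label_col <- NULL
  if (length(labels) == 1L && !file.exists(labels)) {
    if (orientation != "samples_as_rows") {
      abort("a label column name is only valid with samples_as_rows; otherwise pass a label file path.")
    }
    label_col <- labels
  }

  if (!is.null(label_col)) {
    raw <- readLines(path)
    raw <- raw[nzchar(raw)]
    header <- strsplit(raw[1], delim, fixed = TRUE)[[1]]
    j <- match(label_col, header)
    if (is.na(j)) abort(sprintf("label column '%s' not found in '%s'.", label_col, path))
    cells <- strsplit(raw, delim, fixed = TRUE)
    lab <- vapply(cells[-1], `[[`, character(1), j)
    stripped <- vapply(cells, function(r) paste(r[-j], collapse = delim), character(1))
    tmp <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp))
    writeLines(stripped, tmp)
    parsed <- read_delim_matrix(tmp, delim)
    return(expression_table(parsed$values, lab,
      gene_ids = parsed$col_ids, sample_ids = parsed$row_ids
    ))
  }

  parsed <- read_delim_matrix(path, delim)
  lab <- trimws(readLines(labels))
  lab <- lab[nzchar(lab)]
  if (orientation == "genes_as_rows") {
    values <- t(parsed$values)
    g_ids <- parsed$row_ids
    s_ids <- parsed$col_ids
  } else {
    values <- parsed$values
    g_ids <- parsed$col_ids
    s_ids <- parsed$row_ids
  }
  if (length(lab) != nrow(values)) {
    abort(sprintf(
      "label length %d does not match sample count %d.",
      length(lab), nrow(values)
    ))
  }
  expression_table(values, lab, gene_ids = g_ids, sample_ids = s_ids)
}

#' Write an expression table to delimited text
#'
#' Writes the matrix with samples in rows (identifiers in the first column,
#' header row) and the labels to a separate one-per-line file, the format
#' [read_expression()] reads back.
#'
#' @param df An expression table.
#' @param path Output path for the matrix.
#' @param label_path Output path for the labels (default: `path` with a
#'   `.labels.txt` suffix).
#' @param delim Field delimiter; inferred from the extension when `NULL`.
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_expression <- function(df, path, label_path = NULL, delim = NULL) {
  df <- validate_expression_table(df)
  delim <- infer_delim(path, delim)
  label_path <- label_path %||% paste0(sub("\\.[^.]+$", "", path), ".labels.txt")
  m <- expression_matrix(df)
  header <- paste(c("sample_id", colnames(m)), collapse = delim)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
      collapse = delim
    )
  }, character(1))
  writeLines(c(header, body), path)
  writeLines(as.character(df$label), label_path)
  invisible(c(path, label_path))
}

#' Stratified train/test split
#'
#' Splits an expression table into train and test partitions per class:
#' each class contributes `floor(train_fraction * class size)` samples to
#' the training set and the remainder to the test set, so the 70/30 protocol
#' on class sizes 86/70 yields train sizes 60/49 and test sizes 26/21.
#' Deterministic given `seed`.
#'
#' @param df An expression table.
#' @param train_fraction Fraction of each class assigned to training, in
#'   `(0, 1]`.
#' @param seed Integer seed.
#' @return A list with elements `train` and `test`, both expression tables.
#' @export
stratified_split <- function(df, train_fraction = 0.7, seed = 1) {
  df <- validate_expression_table(df)
  check_number(train_fraction, "train_fraction", 0, 1, open_lower = TRUE)
  idx_train <- with_seed(seed, {
    unlist(lapply(levels(df$label), function(lv) {
      idx <- which(df$label == lv)
      n_train <- floor(train_fraction * length(idx))
      sort(sample(idx, n_train))
    }), use.names = FALSE)
  })
  idx_train <- sort(idx_train)
  list(
    train = df[idx_train, , drop = FALSE],
    test = df[setdiff(seq_len(nrow(df)), idx_train), , drop = FALSE]
  )
}

#' Stratified k-fold partition
#'
#' Assigns every sample to one of `k` folds so that, within each class, fold
#' sizes differ by at most one. Class sizes 86/70 at `k = 5` give per-class
#' fold sizes 18,17,17,17,17 and 14,14,14,14,14. Deterministic given `seed`.
#'
#' @param df An expression table.
#' @param k Number of folds (each class must have at least `k` samples).
#' @param seed Integer seed.
#' @return A tibble with columns `sample_id`, `label`, `fold`
#'   (integer in `1...k`).
#' @export
stratified_kfold <- function(df, k = 5, seed = 1) {
  df <- validate_expression_table(df)
  check_number(k, "k", 2, Inf, integer = TRUE)
  k <- as.integer(k)
  tab <- table(df$label)
  if (any(tab < k)) {
    abort(sprintf(
      "every class needs >= k samples for %d folds (class sizes: %s).",
      k, paste(tab, collapse = ", ")
    ))
  }
  fold <- integer(nrow(df))
  with_seed(seed, {
    for (lv in levels(df$label)) {
      idx <- which(df$label == lv)
      shuffled <- sample(idx)
      fold[shuffled] <- rep_len(seq_len(k), length(idx))
    }
  })
  tibble(sample_id = df$sample_id, label = df$label, fold = fold)
}
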