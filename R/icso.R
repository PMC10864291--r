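#' Cuckoo search parameters
#'
#' Bundles and validates the configuration of the improved cuckoo search
#' (ICSO): population size, abandonment probability, the geometric step-size
#' schedule endpoints, iteration budget, Levy tail exponent, the threshold
#' that binarizes continuous nest positions into gene masks, and the seed.
#'
#' @param n_nests Number of nests (candidate gene subsets), >= 2.
#' @param p_a Fraction of worst nests abandoned and re-seeded per iteration,
#'   in `[0, 1]`.
#' @param a_max,a_min Step-size schedule endpoints, `0 < a_min <= a_max`.
#' @param T Total iterations, >= 0 (0 keeps the random initial population).
#' @param levy_lambda Levy tail exponent in `(1, 3)`.
#' @param binarize_threshold Positions at or above this select the gene;
#'   in `(0, 1)`.
#' @param seed Integer seed making the whole search reproducible.
#' @return A validated list of class `cs_params`.
#' @export
cs_params <- function(n_nests = 25, p_a = 0.25, a_max = 1, a_min = 0.01,
                      T = 100, levy_lambda = 2.5, binarize_threshold = 0.5,
                      seed = 1) {
  check_number(n_nests, "n_nests", 2, Inf, integer = TRUE)
  check_number(p_a, "p_a", 0, 1)
  check_number(a_max, "a_max", 0, Inf, open_lower = TRUE)
  check_number(a_min, "a_min", 0, a_max, open_lower = TRUE)
  check_number(T, "T", 0, Inf, integer = TRUE)
  check_number(levy_lambda, "levy_lambda", 1, 3, open_lower = TRUE, open_upper = TRUE)
  check_number(binarize_threshold, "binarize_threshold", 0, 1,
    open_lower = TRUE, open_upper = TRUE
  )
  structure(
    list(
      n_nests = as.integer(n_nests), p_a = p_a, a_max = a_max, a_min = a_min,
      T = as.integer(T), levy_lambda = levy_lambda,
      binarize_threshold = binarize_threshold, seed = as.integer(seed)
    ),
    class = "cs_params"
  )
}

position_to_mask <- function(position, threshold) {
  as.integer(position >= threshold)
}

#' Propose a new nest position by a Levy flight
#'
#' Perturbs a position in the unit cube by `alpha_t * levy_step()`
#' (entrywise product of the step size draw and the Levy vector) and clips
#' the result back into `[0, 1]`. The gene mask is re-derived by
#' thresholding.
#'
#' @param position Numeric vector in `[0,1]` per entry.
#' @param t Current iteration (enters the step-size schedule).
#' @param params A [cs_params()] object.
#' @return A list with `position` (clipped) and `mask` (0/1 integer vector).
#' @export
propose_nest <- function(position, t, params) {
  alpha <- adaptive_step_size(t, params)
  step <- levy_step(length(position), params$levy_lambda)
  pos <- pmin(1, pmax(0, position + alpha * step))
  list(position = pos, mask = position_to_mask(pos, params$binarize_threshold))
}

#' Nearest-centroid fitness evaluator
#'
#' The default wrapper-fitness classifier: class centroids on the selected
#' genes of the training partition, validation samples assigned to the
#' nearest centroid (Euclidean), ties to class 0. Deterministic, has no
#' hyperparameters, and costs O(samples x genes), so it is cheap enough to
#' sit inside the search loop.
#'
#' @param train_x,val_x Numeric matrices (samples x selected genes).
#' @param train_y,val_y Integer class codes in `{0, 1}`.
#' @return Validation accuracy in `[0, 1]`.
#' @export
nearest_centroid_evaluator <- function(train_x, train_y, val_x, val_y) {
  c0 <- colMeans(train_x[train_y == 0L, , drop = FALSE])
  c1 <- colMeans(train_x[train_y == 1L, , drop = FALSE])
  d0 <- colSums((t(val_x) - c0)^2)
  d1 <- colSums((t(val_x) - c1)^2)
  pred <- as.integer(d1 < d0)
  mean(pred == val_y)
}

#' Fitness of a gene mask
#'
#' Classification accuracy of `evaluator` trained on the masked training
#' genes and scored on the masked validation genes — the wrapper objective
#' of the gene-selection search. The empty mask is defined to have fitness
#' 0 so it can never beat any informative subset.
#'
#' @param mask 0/1 (or logical) vector over genes.
#' @param train,val Expression tables sharing gene order.
#' @param evaluator A function `(train_x, train_y, val_x, val_y) -> accuracy`;
#'   default [nearest_centroid_evaluator()].
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_fitness <- function(mask, train, val,
                             evaluator = nearest_centroid_evaluator) {
  mask <- as.integer(as.logical(mask))
  if (!any(mask == 1L)) return(0)
  if (!identical(gene_ids(train), gene_ids(val))) {
    abort("train and val must share gene identifiers in the same order.")
  }
  keep <- which(mask == 1L)
  evaluator(
    expression_matrix(train)[, keep, drop = FALSE], label_codes(train),
    expression_matrix(val)[, keep, drop = FALSE], label_codes(val)
  )
}

# TRUE when (f1, mask1) is strictly preferable to (f2, mask2): higher
# fitness, or equal fitness with fewer selected genes (selection is meant
# to shrink the panel, so ties go to the smaller subset).
mask_beats <- function(f1, n1, f2, n2) {
  f1 > f2 || (f1 == f2 && n1 < n2)
}

#' Improved cuckoo search gene selection
#'
#' Runs the improved Levy-flight cuckoo search over gene-mask space.
#' Each nest holds a continuous position in `[0,1]^G` thresholded into a
#' gene mask whose fitness is validation accuracy. Per iteration: one
#' randomly picked cuckoo proposes a new solution by a Levy flight with the
#' geometrically decaying step size; it replaces a randomly chosen nest if
#' strictly fitter (ties to fewer genes); then the worst `ceiling(p_a *
#' n_nests)` nests are abandoned and re-seeded uniformly; the global best is
#' always retained (elitism), so the recorded best-fitness trace is
#' non-decreasing. Fully deterministic given `params$seed`.
#'
#' @param train,val Expression tables sharing gene order; `val` supplies the
#'   accuracy used as fitness.
#' @param params A [cs_params()] object.
#' @param evaluator Fitness classifier, see [evaluate_fitness()].
#' @return An object of class `icso_result`: `best_mask`, `best_fitness`,
#'   `fitness_trace` (length `max(T, 1)`; with `T = 0` the single entry is
#'   the post-initialization best), `selected_gene_ids`, `params`.
#' @export
icso_select <- function(train, val, params = cs_params(),
                        evaluator = nearest_centroid_evaluator) {
  train <- validate_expression_table(train)
  val <- validate_expression_table(val)
  genes <- gene_ids(train)
  G <- length(genes)
  N <- params$n_nests

  res <- with_seed(params$seed, {
    positions <- matrix(runif(N * G), nrow = N)
    masks <- t(apply(positions, 1, position_to_mask, params$binarize_threshold))
    if (G == 1L) masks <- matrix(masks, ncol = 1L)
    fitness <- vapply(
      seq_len(N),
      function(i) evaluate_fitness(masks[i, ], train, val, evaluator),
      numeric(1)
    )
    n_sel <- rowSums(masks)

    best_i <- order(-fitness, n_sel)[1]
    best <- list(
      mask = masks[best_i, ], fitness = fitness[best_i], n = n_sel[best_i]
    )
    trace <- numeric(max(params$T, 1L))
    if (params$T == 0L) trace[1] <- best$fitness

    n_abandon <- ceiling(params$p_a * N)
    for (t in seq_len(params$T)) {
      # one cuckoo performs a Levy flight from a random nest
      i <- sample.int(N, 1)
      prop <- propose_nest(positions[i, ], t, params)
      f_new <- evaluate_fitness(prop$mask, train, val, evaluator)
      n_new <- sum(prop$mask)
      j <- sample.int(N, 1)
      if (mask_beats(f_new, n_new, fitness[j], n_sel[j])) {
        positions[j, ] <- prop$position
        masks[j, ] <- prop$mask
        fitness[j] <- f_new
        n_sel[j] <- n_new
      }
      if (mask_beats(f_new, n_new, best$fitness, best$n)) {
        best <- list(mask = prop$mask, fitness = f_new, n = n_new)
      }

      # a fraction p_a of the worst nests is deserted and rebuilt
      if (n_abandon > 0L) {
        worst <- order(fitness, -n_sel)[seq_len(n_abandon)]
        for (w in worst) {
          positions[w, ] <- runif(G)
          masks[w, ] <- position_to_mask(positions[w, ], params$binarize_threshold)
          fitness[w] <- evaluate_fitness(masks[w, ], train, val, evaluator)
          n_sel[w] <- sum(masks[w, ])
          if (mask_beats(fitness[w], n_sel[w], best$fitness, best$n)) {
            best <- list(mask = masks[w, ], fitness = fitness[w], n = n_sel[w])
          }
        }
      }
      trace[t] <- best$fitness
    }
    list(best = best, trace = trace)
  })

  structure(
    list(
      best_mask = as.integer(res$best$mask),
      best_fitness = res$best$fitness,
      fitness_trace = res$trace,
      selected_gene_ids = genes[res$best$mask == 1L],
      gene_ids = genes,
      params = params
    ),
    class = "icso_result"
  )
}

#' Exhaustive best mask (test oracle)
#'
#' Enumerates every non-empty gene mask and returns the fitness-maximal one,
#' breaking ties first by fewer selected genes and then by the
#' lexicographically smallest mask vector. Guarded to at most 20 genes.
#'
#' @inheritParams icso_select
#' @return A list with `mask` (0/1 integer vector) and `fitness`.
#' @export
exhaustive_best_mask <- function(train, val,
                                 evaluator = nearest_centroid_evaluator) {
  G <- length(gene_ids(train))
  if (G > 20L) abort("exhaustive_best_mask is limited to G <= 20 genes.")
  best <- NULL
  for (code in seq_len(2^G - 1L)) {
    mask <- as.integer(bitwAnd(bitwShiftR(code, seq_len(G) - 1L), 1L))
    f <- evaluate_fitness(mask, train, val, evaluator)
    n <- sum(mask)
    if (is.null(best) ||
      f > best$fitness ||
      (f == best$fitness && n < best$n) ||
      (f == best$fitness && n == best$n &&
        paste(mask, collapse = "") < paste(best$mask, collapse = ""))) {
      best <- list(mask = mask, fitness = f, n = n)
    }
  }
  best[c("mask", "fitness")]
}

#' @export
print.icso_result <- function(x, ...) {
  cat(
    "Improved cuckoo search gene selection\n",
    sprintf("  genes: %d selected of %d\n", sum(x$best_mask), length(x$best_mask)),
    sprintf("  best fitness (validation accuracy): %.4f\n", x$best_fitness),
    sprintf(
      "  iterations: %d, nests: %d, p_a: %.2f\n",
      x$params$T, x$params$n_nests, x$params$p_a
    ),
    sep = ""
  )
  invisible(x)
}

#' Tidy a cuckoo-search selection result
#'
#' `tidy()` returns one row per gene with its selection status; `glance()`
#' one row summarizing the run.
#'
#' @param x An `icso_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy icso_result
#' @export
tidy.icso_result <- function(x, ...) {
  tibble(
    gene_id = x$gene_ids,
    selected = x$best_mask == 1L
  )
}

#' @rdname tidy.icso_result
#' @method glance icso_result
#' @export
glance.icso_result <- function(x, ...) {
  tibble(
    n_genes = length(x$best_mask),
    n_selected = sum(x$best_mask),
    best_fitness = x$best_fitness,
    iterations = x$params$T,
    n_nests = x$params$n_nests,
    seed = x$params$seed
  )
}

#' Plot the best-fitness trace of a selection run
#'
#' @param object An `icso_result`.
#' @param ... Unused.
#' @return A ggplot object (iteration vs. best validation accuracy so far).
#' @method autoplot icso_result
#' @export
autoplot.icso_result <- function(object, ...) {
  d <- tibble(
    iteration = seq_along(object$fitness_trace),
    best_fitness = object$fitness_trace
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "iteration", y = "best validation accuracy",
      title = "Improved cuckoo search fitness trace"
    )
}

#' Write a selection result to disk
#'
#' Writes the selected gene identifiers (plain text, one per line) and a
#' JSON run report holding the parameters, seed and fitness trace.
#'
#' @param x An `icso_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two paths written.
#' @export
write_selection <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes_path <- file.path(dir, "selected_genes.txt")
  report_path <- file.path(dir, "selection_report.json")
  writeLines(x$selected_gene_ids, genes_path)
  jsonlite::write_json(
    list(
      params = unclass(x$params),
      best_fitness = x$best_fitness,
      n_selected = sum(x$best_mask),
      fitness_trace = x$fitness_trace
    ),
    report_path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(c(genes_path, report_path))
}
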