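test_that("cs_params validates its fields", {
  expect_error(cs_params(n_nests = 1), "n_nests")
  expect_error(cs_params(p_a = 1.5), "p_a")
  expect_error(cs_params(a_min = 2, a_max = 1), "a_min")
  expect_error(cs_params(levy_lambda = 3), "levy_lambda")
  expect_error(cs_params(binarize_threshold = 0), "binarize_threshold")
  p <- cs_params()
  expect_s3_class(p, "cs_params")
  expect_equal(p$n_nests, 25L)
})

test_that("proposals stay in the unit cube and are deterministic", {
  p <- cs_params(a_max = 5, a_min = 1, T = 10, seed = 1)
  pos <- rep(1, 20)
  set.seed(3)
  prop <- propose_nest(pos, 1, p)
  expect_true(all(prop$position <= 1 & prop$position >= 0))
  expect_identical(prop$mask, as.integer(prop$position >= 0.5))

  set.seed(7)
  a <- propose_nest(runif(10), 2, p)
  set.seed(7)
  b <- propose_nest(runif(10), 2, p)
  expect_identical(a, b)
})

test_that("a zero Levy step leaves the position unchanged", {
  local_mocked_bindings(levy_step = function(dim, ...) rep(0, dim))
  p <- cs_params(T = 10)
  pos <- c(0.1, 0.6, 0.9)
  set.seed(1)
  prop <- propose_nest(pos, 3, p)
  expect_identical(prop$position, pos)
})

test_that("fitness is the evaluator's masked validation accuracy", {
  gen <- make_planted(15, 15, 6, 2, 8, seed = 2)
  sp <- stratified_split(gen$data, 0.6, seed = 1)
  perfect <- function(...) 1
  expect_equal(evaluate_fitness(rep(1, 6), sp$train, sp$test, perfect), 1)
  expect_equal(evaluate_fitness(rep(0, 6), sp$train, sp$test), 0)

  majority <- function(train_x, train_y, val_x, val_y) {
    maj <- as.integer(mean(train_y) >= 0.5)
    mean(rep(maj, length(val_y)) == val_y)
  }
  # balanced validation labels -> chance level
  expect_equal(
    evaluate_fitness(rep(1, 6), sp$train, sp$test, majority),
    max(table(label_codes(sp$test))) / nrow(sp$test)
  )

  # only planted genes carry signal: their mask must beat its complement
  planted_mask <- as.integer(gen$planted)
  f_planted <- evaluate_fitness(planted_mask, sp$train, sp$test)
  f_noise <- evaluate_fitness(1L - planted_mask, sp$train, sp$test)
  expect_gt(f_planted, f_noise)
})

test_that("exhaustive oracle honors tie-breaks and matches brute force", {
  # single gene: only one candidate mask
  one <- make_planted(6, 6, 1, 1, 3, seed = 3)
  sp1 <- stratified_split(one$data, 0.5, seed = 1)
  ex1 <- exhaustive_best_mask(sp1$train, sp1$test)
  expect_identical(ex1$mask, 1L)
  expect_equal(ex1$fitness, evaluate_fitness(1L, sp1$train, sp1$test))

  # two identical genes tie; fewer genes, then lexicographically smaller wins
  set.seed(4)
  x <- rnorm(16)
  dup <- expression_table(
    cbind(x, x) + outer(rep(c(0, 3), each = 8), c(1, 1)),
    rep(c("a", "b"), each = 8),
    gene_ids = c("g1", "g2")
  )
  spd <- stratified_split(dup, 0.5, seed = 2)
  exd <- exhaustive_best_mask(spd$train, spd$test)
  expect_equal(sum(exd$mask), 1)
  expect_identical(exd$mask, c(0L, 1L)) # lexicographic: 01 < 10

  # independent brute-force reimplementation on an 8-gene problem
  gen <- make_planted(12, 12, 8, 3, 1.5, seed = 5)
  sp <- stratified_split(gen$data, 0.5, seed = 3)
  ex <- exhaustive_best_mask(sp$train, sp$test)
  cand <- expand.grid(rep(list(0:1), 8))
  cand <- cand[rowSums(cand) > 0, ]
  fits <- apply(cand, 1, function(m) {
    evaluate_fitness(as.integer(m), sp$train, sp$test)
  })
  sizes <- rowSums(cand)
  keys <- apply(cand, 1, paste, collapse = "")
  best_rows <- order(-fits, sizes, keys)[1]
  expect_equal(ex$fitness, unname(fits[best_rows]))
  expect_identical(ex$mask, as.integer(cand[best_rows, ]))

  big <- make_noise_table(4, 4, 21, seed = 1)
  expect_error(exhaustive_best_mask(big, big), "G <= 20")
})

test_that("the search is elitist, reproducible, and handles boundary budgets", {
  gen <- make_planted(20, 20, 8, 3, 2, seed = 6)
  sp <- stratified_split(gen$data, 0.5, seed = 1)

  for (seed in 1:5) {
    res <- icso_select(sp$train, sp$test, cs_params(n_nests = 8, T = 40, seed = seed))
    expect_true(all(diff(res$fitness_trace) >= 0))
    expect_equal(res$best_fitness, tail(res$fitness_trace, 1))
    expect_length(res$fitness_trace, 40)
    expect_identical(
      res$selected_gene_ids,
      gene_ids(sp$train)[res$best_mask == 1L]
    )
  }

  a <- icso_select(sp$train, sp$test, cs_params(n_nests = 6, T = 25, seed = 3))
  b <- icso_select(sp$train, sp$test, cs_params(n_nests = 6, T = 25, seed = 3))
  expect_identical(a$best_mask, b$best_mask)
  expect_identical(a$fitness_trace, b$fitness_trace)

  # T = 0 keeps the best of the random initial population, trace length 1
  r0 <- icso_select(sp$train, sp$test, cs_params(n_nests = 6, T = 0, seed = 2))
  expect_length(r0$fitness_trace, 1)
  expect_equal(r0$best_fitness, r0$fitness_trace[1])

  # constant evaluator -> flat trace
  rc <- icso_select(sp$train, sp$test, cs_params(n_nests = 6, T = 15, seed = 2),
    evaluator = function(...) 0.5
  )
  expect_equal(unique(rc$fitness_trace), 0.5)
})

test_that("selection results tidy, glance, plot and serialize", {
  gen <- make_planted(14, 14, 6, 2, 3, seed = 7)
  sp <- stratified_split(gen$data, 0.5, seed = 1)
  res <- icso_select(sp$train, sp$test, cs_params(n_nests = 6, T = 20, seed = 1))

  td <- tidy(res)
  expect_named(td, c("gene_id", "selected"))
  expect_equal(sum(td$selected), sum(res$best_mask))
  gl <- glance(res)
  expect_equal(gl$n_selected, sum(res$best_mask))
  expect_s3_class(autoplot(res), "ggplot")

  dir <- withr::local_tempdir()
  paths <- write_selection(res, dir)
  expect_identical(readLines(paths[1]), res$selected_gene_ids)
  rep <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  expect_equal(rep$best_fitness, res$best_fitness)
  expect_equal(rep$fitness_trace, res$fitness_trace)
  expect_equal(rep$params$n_nests, 6)
})
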