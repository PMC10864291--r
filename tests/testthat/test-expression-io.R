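test_that("genes-as-rows input is transposed to samples x genes", {
  mat <- withr::local_tempfile(fileext = ".tsv")
  lab <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "gene\ts1\ts2\ts3",
    "gA\t1\t2\t3",
    "gB\t4\t5\t6"
  ), mat)
  writeLines(c("tumor", "normal", "tumor"), lab)

  ds <- read_expression(mat, "genes_as_rows", lab)
  expect_equal(dim(expression_matrix(ds)), c(3L, 2L))
  expect_equal(gene_ids(ds), c("gA", "gB"))
  expect_equal(ds$sample_id, c("s1", "s2", "s3"))
  expect_equal(label_codes(ds), c(1L, 0L, 1L)) # normal < tumor -> 0/1
  expect_equal(ds$gA, c(1, 2, 3))

  # same file as samples_as_rows: 2 samples but 3 labels
  expect_error(
    read_expression(mat, "samples_as_rows", lab),
    "label length 3 does not match sample count 2"
  )
})

test_that("malformed files produce errors naming line and cell", {
  mat <- withr::local_tempfile(fileext = ".tsv")
  lab <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("gene\ts1\ts2", "gA\t1\t2", "gB\t3"), mat)
  writeLines(c("a", "b"), lab)
  expect_error(read_expression(mat, "genes_as_rows", lab), "line 3.*ragged")

  writeLines(c("gene\ts1\ts2", "gA\t1\toops", "gB\t3\t4"), mat)
  expect_error(
    read_expression(mat, "genes_as_rows", lab),
    "line 2, column 's2': non-numeric value 'oops'"
  )

  # label files must resolve to exactly two classes
  writeLines(c("gene\ts1\ts2", "gA\t1\t2", "gB\t3\t4"), mat)
  writeLines(c("a", "a"), lab)
  expect_error(read_expression(mat, "genes_as_rows", lab), "exactly 2 distinct classes")
})

test_that("labels can come from a column when samples are rows", {
  mat <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample,g1,class,g2",
    "s1,0.5,tumor,2",
    "s2,1.5,normal,4"
  ), mat)
  ds <- read_expression(mat, "samples_as_rows", labels = "class")
  expect_equal(gene_ids(ds), c("g1", "g2"))
  expect_equal(as.character(ds$label), c("tumor", "normal"))
  expect_equal(ds$g2, c(2, 4))
})

test_that("write/read round-trip preserves identifiers, labels and values", {
  gen <- make_planted(8, 9, 12, 3, 2, seed = 4)
  mat <- withr::local_tempfile(fileext = ".tsv")
  paths <- write_expression(gen$data, mat)
  back <- read_expression(mat, "samples_as_rows", paths[2])
  expect_identical(gene_ids(back), gene_ids(gen$data))
  expect_identical(back$sample_id, gen$data$sample_id)
  expect_identical(label_codes(back), label_codes(gen$data))
  expect_lt(
    max(abs(expression_matrix(back) - expression_matrix(gen$data))),
    1e-12
  )
})

test_that("stratified split uses per-class floor sizes and is deterministic", {
  ds <- make_noise_table(70, 86, 4, seed = 2)
  sp <- stratified_split(ds, 0.7, seed = 9)
  tr <- table(sp$train$label)
  te <- table(sp$test$label)
  expect_equal(unname(tr[["normal"]]), 49) # floor(0.7 * 70)
  expect_equal(unname(tr[["tumor"]]), 60) # floor(0.7 * 86)
  expect_equal(unname(te[["normal"]]), 21)
  expect_equal(unname(te[["tumor"]]), 26)

  # partition: disjoint and exhaustive
  expect_length(intersect(sp$train$sample_id, sp$test$sample_id), 0)
  expect_setequal(c(sp$train$sample_id, sp$test$sample_id), ds$sample_id)

  sp2 <- stratified_split(ds, 0.7, seed = 9)
  expect_identical(sp$train$sample_id, sp2$train$sample_id)

  sp_all <- stratified_split(ds, 1)
  expect_equal(nrow(sp_all$test), 0)
  expect_identical(sp_all$train$sample_id, ds$sample_id)

  expect_error(stratified_split(ds, 0), "train_fraction")
  expect_error(stratified_split(ds, 1.2), "train_fraction")
})

test_that("stratified k-fold balances classes across folds", {
  ds <- make_noise_table(70, 86, 3, seed = 3)
  fp <- stratified_kfold(ds, 5, seed = 1)
  counts <- table(fp$label, fp$fold)
  expect_equal(sort(as.vector(counts["tumor", ]), decreasing = TRUE),
    c(18, 17, 17, 17, 17)
  )
  expect_equal(as.vector(counts["normal", ]), rep(14, 5))
  # every fold holds both classes
  expect_true(all(counts > 0))

  # reshuffling sample order leaves the per-fold class-count multiset intact
  ds_shuf <- ds[rev(seq_len(nrow(ds))), ]
  fp2 <- stratified_kfold(ds_shuf, 5, seed = 1)
  counts2 <- table(fp2$label, fp2$fold)
  expect_equal(sort(as.vector(counts2)), sort(as.vector(counts)))

  # leave-one-out boundary on balanced tiny data
  tiny <- make_noise_table(3, 3, 2, seed = 5)
  loo <- stratified_kfold(tiny, 3, seed = 1)
  expect_equal(as.vector(table(loo$fold)), rep(2, 3))

  expect_error(stratified_kfold(tiny, 4), "every class needs >= k samples")
})
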