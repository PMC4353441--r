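test_that("expression matrix reads back what it wrote and preserves order", {
  m <- tiny_expr(1:6, 2, 3)
  expect_equal(dim(expr_values(m)), c(2L, 3L))
  expect_equal(unname(expr_values(m)[1, ]), c(1, 2, 3))
  expect_equal(expr_scale(m), "linear")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, path)
  back <- read_expression_matrix(path)
  expect_identical(expr_values(back), expr_values(m))
  expect_identical(back$probe_id, m$probe_id)

  # provenance comment lines are transparent to the reader
  write_expression_matrix(m, path, header_comment = "stage: test")
  expect_identical(expr_values(read_expression_matrix(path)), expr_values(m))
})

test_that("expression matrix validation names the offending cell", {
  expect_error(
    expr_matrix(tibble::tibble(probe_id = c("A", "A"), s1 = c(1, 2))),
    "duplicate probe_id: A"
  )
  expect_error(
    expr_matrix(tibble::tibble(probe_id = "A", s1 = -1)),
    "non-positive.*probe A.*sample s1"
  )
  expect_error(
    expr_matrix(tibble::tibble(probe_id = "A", s1 = NaN)),
    "non-finite"
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_lines(c("probe_id\ts1\ts2", "A\t1\tok"), path)
  expect_error(read_expression_matrix(path), "non-numeric.*probe A.*sample s2")
})

test_that("sample metadata derives 8 groups of 3 from the full design", {
  samples <- design_samples()
  expect_equal(nrow(samples), 24L)
  expect_equal(length(group_levels(samples)), 8L)
  expect_true(all(table(samples$group) == 3))
  # canonical order: strain, then week, then sham before IR
  expect_equal(
    group_levels(samples)[1:2], c("BALBc_wk2_sham", "BALBc_wk2_IR")
  )
})

test_that("group derivation is invariant to row order", {
  samples <- design_samples()
  shuffled <- sample_table(samples[sample(nrow(samples)), names(samples) != "group"])
  expect_setequal(levels(shuffled$group), levels(samples$group))
  merged <- dplyr::inner_join(
    samples[, c("sample_id", "group")], shuffled[, c("sample_id", "group")],
    by = "sample_id"
  )
  expect_equal(as.character(merged$group.x), as.character(merged$group.y))
})

test_that("sample metadata validation catches structural problems", {
  samples <- design_samples()
  expect_error(
    sample_table(samples[, names(samples) != "treatment"]),
    "missing column.*treatment"
  )
  bad <- samples
  bad$treatment[1] <- "mock"
  expect_error(sample_table(bad[names(bad) != "group"]), "unknown treatment.*mock")
  dup <- samples
  dup$sample_id[2] <- dup$sample_id[1]
  expect_error(sample_table(dup[names(dup) != "group"]), "duplicate sample_id")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_sample_metadata(samples, path)
  expect_equal(nrow(read_sample_metadata(path)), 24L)
})

test_that("probe annotation enforces the two-class universe", {
  ann <- probe_annotation(tibble::tibble(
    probe_id = c("l1", "m1"), probe_class = c("lncRNA", "mRNA"),
    gene_symbol = c("Linc1", NA)
  ))
  expect_identical(ann$gene_symbol[2], "") # NA symbol normalized to empty
  expect_error(
    probe_annotation(tibble::tibble(
      probe_id = "c1", probe_class = "circRNA", gene_symbol = "X"
    )),
    "unknown probe_class: circRNA"
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_probe_annotation(ann, path)
  expect_identical(read_probe_annotation(path), ann)
})

test_that("gene signatures deduplicate case-insensitively and round-trip", {
  path <- withr::local_tempfile(fileext = ".txt")
  readr::write_lines(c("Xist", "XIST", "Tsix"), path)
  expect_message(sig <- read_gene_signature(path), "1 duplicate")
  expect_equal(length(sig), 2L)
  expect_setequal(sig$symbols, c("XIST", "TSIX"))

  write_gene_signature(sig, path)
  expect_setequal(read_gene_signature(path)$symbols, sig$symbols)

  readr::write_lines(character(0), path)
  expect_warning(empty <- read_gene_signature(path), "empty")
  expect_equal(length(empty), 0L)
})
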