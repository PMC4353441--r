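test_that("pooled t-test matches the textbook formula and stats::t.test", {
  a <- c(1.0, 1.2, 0.8)
  b <- c(2.0, 2.2, 1.8)
  res <- student_t_test(a, b)
  orc <- oracle_t_test(a, b)
  expect_equal(res$t_statistic, orc$t)
  expect_equal(res$df, orc$df)
  expect_equal(res$p_value, orc$p)
  ref <- stats::t.test(b, a, var.equal = TRUE)
  expect_equal(res$t_statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
})

test_that("degenerate variance cases follow the stated conventions", {
  same <- student_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$degenerate)

  sep <- student_t_test(c(1, 1, 1), c(2, 2, 2))
  expect_true(sep$degenerate)
  expect_equal(sep$p_value, 0)

  expect_error(student_t_test(1, c(1, 2)), "at least 2")
})

test_that("fold change is symmetric, directional, and >= 1", {
  expect_equal(fold_change(2, 2)$fold_change, 1)
  expect_equal(fold_change(0, 1), tibble::tibble(fold_change = 2, direction = "up"))
  expect_equal(
    fold_change(0, -log2(1.5)),
    tibble::tibble(fold_change = 1.5, direction = "down")
  )
  expect_equal(fold_change(3, 3)$direction, "up") # tie convention
})

test_that("differential expression gates strictly at both cutoffs", {
  samples <- design_samples()
  wk2 <- samples$sample_id[samples$strain == "BALBc" & samples$timepoint_weeks == 2]
  # probe 1: delta exactly log2(1.5) with tiny within-group noise -> FC = 1.5
  # fails the strict > gate no matter how small p is
  set.seed(21)
  vals <- matrix(rnorm(3 * 24, 8, 0.5), 3, 24)
  colnames(vals) <- samples$sample_id
  vals[1, ] <- 8
  vals[1, wk2[4:6]] <- 8 + log2(1.5)
  m <- expr_matrix(
    dplyr::bind_cols(
      tibble::tibble(probe_id = c("fc_boundary", "null1", "null2")),
      tibble::as_tibble(vals)
    ),
    scale = "log2"
  )
  cc <- de_contrast("wk2",
    a = strain == "BALBc" & timepoint_weeks == 2 & treatment == "sham",
    b = strain == "BALBc" & timepoint_weeks == 2 & treatment == "IR"
  )
  de <- differential_expression(m, samples, cc)
  row <- de[de$probe_id == "fc_boundary", ]
  expect_equal(row$fold_change, 1.5)
  expect_false(row$passes_fc)
  expect_true(row$degenerate) # zero pooled variance, perfect separation
  expect_false(row$is_de)
})

test_that("swapping the groups negates t and delta and flips direction", {
  samples <- design_samples()
  set.seed(22)
  m <- tiny_expr(rnorm(20 * 24, 8, 1), 20, 24, scale = "log2",
                 sample_ids = samples$sample_id)
  fwd <- de_contrast("fwd",
    a = strain == "SPRET" & treatment == "sham",
    b = strain == "SPRET" & treatment == "IR"
  )
  rev <- de_contrast("rev",
    a = strain == "SPRET" & treatment == "IR",
    b = strain == "SPRET" & treatment == "sham"
  )
  d1 <- differential_expression(m, samples, fwd)
  d2 <- differential_expression(m, samples, rev)
  expect_equal(d2$t_statistic, -d1$t_statistic)
  expect_equal(d2$delta, -d1$delta)
  expect_equal(d2$p_value, d1$p_value)
  expect_equal(d2$fold_change, d1$fold_change)
  disagree <- d1$direction != d2$direction
  expect_true(all(disagree | d1$delta == 0))
})

test_that("null p-values are uniform and the combined filter is conservative", {
  samples <- design_samples()
  set.seed(23)
  n_probes <- 10000
  m <- tiny_expr(rnorm(n_probes * 6, 8, 0.5), n_probes, 6, scale = "log2",
                 sample_ids = samples$sample_id[samples$strain == "SPRET"])
  cc <- de_contrast("spret_wk4",
    a = strain == "SPRET" & treatment == "sham",
    b = strain == "SPRET" & treatment == "IR"
  )
  de <- differential_expression(m, samples[samples$strain == "SPRET", ], cc)
  ks <- stats::ks.test(de$p_value, "punif")
  expect_gt(ks$p.value, 0.01)
  # AND-filter can only remove calls relative to the p filter alone
  expect_lte(sum(de$is_de), sum(de$passes_p))
})

test_that("count_by_class tallies by class and direction with conservation", {
  ann <- probe_annotation(tibble::tibble(
    probe_id = c("l1", "l2", "m1", "m2"),
    probe_class = c("lncRNA", "lncRNA", "mRNA", "mRNA"),
    gene_symbol = c("A", "B", "C", "D")
  ))
  de <- tibble::tibble(
    probe_id = c("l1", "l2", "m1", "m2"),
    direction = c("up", "up", "down", "up"),
    is_de = c(TRUE, TRUE, TRUE, FALSE)
  )
  counts <- count_by_class(de, ann)
  expect_equal(nrow(counts), 4L)
  get <- function(cl, dir) counts$n[counts$probe_class == cl & counts$direction == dir]
  expect_equal(get("lncRNA", "up"), 2L)
  expect_equal(get("lncRNA", "down"), 0L)
  expect_equal(get("mRNA", "down"), 1L)
  expect_equal(sum(counts$n), sum(de$is_de))

  empty <- count_by_class(de[de$is_de == FALSE & FALSE, ], ann)
  expect_equal(sum(empty$n), 0L)
  expect_error(
    count_by_class(tibble::tibble(probe_id = "zz", direction = "up", is_de = TRUE), ann),
    "missing from annotation"
  )
})

test_that("de_union pools DE probes across contrasts", {
  d1 <- tibble::tibble(probe_id = c("a", "b"), is_de = c(TRUE, FALSE))
  d2 <- tibble::tibble(probe_id = c("b", "c"), is_de = c(TRUE, TRUE))
  expect_setequal(de_union(d1, d2), c("a", "b", "c"))
  expect_setequal(de_union(list(d1, d2)), c("a", "b", "c"))
})

test_that("tidy and glance summarize a DE table", {
  samples <- design_samples()
  set.seed(24)
  m <- tiny_expr(rnorm(10 * 24, 8, 1), 10, 24, scale = "log2",
                 sample_ids = samples$sample_id)
  de <- differential_expression(m, samples, default_contrasts(samples)[[1]])
  expect_s3_class(tidy(de), "tbl_df")
  g <- glance(de)
  expect_equal(g$n_probes, 10L)
  expect_equal(g$n_de, g$n_up + g$n_down)
})
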