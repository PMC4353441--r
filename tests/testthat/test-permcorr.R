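test_that("group means average replicates in canonical group order", {
  samples <- design_samples()
  vals <- matrix(0, 2, 24, dimnames = list(NULL, samples$sample_id))
  vals[1, samples$group == "BALBc_wk2_sham"] <- c(1, 2, 3)
  vals[2, ] <- 5
  m <- expr_matrix(
    dplyr::bind_cols(tibble::tibble(probe_id = c("a", "b")),
                     tibble::as_tibble(vals)),
    scale = "log2"
  )
  gm <- group_means(m, samples)
  expect_equal(names(gm), c("probe_id", group_levels(samples)))
  expect_equal(gm$BALBc_wk2_sham[1], 2)
  expect_equal(unlist(gm[2, -1], use.names = FALSE), rep(5, 8))

  # permuting sample columns leaves the result unchanged
  perm <- sample(samples$sample_id)
  m2 <- expr_matrix(
    dplyr::bind_cols(tibble::tibble(probe_id = c("a", "b")),
                     tibble::as_tibble(vals[, perm])),
    scale = "log2"
  )
  expect_equal(group_means(m2, samples), gm)

  single <- samples[samples$replicate == 1 | samples$group != "SPRET_wk4_IR", ]
  m3 <- expr_matrix(
    dplyr::bind_cols(tibble::tibble(probe_id = c("a", "b")),
                     tibble::as_tibble(vals[, single$sample_id])),
    scale = "log2"
  )
  expect_warning(group_means(m3, single), "single replicate")
})

test_that("pearson_r agrees with the direct product-moment formula", {
  x <- as.numeric(1:8)
  y <- c(2, 1, 4, 3, 6, 5, 8, 7)
  expect_equal(pearson_r(x, y), oracle_pearson(x, y))
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(1, 8)), "constant")
  expect_error(pearson_r(x, 1:7), "equal length")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("exhaustive enumeration covers 8! permutations and exact cases", {
  x <- c(1, 3, 2, 5, 4, 7, 6, 8)
  res <- exhaustive_permutation_pvalue(x, x, comparison = "greater")
  expect_equal(res$n_perms, 40320L)
  expect_equal(res$r_observed, 1)
  expect_equal(res$p_perm, 0) # nothing strictly exceeds r = 1

  # anti-sorted pair under one-sided "greater": almost everything exceeds
  anti <- exhaustive_permutation_pvalue(x, rev(x), comparison = "greater")
  expect_gt(anti$p_perm, 0.95)

  expect_error(exhaustive_permutation_pvalue(rnorm(11), rnorm(11)), "length <= 10")
  expect_error(exhaustive_permutation_pvalue(rep(1, 8), rnorm(8)), "constant")
})

test_that("the compiled engine matches brute-force enumeration in R", {
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(6)
    y <- rnorm(6)
    for (cmp in c("abs_greater", "greater")) {
      res <- exhaustive_permutation_pvalue(x, y, comparison = cmp)
      orc <- oracle_exhaustive_p(x, y, absolute = cmp == "abs_greater")
      expect_equal(res$n_perms, orc$n)
      expect_equal(res$p_perm, orc$p, info = sprintf("rep %d, %s", i, cmp))
    }
  }
})

test_that("Monte-Carlo p is deterministic per seed and near the exact p", {
  p <- simulate_pair(8, target_r = 0.6, seed = 32)
  a <- permutation_pvalue(p$x, p$y, n_perms = 5000, seed = 7)
  b <- permutation_pvalue(p$x, p$y, n_perms = 5000, seed = 7)
  expect_identical(tidy(a), tidy(b))

  exact <- exhaustive_permutation_pvalue(p$x, p$y)
  c2 <- permutation_pvalue(p$x, p$y, n_perms = 5000, seed = 99)
  tol <- 3 * sqrt(exact$p_perm * (1 - exact$p_perm) / 5000) + 1e-9
  expect_lt(abs(c2$p_perm - exact$p_perm), tol + 0.01)
  expect_equal(a$p_corrected, (a$n_exceeding + 1) / (a$n_perms + 1))
  expect_error(permutation_pvalue(p$x, p$y, n_perms = 0), "n_perms")
})

test_that("exhaustive p is symmetric in x and y and monotone in |r|", {
  set.seed(33)
  x <- rnorm(7)
  y <- rnorm(7)
  expect_equal(
    exhaustive_permutation_pvalue(x, y)$p_perm,
    exhaustive_permutation_pvalue(y, x)$p_perm
  )

  # within the family of rearrangements of one x against a fixed y, the
  # exact p is a non-increasing function of |r_observed|
  set.seed(34)
  x0 <- rnorm(8)
  y0 <- rnorm(8)
  fam <- c(list(x0, sort(x0), rev(sort(x0))),
           lapply(1:7, function(i) sample(x0)))
  stats <- vapply(fam, function(v) abs(pearson_r(v, y0)), numeric(1))
  ps <- vapply(fam, function(v) exhaustive_permutation_pvalue(v, y0)$p_perm,
               numeric(1))
  ord <- order(stats)
  expect_true(all(diff(ps[ord]) <= 0))
})

test_that("all-pairs scan enumerates pairs, skips constants, ignores order", {
  groups <- sprintf("g%d", 1:8)
  set.seed(35)
  lnc <- tibble::tibble(probe_id = c("l1", "l2", "l_const"))
  lnc[groups] <- as.data.frame(rbind(rnorm(8), rnorm(8), rep(1, 8)))
  mrna <- tibble::tibble(probe_id = c("m1", "m2", "m3"))
  mrna[groups] <- as.data.frame(rbind(rnorm(8), rnorm(8), rnorm(8)))

  edges <- correlate_all_pairs(lnc, mrna, n_perms = 500, seed = 42)
  expect_equal(nrow(edges), 9L)
  expect_true(all(edges$skip_reason[edges$lnc_id == "l_const"] == "constant_lnc"))
  expect_true(all(is.na(edges$skip_reason[edges$lnc_id != "l_const"])))
  expect_equal(edges$p_perm, edges$n_exceeding / edges$n_perms)

  # row order of the inputs must not change any per-pair result
  edges2 <- correlate_all_pairs(lnc[c(3, 1, 2), ], mrna[c(2, 3, 1), ],
                                n_perms = 500, seed = 42)
  j <- dplyr::inner_join(
    tibble::as_tibble(edges), tibble::as_tibble(edges2),
    by = c("lnc_id", "mrna_id")
  )
  expect_equal(nrow(j), 9L)
  expect_equal(j$r.x, j$r.y)
  expect_equal(j$n_exceeding.x, j$n_exceeding.y)

  # exhaustive mode reproduces the single-pair exact test
  ex <- correlate_all_pairs(lnc[1:2, ], mrna, mode = "exhaustive")
  one <- exhaustive_permutation_pvalue(
    unlist(lnc[1, groups]), unlist(mrna[2, groups])
  )
  expect_equal(ex$p_perm[ex$lnc_id == "l1" & ex$mrna_id == "m2"], one$p_perm)

  expect_error(
    correlate_all_pairs(lnc, dplyr::rename(mrna, gX = g8), n_perms = 10),
    "group columns"
  )
})

test_that("edge tables round-trip through TSV", {
  groups <- sprintf("g%d", 1:8)
  set.seed(36)
  lnc <- tibble::tibble(probe_id = "l1")
  lnc[groups] <- as.list(rnorm(8))
  mrna <- tibble::tibble(probe_id = c("m1", "m2"))
  mrna[groups] <- as.data.frame(rbind(rnorm(8), rnorm(8)))
  edges <- correlate_all_pairs(lnc, mrna, n_perms = 200, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_table(edges, path, header_comment = "stage: correlate")
  back <- read_edge_table(path)
  expect_equal(strip_attrs(back), strip_attrs(edges))
})
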