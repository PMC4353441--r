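#' Collapse replicates to per-group mean expression
#'
#' For each experimental treatment group, the mean log2 expression of its
#' biological replicates is computed per probe, producing the group-mean
#' vector (length 8 in the motivating design) that the permutation
#' correlation test consumes. Columns follow the canonical group order
#' (strain, then week, then sham before IR); sample column order in the
#' input never matters.
#'
#' @param m A normalized log2 `expr_tbl`.
#' @param samples A [sample_table()] assigning every matrix sample to a
#'   group.
#' @return Tibble: `probe_id` plus one column per group, attribute
#'   `"groups"` holding the canonical order.
#' @export
group_means <- function(m, samples) {
  stopifnot(inherits(m, "expr_tbl"))
  if (expr_scale(m) != "log2") abort("expected a log2-scale matrix")
  sid <- sample_ids(m)
  unassigned <- setdiff(sid, samples$sample_id)
  if (length(unassigned) > 0) {
    abort(paste0("samples not in metadata: ", paste(unassigned, collapse = ", ")))
  }
  samples <- samples[match(sid, samples$sample_id), ]
  groups <- levels(droplevels(samples$group))
  v <- expr_values(m)
  out <- tibble::tibble(probe_id = m$probe_id)
  for (g in groups) {
    cols <- sid[samples$group == g]
    if (length(cols) == 0) abort(sprintf("group %s has no samples", g))
    if (length(cols) == 1) {
      warn(sprintf("group %s has a single replicate; mean equals that value", g))
    }
    out[[g]] <- unname(rowMeans(v[, cols, drop = FALSE]))
  }
  attr(out, "groups") <- groups
  out
}

#' Pearson correlation of two group-mean vectors
#'
#' Thin, validating wrapper around the product-moment correlation: equal
#' lengths of at least 3, both vectors non-constant (a constant vector has
#' no defined correlation and the pair must be skipped by callers).
#'
#' @param x,y Numeric vectors.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("need at least 3 paired values")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("values must be finite")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("constant vector: correlation undefined")
  }
  cor(x, y, method = "pearson")
}

new_perm_test <- function(r, n_exceeding, n_perms, mode, comparison, seed = NA) {
  structure(
    list(
      r_observed = r,
      p_perm = n_exceeding / n_perms,
      p_corrected = (n_exceeding + 1) / (n_perms + 1),
      n_exceeding = as.integer(n_exceeding),
      n_perms = as.integer(n_perms),
      mode = mode, comparison = comparison, seed = seed
    ),
    class = "perm_test"
  )
}

#' Permutation test for correlation significance
#'
#' With `y` held fixed, the entries of `x` are rearranged uniformly at
#' random `n_perms` times (default 10,000) and the correlation recomputed
#' for each rearrangement; the p-value is the plain fraction of
#' rearrangements whose statistic strictly exceeds the observed one (ties
#' never count, so p can be 0; a `(b+1)/(n+1)` corrected p is also
#' reported). The statistic is `|r|` under the default `"abs_greater"`
#' comparison — strong negative correlations are then significant — or the
#' signed `r` under the literal one-sided `"greater"` reading.
#'
#' The generator is seeded, so the same seed reproduces the result exactly.
#'
#' @param x,y Numeric vectors valid for [pearson_r()].
#' @param n_perms Number of random rearrangements, >= 1.
#' @param comparison `"abs_greater"` (default) or `"greater"`.
#' @param seed Integer seed for the shuffle stream.
#' @return A `perm_test` object; see [tidy.perm_test()].
#' @examples
#' x <- c(1, 3, 2, 5, 4, 7, 6, 8)
#' permutation_pvalue(x, x + 0.1, n_perms = 1000, seed = 7)
#' @export
permutation_pvalue <- function(x, y, n_perms = 10000,
                               comparison = c("abs_greater", "greater"),
                               seed = 1) {
  comparison <- match.arg(comparison)
  if (!is.numeric(n_perms) || n_perms < 1) abort("`n_perms` must be >= 1")
  pearson_r(x, y) # validation (length, finiteness, constancy)
  res <- cpp_perm_montecarlo(
    as.numeric(x), as.numeric(y), as.integer(n_perms),
    comparison == "abs_greater", as.numeric(seed)
  )
  new_perm_test(res$r_observed, res$n_exceeding, res$n_perms,
    mode = "monte_carlo", comparison = comparison, seed = seed
  )
}

#' Exact permutation test by exhaustive enumeration
#'
#' Evaluates the statistic for every distinct rearrangement of `x` — all
#' n! of them, 40,320 for the 8-group design — giving the exact permutation
#' p-value that serves as ground truth for the Monte-Carlo mode. Feasible
#' only for short vectors; lengths above 10 are refused.
#'
#' @inheritParams permutation_pvalue
#' @return A `perm_test` object with `mode = "exhaustive"`.
#' @export
exhaustive_permutation_pvalue <- function(x, y,
                                          comparison = c("abs_greater", "greater")) {
  comparison <- match.arg(comparison)
  if (length(x) > 10) {
    abort("exhaustive enumeration limited to length <= 10; use permutation_pvalue()")
  }
  pearson_r(x, y)
  res <- cpp_perm_exhaustive(
    as.numeric(x), as.numeric(y), comparison == "abs_greater"
  )
  new_perm_test(res$r_observed, res$n_exceeding, res$n_perms,
    mode = "exhaustive", comparison = comparison
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test [%s, %s]: r = %.4f, p = %.4g (%d / %d permutations exceed)>\n",
    x$mode, x$comparison, x$r_observed, x$p_perm, x$n_exceeding, x$n_perms
  ))
  invisible(x)
}

#' Tidy permutation-test results
#'
#' @param x A `perm_test`.
#' @param ... Unused.
#' @return [tidy.perm_test()]: one-row tibble of the test's fields.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(
    r_observed = x$r_observed, p_perm = x$p_perm, p_corrected = x$p_corrected,
    n_exceeding = x$n_exceeding, n_perms = x$n_perms,
    mode = x$mode, comparison = x$comparison
  )
}

#' @rdname tidy.perm_test
#' @export
glance.perm_test <- function(x, ...) tidy(x)

#' Exact permutation p-values for a batch of pairs
#'
#' Vectorized exhaustive enumeration over many (x, y) pairs at once, for
#' calibration scans where thousands of exact small-n p-values are needed.
#' Pair k is row k of `x_mat` against row k of `y_mat`.
#'
#' @param x_mat,y_mat Matrices of identical shape, one pair per row,
#'   at most 10 columns.
#' @inheritParams permutation_pvalue
#' @return Tibble: `r`, `p_perm`, `n_perms`, `n_exceeding`, and `ok`
#'   (FALSE for constant-vector pairs, whose statistics are NA).
#' @export
exhaustive_pvalues <- function(x_mat, y_mat,
                               comparison = c("abs_greater", "greater")) {
  comparison <- match.arg(comparison)
  x_mat <- as.matrix(x_mat)
  y_mat <- as.matrix(y_mat)
  if (!identical(dim(x_mat), dim(y_mat))) abort("`x_mat` and `y_mat` must match in shape")
  if (ncol(x_mat) > 10) abort("exhaustive enumeration limited to length <= 10")
  res <- cpp_perm_exhaustive_batch(x_mat, y_mat, comparison == "abs_greater")
  tibble::tibble(
    r = res$r, p_perm = res$n_exceeding / res$n_perms,
    n_perms = res$n_perms, n_exceeding = res$n_exceeding, ok = res$ok
  )
}

#' Permutation-tested correlations for all lncRNA-mRNA pairs
#'
#' Runs the permutation correlation test for every (lncRNA, mRNA) pair of
#' two group-mean tables sharing identical group columns — typically the
#' radiation-responsive lncRNA and mRNA sets. Pairs involving a constant
#' vector have no defined correlation and are recorded with a
#' `skip_reason` instead of being dropped.
#'
#' A single `seed` governs the whole scan: each pair's shuffle stream is
#' derived deterministically from (seed, lnc_id, mrna_id), so results do
#' not depend on row order or on how the scan is partitioned.
#'
#' @param lnc,mrna [group_means()] tables with identical group columns.
#' @param n_perms Monte-Carlo rearrangements per pair (ignored when
#'   `mode = "exhaustive"`).
#' @param comparison `"abs_greater"` or `"greater"`.
#' @param seed Integer scan seed.
#' @param mode `"monte_carlo"` (default) or `"exhaustive"` (exact, group
#'   count <= 10).
#' @return An edge table: `lnc_id`, `mrna_id`, `r`, `p_perm`, `n_perms`,
#'   `n_exceeding`, `skip_reason` (NA when tested).
#' @export
correlate_all_pairs <- function(lnc, mrna, n_perms = 10000,
                                comparison = c("abs_greater", "greater"),
                                seed = 1, mode = c("monte_carlo", "exhaustive")) {
  comparison <- match.arg(comparison)
  mode <- match.arg(mode)
  g_l <- setdiff(names(lnc), "probe_id")
  g_m <- setdiff(names(mrna), "probe_id")
  if (!identical(g_l, g_m)) {
    abort("group columns of `lnc` and `mrna` differ")
  }
  if (anyDuplicated(lnc$probe_id) || anyDuplicated(mrna$probe_id)) {
    abort("duplicate probe_id in group-mean input; pairs must be unique")
  }
  if (mode == "exhaustive" && length(g_l) > 10) {
    abort("exhaustive mode limited to <= 10 groups")
  }
  lm <- as.matrix(lnc[, g_l, drop = FALSE])
  mm <- as.matrix(mrna[, g_m, drop = FALSE])
  res <- cpp_correlate_pairs(
    lm, mm, lnc$probe_id, mrna$probe_id,
    as.integer(n_perms), comparison == "abs_greater",
    mode == "exhaustive", as.numeric(seed)
  )
  out <- tibble::tibble(
    lnc_id = lnc$probe_id[res$lnc_index],
    mrna_id = mrna$probe_id[res$mrna_index],
    r = res$r,
    p_perm = res$n_exceeding / res$n_perms,
    n_perms = as.integer(res$n_perms),
    n_exceeding = as.integer(res$n_exceeding),
    skip_reason = c(NA_character_, "constant_lnc", "constant_mrna")[res$skip + 1L]
  )
  structure(out,
    class = c("edge_tbl", class(tibble::tibble())),
    comparison = comparison, mode = mode, seed = seed
  )
}

#' Read and write edge tables
#'
#' @param path File path (TSV, `#` comment lines ignored).
#' @export
read_edge_table <- function(path) {
  out <- readr::read_tsv(path,
    col_types = readr::cols(
      lnc_id = readr::col_character(), mrna_id = readr::col_character(),
      r = readr::col_double(), p_perm = readr::col_double(),
      n_perms = readr::col_integer(), n_exceeding = readr::col_integer(),
      skip_reason = readr::col_character()
    ),
    comment = "#", progress = FALSE
  )
  structure(out, class = c("edge_tbl", class(tibble::tibble())))
}

#' @rdname read_edge_table
#' @param edges An edge table.
#' @inheritParams write_expression_matrix
#' @export
write_edge_table <- function(edges, path, header_comment = NULL) {
  write_tsv_commented(tibble::as_tibble(edges), path, header_comment)
  invisible(path)
}
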