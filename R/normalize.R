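#' Log2 transform with an intensity floor
#'
#' Raw linear-scale intensities are floored at `floor` (guarding near-zero
#' signals) and log2-transformed. Applying the transform to a matrix that
#' is already on the log2 scale is refused.
#'
#' @param m An `expr_tbl` on the linear scale.
#' @param floor Linear-scale floor, default 1 (log2 value 0).
#' @return An `expr_tbl` on the log2 scale.
#' @examples
#' m <- expr_matrix(tibble::tibble(probe_id = "p", s1 = 8, s2 = 0.5))
#' expr_values(log2_transform(m)) # 3 and 0
#' @export
log2_transform <- function(m, floor = 1) {
  stopifnot(inherits(m, "expr_tbl"))
  if (expr_scale(m) == "log2") {
    abort("matrix is already log2-scaled (double-transform guard)")
  }
  if (!is.numeric(floor) || floor <= 0) abort("`floor` must be > 0")
  out <- tibble::as_tibble(m)
  for (s in sample_ids(m)) out[[s]] <- log2(pmax(out[[s]], floor))
  expr_matrix(out, scale = "log2")
}

#' Percentile-shift normalization (75th percentile by default)
#'
#' Each sample column is shifted so that its `percentile`-th percentile of
#' log2 signal equals zero — the log-scale equivalent of dividing each
#' array by its 75th-percentile intensity. No per-probe (baseline)
#' transformation is applied. Percentiles use the linear-interpolation
#' convention that places percentile q of sorted x(1)..x(n) at rank
#' 1 + (n-1) q / 100 (R's default, `type = 7`), so results are bit-exactly
#' reproducible.
#'
#' @param m An `expr_tbl` on the log2 scale.
#' @param percentile Percentile in (0, 100); default 75.
#' @return The normalized `expr_tbl`, with the per-sample shift report
#'   attached as attribute `"norm_report"` (retrieve with [norm_report()]).
#' @examples
#' m <- expr_matrix(
#'   tibble::tibble(probe_id = paste0("p", 1:4), s1 = c(1, 2, 3, 4)),
#'   scale = "log2"
#' )
#' norm_report(percentile_shift_normalize(m)) # shift = 3.25
#' @export
percentile_shift_normalize <- function(m, percentile = 75) {
  stopifnot(inherits(m, "expr_tbl"))
  if (expr_scale(m) != "log2") {
    abort("percentile-shift normalization expects a log2-scale matrix; run log2_transform() first")
  }
  if (!is.numeric(percentile) || percentile <= 0 || percentile >= 100) {
    abort("`percentile` must be in (0, 100)")
  }
  out <- tibble::as_tibble(m)
  samples <- sample_ids(m)
  shifts <- vapply(samples, function(s) {
    v <- out[[s]]
    if (sum(is.finite(v)) < 2) {
      abort(sprintf("sample %s has fewer than 2 finite values", s))
    }
    unname(quantile(v, probs = percentile / 100, type = 7, names = FALSE))
  }, numeric(1))
  for (s in samples) out[[s]] <- out[[s]] - shifts[[s]]
  res <- expr_matrix(out, scale = "log2")
  attr(res, "norm_report") <- tibble::tibble(
    sample_id = samples,
    percentile = percentile,
    shift_log2 = unname(shifts)
  )
  res
}

#' @rdname percentile_shift_normalize
#' @return [norm_report()]: a tibble with one row per sample giving the
#'   subtracted log2 shift (the sample's pre-normalization percentile).
#' @export
norm_report <- function(m) {
  attr(m, "norm_report") %||%
    abort("no normalization report attached; run percentile_shift_normalize() first")
}
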