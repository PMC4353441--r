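#' Declare a two-group contrast over the sample table
#'
#' Groups are declared as tidy predicates over the sample-metadata columns,
#' evaluated with [dplyr::filter()] semantics, so contrasts are never
#' hard-coded to a particular design. The two printed cutoff regimes of the
#' motivating analysis are `p_cutoff = 0.05, fc_cutoff = 1.5` for the
#' radiation response and `p_cutoff = 0.001, fc_cutoff = 1.5` for the
#' strain baseline comparison.
#'
#' @param name Contrast label.
#' @param a,b Unquoted predicates selecting the reference (`a`) and test
#'   (`b`) samples; fold change and t are reported as `b` relative to `a`.
#' @param p_cutoff,fc_cutoff Strict cutoffs: a probe is called DE when
#'   `p_value < p_cutoff` and `fold_change > fc_cutoff`.
#' @return A `de_contrast` object.
#' @examples
#' ir4 <- de_contrast("BALBc_wk4_IR_vs_sham",
#'   a = strain == "BALBc" & timepoint_weeks == 4 & treatment == "sham",
#'   b = strain == "BALBc" & timepoint_weeks == 4 & treatment == "IR"
#' )
#' @export
de_contrast <- function(name, a, b, p_cutoff = 0.05, fc_cutoff = 1.5) {
  if (!is.numeric(p_cutoff) || p_cutoff <= 0) abort("`p_cutoff` must be > 0")
  if (!is.numeric(fc_cutoff) || fc_cutoff < 1) abort("`fc_cutoff` must be >= 1")
  structure(
    list(
      name = name, a = rlang::enquo(a), b = rlang::enquo(b),
      p_cutoff = p_cutoff, fc_cutoff = fc_cutoff
    ),
    class = "de_contrast"
  )
}

#' @export
print.de_contrast <- function(x, ...) {
  cat(sprintf(
    "<de_contrast %s: p < %g, FC > %g>\n", x$name, x$p_cutoff, x$fc_cutoff
  ))
  invisible(x)
}

# resolve contrast predicates to disjoint, non-empty sample-id sets
resolve_contrast <- function(contrast, samples) {
  ids_a <- dplyr::filter(samples, !!contrast$a)$sample_id
  ids_b <- dplyr::filter(samples, !!contrast$b)$sample_id
  if (length(ids_a) == 0 || length(ids_b) == 0) {
    abort(sprintf("contrast %s resolves to an empty group", contrast$name))
  }
  both <- intersect(ids_a, ids_b)
  if (length(both) > 0) {
    abort(sprintf(
      "contrast %s groups overlap (e.g. %s)", contrast$name, both[1]
    ))
  }
  list(a = ids_a, b = ids_b)
}

#' Unpaired Student's t-test (pooled variance)
#'
#' The classical two-sample t with pooled variance and `na + nb - 2`
#' degrees of freedom (not Welch), two-sided p from the t distribution.
#' Zero pooled variance with equal means yields `t = 0, p = 1`; zero pooled
#' variance with unequal means is flagged degenerate and reported as
#' `p = 0` (the group separation is perfect but no variance estimate
#' exists).
#'
#' @param a,b Numeric vectors, each with at least 2 finite values.
#' @return One-row tibble: `t_statistic`, `df`, `p_value`, `degenerate`.
#' @examples
#' student_t_test(c(1, 2, 3), c(1, 2, 3)) # t = 0, p = 1
#' @export
student_t_test <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least 2 finite values")
  }
  na <- length(a)
  nb <- length(b)
  df <- na + nb - 2
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  delta <- mean(b) - mean(a)
  if (sp2 == 0) {
    if (delta == 0) {
      return(tibble::tibble(t_statistic = 0, df = df, p_value = 1, degenerate = FALSE))
    }
    return(tibble::tibble(
      t_statistic = sign(delta) * Inf, df = df, p_value = 0, degenerate = TRUE
    ))
  }
  t <- delta / sqrt(sp2 * (1 / na + 1 / nb))
  tibble::tibble(
    t_statistic = t, df = df, p_value = 2 * pt(-abs(t), df), degenerate = FALSE
  )
}

#' Fold change from log2 group means
#'
#' Fold change is computed symmetrically from log2 group means as
#' `2^|mean_b - mean_a|` (always >= 1, linear scale) with the direction
#' carried separately: `up` when `mean_b > mean_a`, `down` when lower, and
#' `up` by convention on exact ties (delta zero).
#'
#' @param mean_a,mean_b Log2 group means (vectorized).
#' @return Tibble with `fold_change` and `direction`.
#' @examples
#' fold_change(0, 1) # FC 2, up
#' fold_change(0, -log2(1.5)) # FC 1.5, down
#' @export
fold_change <- function(mean_a, mean_b) {
  delta <- mean_b - mean_a
  tibble::tibble(
    fold_change = 2^abs(delta),
    direction = ifelse(delta < 0, "down", "up")
  )
}

#' Differential expression for one contrast
#'
#' Per-probe pooled-variance Student's t-test plus fold-change gating on a
#' normalized log2 matrix. Both gates are strict: `p_value < p_cutoff` and
#' `fold_change > fc_cutoff`, so boundary values (e.g. FC exactly 1.5)
#' fail. Raw p-values gate the calls — no multiple-testing correction, per
#' the raw-cutoff convention of the motivating workflow — but a
#' Benjamini-Hochberg `p_adj` column is included for reference.
#'
#' @param m A normalized log2 `expr_tbl`.
#' @param samples A [sample_table()].
#' @param contrast A [de_contrast()].
#' @return A `ldir_de` tibble, one row per probe: group means, `delta`
#'   (log2, b minus a), `fold_change`, `direction`, `t_statistic`, `df`,
#'   `p_value`, `p_adj`, `degenerate`, `passes_p`, `passes_fc`, `is_de`.
#' @export
differential_expression <- function(m, samples, contrast) {
  stopifnot(inherits(m, "expr_tbl"), inherits(contrast, "de_contrast"))
  if (expr_scale(m) != "log2") abort("expected a log2-scale matrix")
  grp <- resolve_contrast(contrast, samples)
  missing <- setdiff(c(grp$a, grp$b), sample_ids(m))
  if (length(missing) > 0) {
    abort(paste0("samples absent from matrix: ", paste(missing, collapse = ", ")))
  }
  if (length(grp$a) < 2 || length(grp$b) < 2) {
    abort(sprintf("contrast %s needs >= 2 samples per group", contrast$name))
  }
  va <- expr_values(m)[, grp$a, drop = FALSE]
  vb <- expr_values(m)[, grp$b, drop = FALSE]
  na <- ncol(va)
  nb <- ncol(vb)
  df <- na + nb - 2
  mean_a <- rowMeans(va)
  mean_b <- rowMeans(vb)
  ss <- rowSums((va - mean_a)^2) + rowSums((vb - mean_b)^2)
  sp2 <- ss / df
  delta <- mean_b - mean_a
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- ifelse(sp2 == 0, ifelse(delta == 0, 0, sign(delta) * Inf), delta / se)
  p <- ifelse(sp2 == 0, ifelse(delta == 0, 1, 0), 2 * pt(-abs(t), df))
  fc <- fold_change(unname(mean_a), unname(mean_b))

  out <- tibble::tibble(
    probe_id = m$probe_id,
    mean_a = unname(mean_a), mean_b = unname(mean_b), delta = unname(delta),
    fold_change = fc$fold_change, direction = fc$direction,
    t_statistic = unname(t), df = df, p_value = unname(p),
    p_adj = p.adjust(unname(p), method = "BH"),
    degenerate = unname(sp2 == 0 & delta != 0),
    passes_p = unname(p < contrast$p_cutoff),
    passes_fc = fc$fold_change > contrast$fc_cutoff
  )
  out$is_de <- out$passes_p & out$passes_fc
  structure(out,
    class = c("ldir_de", class(tibble::tibble())),
    contrast = contrast$name,
    p_cutoff = contrast$p_cutoff, fc_cutoff = contrast$fc_cutoff,
    n_a = na, n_b = nb
  )
}

#' Summarize DE calls by probe class and direction
#'
#' @param de A `ldir_de` table (or any tibble with `probe_id`, `direction`,
#'   `is_de`).
#' @param ann A [probe_annotation()] covering every probe in `de`.
#' @return Tibble with one row per (class, direction) cell and count `n`;
#'   cells with no calls are kept at zero.
#' @export
count_by_class <- function(de, ann) {
  missing <- setdiff(de$probe_id, ann$probe_id)
  if (length(missing) > 0) {
    abort(paste0("probes missing from annotation: ", paste(head(missing, 5), collapse = ", ")))
  }
  grid <- tidyr::expand_grid(
    probe_class = c("lncRNA", "mRNA"), direction = c("up", "down")
  )
  counts <- de |>
    dplyr::filter(.data$is_de) |>
    dplyr::inner_join(ann[, c("probe_id", "probe_class")], by = "probe_id") |>
    dplyr::count(.data$probe_class, .data$direction)
  dplyr::left_join(grid, counts, by = c("probe_class", "direction")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Union of DE probe sets over contrasts
#'
#' The radiation-responsive set for a strain is the union of DE probes over
#' that strain's per-timepoint contrasts; the cross-strain set is the union
#' over strains. Any collection of DE tables can be combined.
#'
#' @param ... `ldir_de` tables (or a single list of them).
#' @return Character vector of probe ids called DE in at least one table.
#' @export
de_union <- function(...) {
  tables <- list(...)
  if (length(tables) == 1 && !inherits(tables[[1]], "data.frame")) {
    tables <- tables[[1]]
  }
  ids <- unlist(lapply(tables, function(d) d$probe_id[d$is_de]))
  unique(ids)
}

#' @export
#' @rdname differential_expression
#' @param x A `ldir_de` table.
#' @param ... Unused.
tidy.ldir_de <- function(x, ...) tibble::as_tibble(x)

#' @export
#' @rdname differential_expression
glance.ldir_de <- function(x, ...) {
  tibble::tibble(
    contrast = attr(x, "contrast"),
    n_probes = nrow(x),
    n_de = sum(x$is_de),
    n_up = sum(x$is_de & x$direction == "up"),
    n_down = sum(x$is_de & x$direction == "down"),
    n_degenerate = sum(x$degenerate),
    p_cutoff = attr(x, "p_cutoff"),
    fc_cutoff = attr(x, "fc_cutoff")
  )
}
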