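#' Volcano plot of a differential-expression table
#'
#' @param object A `ldir_de` table.
#' @param ... Unused.
#' @return A ggplot: log2 difference vs -log10 p, DE calls highlighted.
#' @export
autoplot.ldir_de <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$p_plot <- pmax(df$p_value, .Machine$double.xmin)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$delta, y = -log10(.data$p_plot), colour = .data$is_de
  )) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick"), name = "DE call"
    ) +
    ggplot2::geom_hline(
      yintercept = -log10(attr(object, "p_cutoff")), linetype = "dashed"
    ) +
    ggplot2::geom_vline(
      xintercept = c(-1, 1) * log2(attr(object, "fc_cutoff")), linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "log2 difference (b - a)", y = "-log10 p",
      title = attr(object, "contrast")
    ) +
    ggplot2::theme_minimal()
}

#' Permutation-p versus correlation for an edge table
#'
#' @param object An edge table from [correlate_all_pairs()].
#' @param ... Unused.
#' @export
autoplot.edge_tbl <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), is.na(.data$skip_reason))
  df$p_plot <- pmax(df$p_perm, 1 / (df$n_perms + 1))
  ggplot2::ggplot(df, ggplot2::aes(x = abs(.data$r), y = -log10(.data$p_plot))) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7) +
    ggplot2::labs(x = "|r| of group means", y = "-log10 permutation p") +
    ggplot2::theme_minimal()
}

#' Connectivity across significance thresholds
#'
#' @param conn Output of [connectivity_summary()].
#' @return A ggplot of the fraction of lncRNAs with at least one
#'   significant mRNA partner, per threshold.
#' @export
plot_connectivity <- function(conn) {
  ggplot2::ggplot(conn, ggplot2::aes(
    x = .data$threshold, y = .data$fraction_connected
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "permutation-p threshold",
      y = "fraction of lncRNAs with ≥ 1 mRNA partner"
    ) +
    ggplot2::theme_minimal()
}

#' Permutation null distribution for one pair
#'
#' Draws `n_perms` random rearrangements in R (an independent stream from
#' the test engine) and shows the null statistic distribution with the
#' observed value marked — a visual companion to [permutation_pvalue()].
#'
#' @inheritParams permutation_pvalue
#' @export
plot_permutation_null <- function(x, y, n_perms = 2000,
                                  comparison = c("abs_greater", "greater"),
                                  seed = 1) {
  comparison <- match.arg(comparison)
  r_obs <- pearson_r(x, y)
  stat <- function(r) if (comparison == "abs_greater") abs(r) else r
  null <- with_sim_seed(seed, {
    vapply(seq_len(n_perms), function(i) stat(cor(sample(x), y)), numeric(1))
  })
  ggplot2::ggplot(tibble::tibble(stat = null), ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = stat(r_obs), colour = "firebrick") +
    ggplot2::labs(
      x = if (comparison == "abs_greater") "|r| under permutation" else "r under permutation",
      y = "count"
    ) +
    ggplot2::theme_minimal()
}
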