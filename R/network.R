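#' Bipartite lncRNA-mRNA network at a p-value threshold
#'
#' Edges are the non-skipped pairs with `p_perm < p_threshold` (strict, as
#' the threshold notation `p < 5e-02` implies). Vertices carry their probe
#' class as both the igraph bipartite `type` flag (lncRNA = FALSE,
#' mRNA = TRUE) and a `probe_class` attribute; edges carry `r` and
#' `p_perm`.
#'
#' @param edges An edge table from [correlate_all_pairs()].
#' @param p_threshold Cutoff in (0, 1].
#' @param keep_isolated Include zero-degree lncRNA/mRNA vertices from the
#'   edge-table universe (default FALSE: vertices are endpoints of kept
#'   edges only).
#' @return An [igraph::graph] object.
#' @export
build_bipartite_network <- function(edges, p_threshold, keep_isolated = FALSE) {
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    abort("`p_threshold` must be in (0, 1]")
  }
  tested <- dplyr::filter(edges, is.na(.data$skip_reason))
  kept <- dplyr::filter(tested, .data$p_perm < p_threshold)
  if (keep_isolated) {
    lnc <- unique(tested$lnc_id)
    mrna <- unique(tested$mrna_id)
  } else {
    lnc <- unique(kept$lnc_id)
    mrna <- unique(kept$mrna_id)
  }
  verts <- tibble::tibble(
    name = c(lnc, mrna),
    type = c(rep(FALSE, length(lnc)), rep(TRUE, length(mrna))),
    probe_class = c(rep("lncRNA", length(lnc)), rep("mRNA", length(mrna)))
  )
  igraph::graph_from_data_frame(
    kept[, c("lnc_id", "mrna_id", "r", "p_perm")],
    directed = FALSE, vertices = verts
  )
}

#' Connectivity of lncRNAs across significance thresholds
#'
#' For each threshold, counts the lncRNAs correlated with at least one
#' mRNA at `p_perm < threshold` — the robustness summary of the analysis.
#' The denominator is every lncRNA in the edge-table universe with at
#' least one testable (non-skipped) pair, including zero-degree ones;
#' lncRNAs whose every pair was skipped were never testable and are
#' reported separately in the `"untestable_lnc"` attribute.
#'
#' @param edges An edge table.
#' @param thresholds Decreasing p cutoffs; default `c(5e-2, 5e-3, 5e-4)`.
#' @return Tibble, one row per threshold: `threshold`, `n_lnc_total`,
#'   `n_lnc_connected`, `fraction_connected`, `n_edges`, and a `degree`
#'   list-column of named per-lncRNA degrees.
#' @export
connectivity_summary <- function(edges, thresholds = c(5e-2, 5e-3, 5e-4)) {
  tested <- dplyr::filter(edges, is.na(.data$skip_reason))
  universe <- unique(tested$lnc_id)
  untestable <- setdiff(unique(edges$lnc_id), universe)
  out <- purrr::map_dfr(thresholds, function(th) {
    sig <- dplyr::filter(tested, .data$p_perm < th)
    deg <- table(factor(sig$lnc_id, levels = universe))
    tibble::tibble(
      threshold = th,
      n_lnc_total = length(universe),
      n_lnc_connected = sum(deg > 0),
      fraction_connected = if (length(universe) == 0) NA_real_ else sum(deg > 0) / length(universe),
      n_edges = nrow(sig),
      degree = list(setNames(as.integer(deg), names(deg)))
    )
  })
  attr(out, "untestable_lnc") <- untestable
  out
}

#' Export a network for external graph tools
#'
#' GraphML keeps node class and edge r/p attributes and round-trips
#' through [import_network()]; `edge_tsv` writes a flat edge list.
#'
#' @param network An igraph object from [build_bipartite_network()].
#' @param path Output file.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @export
export_network <- function(network, path, format = c("graphml", "edge_tsv")) {
  format <- rlang::arg_match(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(network, what = "edges")
    names(el)[1:2] <- c("lnc_id", "mrna_id")
    readr::write_tsv(tibble::as_tibble(el), path)
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("graphml", "edge_tsv")) {
  format <- rlang::arg_match(format)
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  el <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  igraph::graph_from_data_frame(el, directed = FALSE)
}
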