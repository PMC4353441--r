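#' Overlap between a DE gene set and a variable-gene signature
#'
#' Quantifies how much of a differential-expression call set is explained
#' by a gene signature (here, genes fluctuating over the mouse estrous
#' cycle), under the package's case-insensitive symbol matching. Set
#' arithmetic is exact; the fraction uses the DE set as denominator.
#'
#' @param de_symbols A [gene_set()] of DE gene symbols.
#' @param signature A [gene_set()] signature.
#' @return One-row tibble: `n_de`, `n_signature`, `n_overlap`,
#'   `overlap_fraction`, and list-columns `retained` (DE minus signature)
#'   and `overlapped`. An empty DE set reports fraction 0 with a warning.
#' @examples
#' overlap_with_signature(
#'   gene_set(c("a", "b", "c")), gene_set(c("b", "c", "d"))
#' )
#' @export
overlap_with_signature <- function(de_symbols, signature) {
  stopifnot(inherits(de_symbols, "gene_set"), inherits(signature, "gene_set"))
  de <- de_symbols$symbols
  sig <- signature$symbols
  hit <- intersect(de, sig)
  kept <- setdiff(de, sig)
  frac <- if (length(de) == 0) {
    warn("empty DE gene set: overlap fraction undefined, reporting 0")
    0
  } else {
    length(hit) / length(de)
  }
  tibble::tibble(
    n_de = length(de), n_signature = length(sig), n_overlap = length(hit),
    overlap_fraction = frac,
    retained = list(kept), overlapped = list(hit)
  )
}

#' Drop DE probes whose gene symbol is in a signature
#'
#' Removes every probe whose annotated gene symbol matches the signature
#' (case-insensitively). Because the signature is gene-level while DE calls
#' are probe-level, all probes of a matching gene are removed; probes with
#' an empty symbol never match and are retained. The operation is
#' idempotent.
#'
#' @param de A `ldir_de` table (any tibble with `probe_id` works).
#' @param ann A [probe_annotation()] covering the probes in `de`.
#' @param signature A [gene_set()].
#' @return `de` without the signature-matching rows; other rows unchanged.
#' @export
exclude_signature <- function(de, ann, signature) {
  stopifnot(inherits(signature, "gene_set"))
  missing <- setdiff(de$probe_id, ann$probe_id)
  if (length(missing) > 0) {
    abort(paste0("probes missing from annotation: ", paste(head(missing, 5), collapse = ", ")))
  }
  sym <- setNames(toupper(ann$gene_symbol), ann$probe_id)[de$probe_id]
  drop <- nzchar(sym) & sym %in% signature$symbols
  out <- de[!drop, , drop = FALSE]
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Symbols of the DE probes in a table, as a gene_set
#'
#' Convenience bridge from probe-level DE calls to gene-symbol-level set
#' operations; probes with empty symbols are dropped.
#'
#' @inheritParams exclude_signature
#' @param name Name for the resulting set.
#' @param de_only Use only `is_de` rows (default) or all rows.
#' @export
de_gene_set <- function(de, ann, name = "de_genes", de_only = TRUE) {
  ids <- if (de_only && "is_de" %in% names(de)) de$probe_id[de$is_de] else de$probe_id
  sym <- setNames(ann$gene_symbol, ann$probe_id)[ids]
  gene_set(sym[nzchar(sym)], name = name)
}
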