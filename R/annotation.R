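#' Probe annotation: class (lncRNA or mRNA) and gene symbol
#'
#' Every probe carries exactly one class, so the two classes partition the
#' probe universe. `gene_symbol` may be empty: such probes can never match
#' a gene signature (absence of evidence is not membership) and are
#' retained by signature exclusion.
#'
#' @param data Data frame with columns `probe_id`, `probe_class`,
#'   `gene_symbol`.
#' @return A validated tibble.
#' @export
probe_annotation <- function(data) {
  data <- tibble::as_tibble(data)
  required <- c("probe_id", "probe_class", "gene_symbol")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(paste0("probe annotation missing column(s): ", paste(missing, collapse = ", ")))
  }
  data$probe_id <- as.character(data$probe_id)
  dup <- unique(data$probe_id[duplicated(data$probe_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate probe_id in annotation: ", paste(head(dup, 5), collapse = ", ")))
  }
  bad <- setdiff(unique(data$probe_class), c("lncRNA", "mRNA"))
  if (length(bad) > 0) {
    abort(paste0("unknown probe_class: ", paste(bad, collapse = ", "),
                 " (expected lncRNA or mRNA)"))
  }
  data$gene_symbol <- dplyr::coalesce(as.character(data$gene_symbol), "")
  data
}

#' @rdname probe_annotation
#' @param path Tab-separated file with the three columns.
#' @export
read_probe_annotation <- function(path) {
  data <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#", progress = FALSE
  )
  probe_annotation(data)
}

#' @rdname probe_annotation
#' @param ann A probe annotation tibble.
#' @inheritParams write_expression_matrix
#' @export
write_probe_annotation <- function(ann, path, header_comment = NULL) {
  write_tsv_commented(ann, path, header_comment)
  invisible(path)
}

#' Gene sets with case-insensitive symbol matching
#'
#' Gene symbols are matched case-insensitively across sources (mouse symbol
#' casing varies by platform), so symbols are normalized to upper case on
#' construction and duplicates under that normalization are dropped.
#'
#' @param symbols Character vector of gene symbols.
#' @param name Set name (e.g. `"estrous_signature"`).
#' @return A `gene_set`: list with `symbols` (unique, upper-cased), `name`,
#'   and `n_duplicates_removed`.
#' @examples
#' gene_set(c("Xist", "XIST", "Tsix"), "demo")
#' @export
gene_set <- function(symbols, name = "gene_set") {
  symbols <- as.character(symbols)
  symbols <- symbols[!is.na(symbols) & nzchar(trimws(symbols))]
  norm <- toupper(trimws(symbols))
  n_dup <- sum(duplicated(norm))
  if (n_dup > 0) {
    inform(sprintf("gene_set %s: removed %d duplicate symbol(s)", name, n_dup))
  }
  out <- structure(
    list(symbols = unique(norm), name = name, n_duplicates_removed = n_dup),
    class = "gene_set"
  )
  if (length(out$symbols) == 0) warn(sprintf("gene_set %s is empty", name))
  out
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set %s: %d symbols>\n", x$name, length(x$symbols)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$symbols)

#' @rdname gene_set
#' @param path Text file, one symbol per line; blank lines ignored.
#' @export
read_gene_signature <- function(path, name = basename(path)) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  gene_set(lines, name = name)
}

#' @rdname gene_set
#' @param set A `gene_set`.
#' @export
write_gene_signature <- function(set, path) {
  readr::write_lines(set$symbols, path)
  invisible(path)
}
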