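#' Expression matrix as a tibble with a scale flag
#'
#' An expression matrix is stored as a tibble whose first column,
#' `probe_id`, identifies the probe and whose remaining columns hold one
#' sample each (linear-scale hybridization intensities on ingest, log2
#' signals after [log2_transform()]). The scale travels with the object as
#' the `"scale"` attribute so a double log-transform can be refused.
#'
#' @param data A data frame: `probe_id` column plus one numeric column per
#'   sample.
#' @param scale `"linear"` or `"log2"`.
#' @return A tibble of class `expr_tbl` with a `"scale"` attribute.
#' @examples
#' m <- expr_matrix(
#'   tibble::tibble(probe_id = c("p1", "p2"), s1 = c(1, 2), s2 = c(3, 4)),
#'   scale = "linear"
#' )
#' expr_scale(m)
#' @export
expr_matrix <- function(data, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  data <- tibble::as_tibble(data)
  if (!"probe_id" %in% names(data)) {
    abort("expression data must have a `probe_id` column")
  }
  data$probe_id <- as.character(data$probe_id)
  data <- dplyr::relocate(data, "probe_id")
  if (ncol(data) < 2) abort("expression data has no sample columns")

  dup <- unique(data$probe_id[duplicated(data$probe_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate probe_id: ", paste(head(dup, 5), collapse = ", ")))
  }
  dup_s <- unique(names(data)[duplicated(names(data))])
  if (length(dup_s) > 0) {
    abort(paste0("duplicate sample_id: ", paste(dup_s, collapse = ", ")))
  }
  vals <- as.matrix(data[, -1])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(data[-1], is.numeric, logical(1)))[1]
    abort(paste0("non-numeric sample column: ", names(data[-1])[bad]))
  }
  if (any(!is.finite(vals))) {
    idx <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "non-finite intensity at probe %s, sample %s",
      data$probe_id[idx[1]], colnames(vals)[idx[2]]
    ))
  }
  if (scale == "linear" && any(vals <= 0)) {
    idx <- which(vals <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "non-positive linear intensity at probe %s, sample %s",
      data$probe_id[idx[1]], colnames(vals)[idx[2]]
    ))
  }
  structure(data,
    class = c("expr_tbl", class(tibble::tibble())),
    scale = scale
  )
}

#' @rdname expr_matrix
#' @param m An `expr_tbl`.
#' @export
expr_scale <- function(m) attr(m, "scale") %||% "linear"

#' @rdname expr_matrix
#' @export
sample_ids <- function(m) setdiff(names(m), "probe_id")

#' Extract the numeric value matrix (probes x samples)
#'
#' @param m An `expr_tbl`.
#' @return A numeric matrix with probe ids as rownames.
#' @export
expr_values <- function(m) {
  v <- as.matrix(m[, setdiff(names(m), "probe_id"), drop = FALSE])
  rownames(v) <- m$probe_id
  v
}

#' @export
print.expr_tbl <- function(x, ...) {
  cat(sprintf(
    "# Expression matrix: %d probes x %d samples [%s scale]\n",
    nrow(x), ncol(x) - 1L, expr_scale(x)
  ))
  NextMethod()
}

#' Read and write expression matrices
#'
#' Tab-separated, UTF-8, `.` decimal: first column `probe_id`, header row of
#' sample ids, one row per probe. Lines starting with `#` are ignored so
#' pipeline provenance headers round-trip. Cell-level validation reports the
#' offending probe/sample on failure.
#'
#' @param path File path.
#' @param scale Scale of the stored values (`"linear"` on ingest of raw
#'   intensities).
#' @return [read_expression_matrix()]: an `expr_tbl`;
#'   [write_expression_matrix()]: `path`, invisibly.
#' @export
read_expression_matrix <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  raw <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#", progress = FALSE
  )
  if (ncol(raw) < 2) abort(sprintf("%s: expected probe_id plus sample columns", path))
  names(raw)[1] <- "probe_id"
  for (j in seq(2, ncol(raw))) {
    num <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(num) & !is.na(raw[[j]]))
    if (length(bad) > 0) {
      abort(sprintf(
        "%s: non-numeric value %s at probe %s, sample %s",
        path, dQuote(raw[[j]][bad[1]]), raw$probe_id[bad[1]], names(raw)[j]
      ))
    }
    raw[[j]] <- num
  }
  expr_matrix(raw, scale = scale)
}

#' @rdname read_expression_matrix
#' @param m An `expr_tbl`.
#' @param header_comment Optional character vector written as `#`-prefixed
#'   provenance lines before the table.
#' @export
write_expression_matrix <- function(m, path, header_comment = NULL) {
  stopifnot(inherits(m, "expr_tbl"))
  write_tsv_commented(tibble::as_tibble(m), path, header_comment)
  invisible(path)
}

# shared writer: optional "# ..." provenance lines, then the TSV body
write_tsv_commented <- function(tbl, path, header_comment = NULL) {
  if (!is.null(header_comment)) {
    readr::write_lines(paste0("# ", header_comment), path)
    readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(tbl, path)
  }
  invisible(path)
}
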