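#' Sample metadata and experimental-group derivation
#'
#' The design factors are `strain`, `timepoint_weeks` and `treatment`
#' (`sham` or `IR`); each unique combination is one experimental treatment
#' group. The motivating design has 8 groups (BALB/c sham/IR at 2, 4 and 8
#' weeks; SPRET/EiJ sham/IR at 4 weeks) with 3 biological replicates each,
#' but any fully-crossed subset is accepted.
#'
#' The derived `group` column is a factor in canonical order: strain
#' (alphabetical), then week (ascending), then sham before IR. Group
#' derivation is a pure function of the three design factors, so row order
#' never changes the partition.
#'
#' @param data A data frame with columns `sample_id`, `strain`,
#'   `timepoint_weeks`, `treatment`, `replicate` (and optionally
#'   `dose_cGy`, carried as metadata).
#' @return A tibble with a `group` factor column appended.
#' @export
sample_table <- function(data) {
  data <- tibble::as_tibble(data)
  required <- c("sample_id", "strain", "timepoint_weeks", "treatment", "replicate")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(paste0("sample metadata missing column(s): ", paste(missing, collapse = ", ")))
  }
  data$sample_id <- as.character(data$sample_id)
  dup <- unique(data$sample_id[duplicated(data$sample_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate sample_id: ", paste(dup, collapse = ", ")))
  }
  bad_trt <- setdiff(unique(data$treatment), c("sham", "IR"))
  if (length(bad_trt) > 0) {
    abort(paste0("unknown treatment value(s): ", paste(bad_trt, collapse = ", "),
                 " (expected sham or IR)"))
  }
  data$timepoint_weeks <- as.numeric(data$timepoint_weeks)
  data$replicate <- as.integer(data$replicate)
  if (any(is.na(data$timepoint_weeks)) || any(is.na(data$replicate))) {
    abort("timepoint_weeks and replicate must be numeric")
  }
  if (any(data$replicate < 1)) abort("replicate must be >= 1")
  data$group <- derive_group(data)
  data
}

# canonical group factor: strain, then week, then sham < IR
derive_group <- function(data) {
  lab <- sprintf("%s_wk%g_%s", data$strain, data$timepoint_weeks, data$treatment)
  key <- unique(data.frame(
    strain = data$strain, wk = data$timepoint_weeks,
    trt = factor(data$treatment, levels = c("sham", "IR")), lab = lab,
    stringsAsFactors = FALSE
  ))
  key <- key[order(key$strain, key$wk, key$trt), ]
  factor(lab, levels = key$lab)
}

#' @rdname sample_table
#' @param path Tab-separated file with the required columns.
#' @export
read_sample_metadata <- function(path) {
  data <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_guess()),
    comment = "#", progress = FALSE
  )
  sample_table(data)
}

#' @rdname sample_table
#' @param samples A validated sample table.
#' @export
write_sample_metadata <- function(samples, path, header_comment = NULL) {
  out <- samples
  out$group <- NULL # derived, not stored
  write_tsv_commented(out, path, header_comment)
  invisible(path)
}

#' @rdname sample_table
#' @inheritParams write_expression_matrix
#' @export
group_levels <- function(samples) levels(samples$group)
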