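#' IR-vs-sham contrasts implied by a sample table
#'
#' One contrast per (strain, timepoint) cell that has both sham and IR
#' samples — the per-timepoint radiation-response comparisons. Contrasts
#' are derived from the metadata, never hard-coded to a design.
#'
#' @param samples A [sample_table()].
#' @param p_cutoff,fc_cutoff Cutoffs applied to every generated contrast.
#' @return List of [de_contrast()] objects.
#' @export
default_contrasts <- function(samples, p_cutoff = 0.05, fc_cutoff = 1.5) {
  cells <- dplyr::distinct(samples, .data$strain, .data$timepoint_weeks, .data$treatment) |>
    dplyr::count(.data$strain, .data$timepoint_weeks) |>
    dplyr::filter(.data$n == 2)
  purrr::map2(cells$strain, cells$timepoint_weeks, function(s, w) {
    new_de_contrast(
      sprintf("%s_wk%g_IR_vs_sham", s, w),
      rlang::quo(.data$strain == !!s & .data$timepoint_weeks == !!w & .data$treatment == "sham"),
      rlang::quo(.data$strain == !!s & .data$timepoint_weeks == !!w & .data$treatment == "IR"),
      p_cutoff, fc_cutoff
    )
  })
}

# quosure-level constructor shared by de_contrast() and config parsing
new_de_contrast <- function(name, a_quo, b_quo, p_cutoff = 0.05, fc_cutoff = 1.5) {
  structure(
    list(name = name, a = a_quo, b = b_quo,
         p_cutoff = p_cutoff, fc_cutoff = fc_cutoff),
    class = "de_contrast"
  )
}

#' Pipeline configuration
#'
#' Collects every stage's settings in one declarative object. Inputs come
#' either from files (`expr_path`, `samples_path`, `annotation_path`,
#' optional `signature_path`) or from the simulator (`simulate` =
#' a [sim_config()]). All workflow defaults — 75th percentile, p < 0.05
#' with FC > 1.5, 10,000 permutations, thresholds 5e-2/5e-3/5e-4 — live
#' here, never inside the stages.
#'
#' @param expr_path,samples_path,annotation_path,signature_path Input
#'   files (TSV dialects of the package writers; signature is one symbol
#'   per line). Ignored when `simulate` is given.
#' @param simulate Optional [sim_config()]: generate inputs in-run.
#' @param contrasts List of [de_contrast()]s; NULL derives
#'   [default_contrasts()] from the sample table.
#' @param percentile,floor Normalization settings.
#' @param use_signature Apply signature exclusion when a signature is
#'   available (when none is, the stage is skipped with a notice).
#' @param n_perms,comparison,perm_mode,seed Permutation-test settings.
#' @param thresholds Connectivity-summary p cutoffs.
#' @param network_threshold Threshold of the exported GraphML network.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expr_path = NULL, samples_path = NULL,
                            annotation_path = NULL, signature_path = NULL,
                            simulate = NULL, contrasts = NULL,
                            percentile = 75, floor = 1,
                            use_signature = TRUE,
                            n_perms = 10000,
                            comparison = c("abs_greater", "greater"),
                            perm_mode = c("monte_carlo", "exhaustive"),
                            seed = 1,
                            thresholds = c(5e-2, 5e-3, 5e-4),
                            network_threshold = 5e-3) {
  comparison <- match.arg(comparison)
  perm_mode <- match.arg(perm_mode)
  if (is.null(simulate)) {
    for (p in c(expr_path, samples_path, annotation_path)) {
      if (is.null(p)) abort("either `simulate` or all of expr/samples/annotation paths must be given")
    }
  }
  structure(
    list(
      expr_path = expr_path, samples_path = samples_path,
      annotation_path = annotation_path, signature_path = signature_path,
      simulate = simulate, contrasts = contrasts,
      percentile = percentile, floor = floor, use_signature = use_signature,
      n_perms = n_perms, comparison = comparison, perm_mode = perm_mode,
      seed = seed, thresholds = thresholds,
      network_threshold = network_threshold
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Contrast predicates appear as strings (e.g.
#' `a: strain == "BALBc" & treatment == "sham"`) and are parsed into tidy
#' predicates; a `simulate:` block holds [sim_config()] overrides.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  rlang::check_installed("yaml")
  raw <- yaml::read_yaml(path)
  contrasts <- NULL
  if (!is.null(raw$contrasts)) {
    contrasts <- lapply(raw$contrasts, function(cc) {
      new_de_contrast(
        cc$name,
        rlang::new_quosure(rlang::parse_expr(cc$a)),
        rlang::new_quosure(rlang::parse_expr(cc$b)),
        cc$p_cutoff %||% 0.05, cc$fc_cutoff %||% 1.5
      )
    })
  }
  sim <- if (!is.null(raw$simulate)) do.call(sim_config, raw$simulate) else NULL
  args <- raw[setdiff(names(raw), c("contrasts", "simulate"))]
  args$thresholds <- unlist(args$thresholds %||% NULL)
  args <- args[!vapply(args, is.null, logical(1))]
  do.call(pipeline_config, c(args, list(contrasts = contrasts, simulate = sim)))
}

# hash of the analysis-relevant config (paths excluded so identical runs in
# different directories produce identical bytes)
config_hash <- function(cfg) {
  keep <- cfg[setdiff(names(cfg), c("expr_path", "samples_path",
                                    "annotation_path", "signature_path"))]
  keep$contrasts <- lapply(keep$contrasts, function(cc) {
    list(cc$name, rlang::expr_text(rlang::quo_get_expr(cc$a)),
         rlang::expr_text(rlang::quo_get_expr(cc$b)), cc$p_cutoff, cc$fc_cutoff)
  })
  keep$simulate <- if (is.null(keep$simulate)) NULL else unclass(keep$simulate)
  rlang::hash(keep)
}

#' Run the full analysis: matrix to network summary
#'
#' Executes the stages in fixed order — normalize (log2 + percentile
#' shift), differential expression per contrast, union of the
#' radiation-responsive sets, signature exclusion (skipped with a notice
#' when no signature is available), group means, all-pairs permutation
#' correlation, and connectivity summaries — writing every stage output
#' plus a JSON run manifest under `outdir`. A rerun with the same config
#' and seed reproduces all outputs byte-for-byte; each emitted table
#' carries a header comment naming the producing stage and the config
#' hash.
#'
#' @param cfg A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a list with the in-memory stage results (`de`,
#'   `edges`, `connectivity`, `manifest`, ...).
#' @export
run_all <- function(cfg, outdir, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  say <- function(...) if (!quiet) inform(sprintf(...))
  stages <- character(0)
  note <- function(stage, status = "completed") {
    stages <<- c(stages, setNames(status, stage))
  }
  hdr <- function(stage) sprintf("stage: %s | config: %s", stage, hash)
  in_stage <- function(stage, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", stage, conditionMessage(e)))
    })
  }

  # inputs
  if (!is.null(cfg$simulate)) {
    say("inputs: simulating dataset (seed %d)", cfg$simulate$seed)
    sim <- simulate_dataset(cfg$simulate)
    expr <- sim$expr
    samples <- sim$samples
    ann <- sim$annotation
    signature <- if (length(sim$signature$symbols) > 0) sim$signature else NULL
    readr::write_tsv(sim$truth$de, file.path(outdir, "truth_de.tsv"))
    readr::write_tsv(sim$truth$pairs, file.path(outdir, "truth_pairs.tsv"))
  } else {
    expr <- read_expression_matrix(cfg$expr_path)
    samples <- read_sample_metadata(cfg$samples_path)
    ann <- read_probe_annotation(cfg$annotation_path)
    signature <- if (!is.null(cfg$signature_path)) read_gene_signature(cfg$signature_path) else NULL
  }

  # 1. normalize
  say("stage normalize: log2 (floor %g) + percentile %g shift", cfg$floor, cfg$percentile)
  norm <- in_stage("normalize", {
    percentile_shift_normalize(log2_transform(expr, cfg$floor), cfg$percentile)
  })
  write_expression_matrix(norm, file.path(outdir, "normalized.tsv"), hdr("normalize"))
  write_tsv_commented(norm_report(norm), file.path(outdir, "normalization_report.tsv"),
                      hdr("normalize"))
  note("normalize")

  # 2. differential expression per contrast
  contrasts <- cfg$contrasts %||% default_contrasts(samples)
  say("stage differential_expression: %d contrast(s)", length(contrasts))
  de_list <- in_stage("differential_expression", {
    setNames(
      lapply(contrasts, function(cc) differential_expression(norm, samples, cc)),
      vapply(contrasts, function(cc) cc$name, character(1))
    )
  })
  for (nm in names(de_list)) {
    write_tsv_commented(tibble::as_tibble(de_list[[nm]]),
      file.path(outdir, sprintf("de_%s.tsv", nm)),
      hdr("differential_expression")
    )
  }
  note("differential_expression")

  # 3. union of radiation-responsive probes
  de_ids <- in_stage("ldir_union", de_union(de_list))
  say("stage ldir_union: %d DE probes across contrasts", length(de_ids))
  readr::write_lines(
    c(paste0("# ", hdr("ldir_union")), de_ids),
    file.path(outdir, "ldir_probes.txt")
  )
  note("ldir_union")

  # 4. signature exclusion (optional)
  if (!is.null(signature) && cfg$use_signature) {
    ov <- in_stage("signature_exclusion", {
      overlap_with_signature(
        gene_set(ann$gene_symbol[match(de_ids, ann$probe_id)], "de_union"),
        signature
      )
    })
    say(
      "stage signature_exclusion: %d/%d DE genes in signature (%.1f%%)",
      ov$n_overlap, ov$n_de, 100 * ov$overlap_fraction
    )
    sym <- toupper(ann$gene_symbol[match(de_ids, ann$probe_id)])
    de_ids <- de_ids[!(nzchar(sym) & sym %in% signature$symbols)]
    write_tsv_commented(
      dplyr::select(ov, -"retained", -"overlapped"),
      file.path(outdir, "signature_overlap.tsv"), hdr("signature_exclusion")
    )
    note("signature_exclusion")
  } else {
    say("stage signature_exclusion: no signature configured, skipped")
    note("signature_exclusion", "skipped")
  }

  # 5. group means, split by probe class, restricted to the DE universe
  gm <- in_stage("group_means", group_means(norm, samples))
  lnc_ids <- intersect(de_ids, ann$probe_id[ann$probe_class == "lncRNA"])
  mrna_ids <- intersect(de_ids, ann$probe_id[ann$probe_class == "mRNA"])
  gm_lnc <- gm[match(lnc_ids, gm$probe_id), , drop = FALSE]
  gm_mrna <- gm[match(mrna_ids, gm$probe_id), , drop = FALSE]
  say("stage group_means: %d lncRNA x %d mRNA candidates", nrow(gm_lnc), nrow(gm_mrna))
  write_tsv_commented(gm_lnc, file.path(outdir, "group_means_lnc.tsv"), hdr("group_means"))
  write_tsv_commented(gm_mrna, file.path(outdir, "group_means_mrna.tsv"), hdr("group_means"))
  note("group_means")

  # 6. all-pairs permutation correlation
  say(
    "stage correlate: %d pairs, %s mode, %d permutations",
    nrow(gm_lnc) * nrow(gm_mrna), cfg$perm_mode, cfg$n_perms
  )
  edges <- in_stage("correlate", {
    if (nrow(gm_lnc) == 0 || nrow(gm_mrna) == 0) {
      abort("no candidate lncRNA-mRNA pairs after filtering")
    }
    correlate_all_pairs(gm_lnc, gm_mrna,
      n_perms = cfg$n_perms, comparison = cfg$comparison,
      seed = cfg$seed, mode = cfg$perm_mode
    )
  })
  write_edge_table(edges, file.path(outdir, "edges.tsv"), hdr("correlate"))
  note("correlate")

  # 7. network summaries + export
  conn <- in_stage("network", connectivity_summary(edges, cfg$thresholds))
  say(
    "stage network: fraction connected = %s",
    paste(sprintf("%.3f @ p<%g", conn$fraction_connected, conn$threshold), collapse = ", ")
  )
  write_tsv_commented(
    dplyr::select(conn, -"degree"),
    file.path(outdir, "connectivity_summary.tsv"), hdr("network")
  )
  net <- build_bipartite_network(edges, cfg$network_threshold)
  export_network(net, file.path(outdir, "network.graphml"), "graphml")
  note("network")

  manifest <- list(
    package = "lnclink",
    version = as.character(utils::packageVersion("lnclink")),
    config_hash = hash,
    seed = cfg$seed,
    n_perms = cfg$n_perms,
    comparison = cfg$comparison,
    perm_mode = cfg$perm_mode,
    percentile = cfg$percentile,
    thresholds = cfg$thresholds,
    stages = lapply(seq_along(stages), function(i) {
      list(name = names(stages)[i], status = unname(stages[i]))
    })
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )

  invisible(list(
    normalized = norm, de = de_list, de_ids = de_ids,
    group_means = list(lnc = gm_lnc, mrna = gm_mrna),
    edges = edges, connectivity = conn, network = net, manifest = manifest
  ))
}
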