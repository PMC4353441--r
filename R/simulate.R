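#' Simulation configuration
#'
#' Describes a synthetic dataset with the structure the pipeline assumes:
#' the two-strain, three-timepoint, sham/IR design (8 experimental groups,
#' 3 biological replicates each), a lncRNA/mRNA probe universe, planted
#' strain effects, planted radiation (LDIR) responses, and planted
#' lncRNA-to-mRNA coupling with analytically known group-mean correlation.
#'
#' Coupling: each regulator lncRNA j carries a latent per-group factor
#' z(j,g) ~ N(0,1); the regulator and each of its targets add a * z(j,g)
#' to their group-g log2 mean, with the loading a chosen so the population
#' correlation of two coupled group-mean vectors equals `coupling_strength`
#' exactly (a^2 = sigma_g^2 * c / (1 - c), where sigma_g = noise_sd_log2 /
#' sqrt(n_reps) is the group-mean noise sd). Coupled probes receive no
#' additional fixed effects, so the planted correlation is not disturbed.
#'
#' @param n_mrna,n_lnc Probe counts per class.
#' @param n_reps Biological replicates per group.
#' @param design Tibble of (strain, timepoint_weeks, treatment) rows; the
#'   default is the 8-group motivating design.
#' @param frac_de Fraction of (uncoupled) probes with a planted LDIR
#'   response.
#' @param de_effect_log2 Magnitude of the planted LDIR effect (log2 units,
#'   random sign), applied to the IR groups of one randomly chosen strain.
#' @param frac_strain_de,strain_effect_log2 Analogous planted baseline
#'   strain differences (applied to all SPRET groups).
#' @param n_regulators,targets_per_regulator Coupled lncRNA regulators and
#'   mRNA targets per regulator.
#' @param coupling_strength Population correlation of coupled group-mean
#'   vectors, in \[0, 1).
#' @param noise_sd_log2 Replicate noise sd (log2 units).
#' @param baseline_mean_log2,baseline_sd_log2 Per-probe baseline abundance
#'   distribution.
#' @param signature_fraction Fraction of planted-DE mRNA gene symbols put
#'   into the synthetic estrous signature.
#' @param seed Integer seed; the full output tuple is a pure function of
#'   the config including the seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_mrna = 2000, n_lnc = 800, n_reps = 3,
                       design = default_design(),
                       frac_de = 0.1, de_effect_log2 = 2,
                       frac_strain_de = 0.1, strain_effect_log2 = 1.5,
                       n_regulators = 50, targets_per_regulator = 5,
                       coupling_strength = 0.98,
                       noise_sd_log2 = 0.25,
                       baseline_mean_log2 = 8, baseline_sd_log2 = 2,
                       signature_fraction = 0.2,
                       seed = 1) {
  cfg <- list(
    n_mrna = n_mrna, n_lnc = n_lnc, n_reps = n_reps, design = design,
    frac_de = frac_de, de_effect_log2 = de_effect_log2,
    frac_strain_de = frac_strain_de, strain_effect_log2 = strain_effect_log2,
    n_regulators = n_regulators, targets_per_regulator = targets_per_regulator,
    coupling_strength = coupling_strength, noise_sd_log2 = noise_sd_log2,
    baseline_mean_log2 = baseline_mean_log2, baseline_sd_log2 = baseline_sd_log2,
    signature_fraction = signature_fraction, seed = seed
  )
  if (any(c(frac_de, frac_strain_de, signature_fraction) < 0) ||
      any(c(frac_de, frac_strain_de, signature_fraction) > 1)) {
    abort("fractions must lie in [0, 1]")
  }
  if (coupling_strength < 0 || coupling_strength >= 1) {
    abort("`coupling_strength` must lie in [0, 1)")
  }
  if (noise_sd_log2 <= 0) abort("`noise_sd_log2` must be > 0")
  if (n_regulators * targets_per_regulator > n_mrna) {
    abort("targets_per_regulator * n_regulators exceeds n_mrna")
  }
  if (n_regulators > n_lnc) abort("n_regulators exceeds n_lnc")
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_design <- function() {
  tibble::tibble(
    strain = c(rep("BALBc", 6), rep("SPRET", 2)),
    timepoint_weeks = c(2, 2, 4, 4, 8, 8, 4, 4),
    treatment = rep(c("sham", "IR"), 4)
  )
}

# run code under a seed without clobbering the caller's RNG state
with_sim_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a dataset with planted structure
#'
#' Generates the full input tuple the pipeline consumes — linear-scale
#' expression matrix, sample metadata, probe annotation, a synthetic
#' estrous signature — plus truth tables recording every planted effect
#' and coupled pair, so recovery can be scored exactly.
#'
#' Generative model, per probe i, group g, replicate k (log2 scale):
#' baseline_i + strain effect (if planted and g is SPRET) + LDIR effect
#' (if planted, g is an IR group of the probe's assigned strain) +
#' coupling term a * z(j,g) (coupled probes only) + N(0, noise_sd_log2)
#' replicate noise. The emitted matrix is 2^(log2 values).
#'
#' @param cfg A [sim_config()].
#' @return List: `expr` (linear `expr_tbl`), `samples`, `annotation`,
#'   `signature` ([gene_set()]), `truth` (list with `de` and `pairs`
#'   tibbles), and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_sim_seed(cfg$seed, {
    mrna_ids <- sprintf("mRNA_%05d", seq_len(cfg$n_mrna))
    lnc_ids <- sprintf("lnc_%05d", seq_len(cfg$n_lnc))
    ann <- probe_annotation(tibble::tibble(
      probe_id = c(mrna_ids, lnc_ids),
      probe_class = c(rep("mRNA", cfg$n_mrna), rep("lncRNA", cfg$n_lnc)),
      gene_symbol = c(sprintf("Gene%05d", seq_len(cfg$n_mrna)),
                      sprintf("Linc%05d", seq_len(cfg$n_lnc)))
    ))
    probe_ids <- ann$probe_id
    n_probes <- length(probe_ids)

    design <- cfg$design
    samples <- sample_table(tibble::tibble(
      sample_id = unlist(lapply(seq_len(nrow(design)), function(i) {
        sprintf(
          "%s_wk%g_%s_r%d", design$strain[i], design$timepoint_weeks[i],
          design$treatment[i], seq_len(cfg$n_reps)
        )
      })),
      strain = rep(design$strain, each = cfg$n_reps),
      timepoint_weeks = rep(design$timepoint_weeks, each = cfg$n_reps),
      treatment = rep(design$treatment, each = cfg$n_reps),
      dose_cGy = rep(ifelse(design$treatment == "IR", 10, 0), each = cfg$n_reps),
      replicate = rep(seq_len(cfg$n_reps), nrow(design))
    ))
    groups <- group_levels(samples)
    n_groups <- length(groups)
    grp_design <- design[match(
      groups,
      sprintf("%s_wk%g_%s", design$strain, design$timepoint_weeks, design$treatment)
    ), ]

    # --- coupled regulator/target probes (chosen first, kept effect-free)
    n_targets <- cfg$n_regulators * cfg$targets_per_regulator
    regulators <- if (cfg$n_regulators > 0) sample(lnc_ids, cfg$n_regulators) else character(0)
    targets <- if (n_targets > 0) sample(mrna_ids, n_targets) else character(0)
    pair_truth <- tibble::tibble(
      lnc_id = rep(regulators, each = cfg$targets_per_regulator),
      mrna_id = targets,
      coupling_strength = cfg$coupling_strength,
      expected_r = cfg$coupling_strength
    )
    coupled <- c(regulators, targets)

    # --- planted fixed effects among the uncoupled probes
    free <- setdiff(probe_ids, coupled)
    n_ldir <- round(cfg$frac_de * length(free))
    ldir_probes <- if (n_ldir > 0) sample(free, n_ldir) else character(0)
    ldir_strain <- sample(unique(design$strain), length(ldir_probes), replace = TRUE)
    ldir_sign <- sample(c(-1, 1), length(ldir_probes), replace = TRUE)

    free2 <- setdiff(free, ldir_probes)
    n_str <- round(cfg$frac_strain_de * length(free2))
    strain_probes <- if (n_str > 0) sample(free2, n_str) else character(0)
    strain_sign <- sample(c(-1, 1), length(strain_probes), replace = TRUE)
    strains <- sort(unique(design$strain))
    alt_strain <- if (length(strains) > 1) strains[2] else strains[1]

    truth_de <- dplyr::bind_rows(
      tibble::tibble(
        probe_id = ldir_probes, kind = "ldir", strain = ldir_strain,
        direction = as.character(ifelse(ldir_sign > 0, "up", "down")),
        effect_log2 = ldir_sign * cfg$de_effect_log2
      ),
      tibble::tibble(
        probe_id = strain_probes, kind = "strain",
        strain = rep(alt_strain, length(strain_probes)),
        direction = as.character(ifelse(strain_sign > 0, "up", "down")),
        effect_log2 = strain_sign * cfg$strain_effect_log2
      )
    )

    # --- group-level mean matrix (probes x groups), log2 scale
    baseline <- rnorm(n_probes, cfg$baseline_mean_log2, cfg$baseline_sd_log2)
    mu <- matrix(baseline, n_probes, n_groups,
      dimnames = list(probe_ids, groups)
    )
    if (length(strain_probes) > 0) {
      alt_cols <- which(grp_design$strain == alt_strain)
      mu[strain_probes, alt_cols] <- mu[strain_probes, alt_cols] +
        strain_sign * cfg$strain_effect_log2
    }
    if (length(ldir_probes) > 0) {
      for (s in unique(ldir_strain)) {
        rows <- ldir_probes[ldir_strain == s]
        cols <- which(grp_design$strain == s & grp_design$treatment == "IR")
        mu[rows, cols] <- mu[rows, cols] +
          (ldir_sign[ldir_strain == s]) * cfg$de_effect_log2
      }
    }
    if (cfg$n_regulators > 0 && cfg$coupling_strength > 0) {
      sigma_g <- cfg$noise_sd_log2 / sqrt(cfg$n_reps)
      a <- sigma_g * sqrt(cfg$coupling_strength / (1 - cfg$coupling_strength))
      z <- matrix(rnorm(cfg$n_regulators * n_groups), cfg$n_regulators, n_groups)
      for (j in seq_len(cfg$n_regulators)) {
        members <- c(regulators[j],
                     targets[seq((j - 1) * cfg$targets_per_regulator + 1,
                                 j * cfg$targets_per_regulator)])
        mu[members, ] <- sweep(mu[members, , drop = FALSE], 2, a * z[j, ], "+")
      }
    }

    # --- replicate-level log2 matrix, then back to linear intensities
    log2_vals <- mu[, as.character(samples$group), drop = FALSE] +
      matrix(rnorm(n_probes * nrow(samples), 0, cfg$noise_sd_log2),
             n_probes, nrow(samples))
    colnames(log2_vals) <- samples$sample_id
    expr <- expr_matrix(
      tibble::as_tibble(cbind(
        tibble::tibble(probe_id = probe_ids),
        tibble::as_tibble(2^log2_vals)
      )),
      scale = "linear"
    )

    # --- synthetic estrous signature: subset of planted-DE mRNA symbols
    de_mrna <- intersect(ldir_probes, mrna_ids)
    sig_symbols <- character(0)
    if (length(de_mrna) > 0 && cfg$signature_fraction > 0) {
      pick <- sample(de_mrna, round(cfg$signature_fraction * length(de_mrna)))
      sig_symbols <- ann$gene_symbol[match(pick, ann$probe_id)]
    }
    signature <- suppressWarnings(
      gene_set(sig_symbols, name = "synthetic_estrous_signature")
    )

    list(
      expr = expr, samples = samples, annotation = ann, signature = signature,
      truth = list(de = truth_de, pairs = pair_truth),
      config = cfg
    )
  })
}

#' Simulate one pair of group-mean vectors with known correlation
#'
#' Bivariate-normal construction: both vectors have sd `noise_sd` and
#' population correlation exactly `target_r`. Used as a unit-test and
#' calibration fixture generator for the permutation test.
#'
#' @param n_groups Vector length (>= 3); 8 in the motivating design.
#' @param target_r Population correlation, in \[-1, 1\].
#' @param noise_sd Marginal sd.
#' @param seed Optional seed (NULL uses the current RNG stream).
#' @return Tibble with columns `x` and `y`.
#' @export
simulate_pair <- function(n_groups = 8, target_r, noise_sd = 1, seed = NULL) {
  if (n_groups < 3) abort("`n_groups` must be >= 3")
  if (abs(target_r) > 1) abort("`target_r` must lie in [-1, 1]")
  gen <- function() {
    zx <- rnorm(n_groups)
    zy <- rnorm(n_groups)
    tibble::tibble(
      x = noise_sd * zx,
      y = noise_sd * (target_r * zx + sqrt(1 - target_r^2) * zy)
    )
  }
  if (is.null(seed)) gen() else with_sim_seed(seed, gen())
}
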