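# Small fixtures shared across test files; everything is built in code.

# probes x samples matrix of given values (by row), linear scale by default
tiny_expr <- function(values, n_probes, n_samples, scale = "linear",
                      probe_ids = sprintf("p%d", seq_len(n_probes)),
                      sample_ids = sprintf("s%d", seq_len(n_samples))) {
  m <- matrix(as.numeric(values), n_probes, n_samples, byrow = TRUE)
  tbl <- tibble::as_tibble(as.data.frame(m))
  names(tbl) <- sample_ids
  expr_matrix(dplyr::bind_cols(tibble::tibble(probe_id = probe_ids), tbl),
    scale = scale
  )
}

# the full 8-group x n_reps design as a sample table
design_samples <- function(n_reps = 3) {
  d <- default_design()
  sample_table(tibble::tibble(
    sample_id = unlist(lapply(seq_len(nrow(d)), function(i) {
      sprintf("%s_wk%g_%s_r%d", d$strain[i], d$timepoint_weeks[i],
              d$treatment[i], seq_len(n_reps))
    })),
    strain = rep(d$strain, each = n_reps),
    timepoint_weeks = rep(d$timepoint_weeks, each = n_reps),
    treatment = rep(d$treatment, each = n_reps),
    replicate = rep(seq_len(n_reps), nrow(d))
  ))
}

# draw a pair of independent standard-normal vectors of length n
null_pair <- function(n = 8) list(x = rnorm(n), y = rnorm(n))

# textbook pooled-variance two-sample t, written directly from the formula
oracle_t_test <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  df <- na + nb - 2
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# direct product-moment formula, independent of stats::cor
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# exact permutation p by brute-force enumeration in R (independent of the
# compiled engine); feasible for n <= 7 in tests
oracle_exhaustive_p <- function(x, y, absolute = TRUE) {
  n <- length(x)
  perms <- gtools_permutations(n)
  stat <- function(v) {
    r <- oracle_pearson(v, y)
    if (absolute) abs(r) else r
  }
  s0 <- stat(x)
  stats_all <- apply(perms, 1, function(idx) stat(x[idx]))
  list(p = mean(stats_all > s0 + 1e-12), n = nrow(perms))
}

# drop tibble metadata attributes so value comparisons see columns only
strip_attrs <- function(x) {
  x <- tibble::as_tibble(x)
  for (a in setdiff(names(attributes(x)), c("names", "row.names"))) {
    attr(x, a) <- NULL
  }
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

# all permutations of 1..n as rows (recursive, no extra packages)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub), n - 1))
  }))
}
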