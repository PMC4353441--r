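test_that("simulation is a pure function of config and seed", {
  cfg <- sim_config(n_mrna = 80, n_lnc = 30, n_regulators = 3,
                    targets_per_regulator = 2, seed = 51)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(expr_values(s1$expr), expr_values(s2$expr))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$signature$symbols, s2$signature$symbols)

  s3 <- simulate_dataset(sim_config(n_mrna = 80, n_lnc = 30, n_regulators = 3,
                                    targets_per_regulator = 2, seed = 52))
  expect_false(identical(expr_values(s1$expr), expr_values(s3$expr)))
})

test_that("the generated design has 8 groups x 3 replicates and valid objects", {
  sim <- simulate_dataset(sim_config(n_mrna = 50, n_lnc = 20, n_regulators = 2,
                                     targets_per_regulator = 2, seed = 53))
  expect_equal(nrow(sim$samples), 24L)
  expect_equal(length(group_levels(sim$samples)), 8L)
  expect_equal(expr_scale(sim$expr), "linear")
  expect_true(all(expr_values(sim$expr) > 0))
  expect_equal(nrow(sim$expr), 70L)
  # planted ids exist in the annotation; pair list has no duplicates
  expect_true(all(sim$truth$de$probe_id %in% sim$annotation$probe_id))
  pairs <- sim$truth$pairs
  expect_false(any(duplicated(paste(pairs$lnc_id, pairs$mrna_id))))
  expect_true(all(pairs$lnc_id %in% sim$annotation$probe_id[sim$annotation$probe_class == "lncRNA"]))
  expect_true(all(pairs$mrna_id %in% sim$annotation$probe_id[sim$annotation$probe_class == "mRNA"]))
})

test_that("a null config gives DE calls at roughly the nominal rate", {
  cfg <- sim_config(n_mrna = 2500, n_lnc = 500, frac_de = 0, frac_strain_de = 0,
                    n_regulators = 0, targets_per_regulator = 0, seed = 54)
  sim <- simulate_dataset(cfg)
  norm <- percentile_shift_normalize(log2_transform(sim$expr))
  de <- differential_expression(norm, sim$samples, default_contrasts(sim$samples)[[1]])
  rate <- mean(de$passes_p)
  ci <- 2.576 * sqrt(0.05 * 0.95 / nrow(de))
  expect_lt(abs(rate - 0.05), ci + 0.005)
  expect_equal(nrow(sim$truth$de), 0L)
})

test_that("planted coupling yields the advertised group-mean correlation", {
  cfg <- sim_config(n_mrna = 600, n_lnc = 250, n_regulators = 50,
                    targets_per_regulator = 4, coupling_strength = 0.98,
                    frac_de = 0, frac_strain_de = 0, seed = 55)
  sim <- simulate_dataset(cfg)
  norm <- percentile_shift_normalize(log2_transform(sim$expr))
  gm <- group_means(norm, sim$samples)
  pairs <- sim$truth$pairs # 200 planted pairs
  v <- as.matrix(gm[, -1])
  rownames(v) <- gm$probe_id
  rs <- vapply(seq_len(nrow(pairs)), function(i) {
    abs(cor(v[pairs$lnc_id[i], ], v[pairs$mrna_id[i], ]))
  }, numeric(1))
  expect_equal(mean(rs), 0.98, tolerance = 0.02 / 0.98)
})

test_that("simulate_pair controls the population correlation", {
  p1 <- simulate_pair(8, target_r = 1, seed = 56)
  expect_equal(cor(p1$x, p1$y), 1)

  # mean empirical r over many draws concentrates near the target
  set.seed(57)
  rs0 <- replicate(2000, with(simulate_pair(8, 0), cor(x, y)))
  expect_lt(abs(mean(rs0)), 0.02)
  rs9 <- replicate(10000, with(simulate_pair(8, 0.9), cor(x, y)))
  # finite-sample E[r] sits below the population value by the classical
  # first-order bias rho (1 - rho^2) / (2 (n - 1))
  expected <- 0.9 * (1 - (1 - 0.9^2) / (2 * (8 - 1)))
  expect_equal(mean(rs9), expected, tolerance = 0.01 / expected)

  expect_error(simulate_pair(2, 0.5), "n_groups")
  expect_error(simulate_pair(8, 1.5), "target_r")
})

test_that("config validation rejects impossible plantings", {
  expect_error(sim_config(n_mrna = 10, n_regulators = 5, targets_per_regulator = 3),
               "exceeds n_mrna")
  expect_error(sim_config(coupling_strength = 1), "coupling_strength")
  expect_error(sim_config(frac_de = 1.2), "fractions")
  expect_error(sim_config(noise_sd_log2 = 0), "noise_sd_log2")
})
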