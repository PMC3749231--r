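test_that("the generator is deterministic given the seed", {
  cfg <- simulation_config(n_proteins = 40, seed = 41)
  s1 <- simulate_psm(cfg)
  s2 <- simulate_psm(cfg)
  expect_identical(s1$psm, s2$psm)
  expect_identical(s1$truth$proteins, s2$truth$proteins)
  s3 <- simulate_psm(simulation_config(n_proteins = 40, seed = 42))
  expect_false(identical(s1$psm$i114, s3$psm$i114))

  # written tables are byte-identical too
  p1 <- tempfile(); p2 <- tempfile()
  write_psm_table(s1$psm, p1); write_psm_table(s2$psm, p2)
  expect_identical(readLines(p1), readLines(p2))
})

noiseless <- function(...) {
  simulation_config(technical_sd = 0, biological_sd = 0,
                    peptide_log2_sd = 0, channel_bias = c(1, 1, 1, 1),
                    decoy_rate = 0, unlabeled_rate = 0,
                    low_confidence_rate = 0, degenerate_rate = 0,
                    low_intensity_rate = 0, ...)
}

test_that("the noiseless null yields R = 0 for every protein", {
  cfg <- noiseless(n_proteins = 30, frac_differential = 0, seed = 43)
  sim <- simulate_psm(cfg)
  ints <- as.matrix(sim$psm[paste0("i", c(114, 115, 116, 117))])
  # all four channels of every peptide agree exactly
  for (k in 2:4) expect_equal(ints[, k], ints[, 1])
  q <- qualify_peptides(sim$psm)$qualified
  quant <- rollup(q, sim$design)
  stats <- differential_stats(quant)
  expect_equal(stats$R, rep(0, nrow(stats)))
  expect_equal(stats$S, rep(0, nrow(stats)))
})

test_that("a uniform 2-fold shift is recovered exactly without noise", {
  cfg <- noiseless(n_proteins = 25, frac_differential = 1, fc_mean = 1,
                   fc_sd = 0, fc_sign = "positive", seed = 44)
  sim <- simulate_psm(cfg)
  expect_true(all(sim$truth$proteins$delta == 1))
  # rollup on raw qualified peptides: normalization would re-center a
  # world where every protein changes
  quant <- rollup(qualify_peptides(sim$psm)$qualified, sim$design)
  stats <- differential_stats(quant)
  expect_equal(stats$R, rep(1, nrow(stats)), tolerance = 1e-12)
})

test_that("nuisance-record bookkeeping matches the qualification report", {
  cfg <- simulation_config(n_proteins = 150, decoy_rate = 0.05,
                           unlabeled_rate = 0.02, low_confidence_rate = 0.03,
                           degenerate_rate = 0.02, low_intensity_rate = 0.04,
                           seed = 45)
  sim <- simulate_psm(cfg)
  cnt <- sim$truth$counts
  expect_equal(nrow(sim$psm), cnt$n_real + cnt$n_decoy)
  rep <- qualify_peptides(sim$psm)
  expect_equal(rep$n_decoy_removed, cnt$n_decoy)
  # violations are injected on disjoint rows, so first-failing-criterion
  # attribution reproduces the generator counts exactly (criterion 4 may
  # additionally catch honestly faint peptides)
  expect_equal(unname(rep$n_failed_per_criterion[1:3]),
               c(cnt$n_unlabeled, cnt$n_low_confidence, cnt$n_degenerate))
  expect_gte(rep$n_failed_per_criterion[["dynamic_range"]],
             cnt$n_low_intensity)
  expect_equal(rep$labeled_fraction,
               100 * (cnt$n_real - cnt$n_unlabeled) / cnt$n_real)
})

test_that("species fractions follow the configuration", {
  cfg <- simulation_config(n_proteins = 400, frac_mouse = 0.1,
                           frac_shared = 0.25, seed = 46)
  tr <- simulate_psm(cfg)$truth$proteins
  expect_equal(sum(tr$species_class == "mouse_only"), 40L)
  expect_equal(sum(tr$species_class == "shared"), 100L)
  expect_true(all(tr$is_differential == (tr$delta != 0)))
})

test_that("technical duplicates share biology; sigma_S(t) vanishes with tau = 0", {
  cfg <- noiseless(n_proteins = 40, frac_differential = 0.1,
                   design_kind = "technical", seed = 47)
  cfg$biological_sd <- 0.4  # biology present but shared within tumor
  pair <- make_duplicate_pair(cfg)
  q <- qualify_peptides(pair$technical$psm)$qualified
  quant <- rollup(q, pair$technical$design)
  s <- s_value(quant$`T1/C1`, quant$`T2/C2`)
  expect_equal(s, rep(0, length(s)), tolerance = 1e-12)
  # the linked biological run sees the same proteome truth
  expect_identical(pair$technical$truth$proteins,
                   pair$biological$truth$proteins)
})

test_that("the pair supports tau/beta recovery at moderate scale", {
  cfg <- simulation_config(n_proteins = 800, peptides_dist = "fixed",
                           peptides_mean = 1, technical_sd = 0.245,
                           biological_sd = 0.3, frac_differential = 0,
                           seed = 48)
  pair <- make_duplicate_pair(cfg)
  run <- function(sim) {
    q <- qualify_peptides(sim$psm)$qualified
    quant <- rollup(normalize_psm(q, 2)$psm, sim$design)
    differential_stats(quant)$S
  }
  sig_t <- sd(run(pair$technical))
  sig_tot <- sd(run(pair$biological))
  # with one peptide per protein, sd(S) in the technical design is tau
  expect_equal(sig_t, 0.245, tolerance = 0.1)
  expect_equal(decompose_variance(sig_tot, sig_t), 0.3, tolerance = 0.1)
})

test_that("configuration validation rejects impossible worlds", {
  expect_error(simulation_config(frac_mouse = 0.7, frac_shared = 0.5),
               "must not exceed 1")
  expect_error(simulation_config(decoy_rate = 1.2), "rates")
  expect_error(simulation_config(technical_sd = -1), "non-negative")
  expect_error(simulation_config(n_proteins = 0), "at least one")
})
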