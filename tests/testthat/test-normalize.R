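test_that("peptide ratios divide by the reference channel", {
  flat <- make_psm(i114 = 100, i115 = 100, i116 = 100, i117 = 100)
  expect_equal(unname(peptide_ratios(flat)[1, ]), c(1, 1, 1, 1))

  one <- make_psm(i114 = 100, i115 = 200, i116 = 50, i117 = 100)
  expect_equal(unname(peptide_ratios(one, "114")[1, ]), c(1, 2, 0.5, 1))
  expect_equal(unname(peptide_ratios(one, "115")[1, ]), c(0.5, 1, 0.25, 0.5))

  zero <- make_psm(i114 = 0)
  expect_error(peptide_ratios(zero), "non-positive")
})

test_that("method 1 equalizes channel totals to the reference total", {
  # channel totals 100/200/100/50
  psm <- make_psm(2, i114 = c(60, 40), i115 = c(150, 50),
                  i116 = c(30, 70), i117 = c(20, 30))
  f <- fit_method1(psm)
  expect_equal(unname(f$factors), c(1, 0.5, 1, 2))

  equal <- make_biased_psm(c(10, 20, 30))
  expect_equal(unname(fit_method1(equal)$factors), rep(1, 4))

  single <- make_psm(i114 = 10, i115 = 20, i116 = 40, i117 = 80)
  expect_equal(unname(fit_method1(single)$factors), c(1, 0.5, 0.25, 0.125))

  # post-condition: all normalized sums equal the reference raw sum
  set.seed(5)
  rnd <- make_biased_psm(2^rnorm(50, 8, 1), bias = c(1, 1.3, 0.7, 1.1))
  nn <- apply_factors(rnd, fit_method1(rnd))
  sums <- colSums(as.matrix(nn[paste0("i", c(114, 115, 116, 117))]))
  expect_equal(unname(sums / sums[1]), rep(1, 4), tolerance = 1e-12)

  zero_total <- make_psm(i116 = 0)
  expect_error(fit_method1(zero_total), "zero total")
})

test_that("method 2 centers the median log2 ratio at zero", {
  # channel 115 ratios {2, 2, 8}: median log2 = 1, factor 0.5
  psm <- make_psm(3, i114 = c(10, 20, 40), i115 = c(20, 40, 320))
  f <- fit_method2(psm)
  expect_equal(unname(f$factors["115"]), 0.5)
  expect_equal(unname(f$factors["114"]), 1)  # reference factor

  centered <- make_psm(3, i114 = c(10, 10, 10), i115 = c(5, 10, 20))
  expect_equal(unname(fit_method2(centered)$factors["115"]), 1)

  # exact post-condition on arbitrary data, and fixed point on re-fit
  set.seed(6)
  rnd <- make_biased_psm(2^rnorm(101, 8, 1.5), bias = c(1, 2.2, 0.4, 1.3))
  rnd[paste0("i", c(114, 115, 116, 117))] <-
    rnd[paste0("i", c(114, 115, 116, 117))] * 2^matrix(rnorm(404, 0, 0.3), 101, 4)
  nn <- apply_factors(rnd, fit_method2(rnd))
  med <- apply(log2(peptide_ratios(nn)), 2, median)
  expect_equal(unname(med), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(fit_method2(nn)$factors), rep(1, 4), tolerance = 1e-12)
})

test_that("trend-line methods recover a pure channel scaling", {
  set.seed(7)
  base <- 2^rnorm(60, 8, 1)
  doubled <- make_biased_psm(base, bias = c(1, 2, 1, 1))
  expect_equal(unname(fit_method3(doubled)$factors["115"]), 0.5,
               tolerance = 1e-12)
  expect_equal(unname(fit_method4(doubled)$factors["115"]), 0.5,
               tolerance = 1e-12)

  same <- make_biased_psm(base)
  expect_equal(unname(fit_method3(same)$factors), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(fit_method4(same)$factors), rep(1, 4), tolerance = 1e-12)

  expect_error(fit_method3(make_psm(2, i114 = c(5, 5))), "degenerate")
})

test_that("method 7 shifts the protein-level median to zero", {
  expect_equal(fit_method7(c(0.2, 0.4, 0.6)), -0.4)
  expect_equal(fit_method7(c(-1, 0, 1)), 0)
  expect_equal(fit_method7(1.0), -1.0)
  expect_error(fit_method7(numeric(0)), "no protein ratios")
})

test_that("apply_factors rescales channels and preserves order", {
  psm <- make_psm(2, i115 = c(200, 100))
  ident <- normalization_factors(setNames(rep(1, 4), c("114", "115", "116", "117")),
                                 1L, "114")
  expect_equal(apply_factors(psm, ident), psm)
  half <- normalization_factors(setNames(c(1, 0.5, 1, 1), c("114", "115", "116", "117")),
                                1L, "114")
  expect_equal(apply_factors(psm, half)$i115, c(100, 50))
  expect_equal(apply_factors(psm, half)$spectrum_id, psm$spectrum_id)
})

test_that("fits are invariant to record order and global rescaling", {
  set.seed(8)
  psm <- make_biased_psm(2^rnorm(40, 8, 1), bias = c(1, 1.4, 0.8, 1.2))
  psm[paste0("i", c(114, 115, 116, 117))] <-
    psm[paste0("i", c(114, 115, 116, 117))] * 2^matrix(rnorm(160, 0, 0.2), 40, 4)
  perm <- psm[sample(nrow(psm)), ]
  scaled <- psm
  scaled[paste0("i", c(114, 115, 116, 117))] <-
    scaled[paste0("i", c(114, 115, 116, 117))] * 7.3
  for (fit in list(fit_method1, fit_method2, fit_method3, fit_method4)) {
    f0 <- unname(fit(psm)$factors)
    expect_equal(unname(fit(perm)$factors), f0, tolerance = 1e-10)
    expect_equal(unname(fit(scaled)$factors), f0, tolerance = 1e-10)
  }
})

test_that("an injected 2x channel bias is removed by methods 1 and 2", {
  cfg <- simulation_config(n_proteins = 300, channel_bias = c(1, 2, 1, 1),
                           frac_differential = 0, technical_sd = 0.1,
                           biological_sd = 0, seed = 9)
  q <- qualify_peptides(simulate_psm(cfg)$psm)$qualified
  for (method in 1:2) {
    nn <- normalize_psm(q, method)$psm
    med <- apply(log2(peptide_ratios(nn)), 2, median)
    if (method == 2) {
      expect_equal(unname(med), rep(0, 4), tolerance = 1e-9)
    } else {
      # method 1 equalizes sums; the residual median offset must be far
      # smaller than the injected log2 bias of 1
      expect_lt(max(abs(med)), 0.05)
    }
  }
  # and without normalization the bias is plainly visible
  med_raw <- apply(log2(peptide_ratios(q)), 2, median)
  expect_gt(abs(med_raw[2]), 0.9)
})

test_that("evaluate_normalization summarizes per-protein S values", {
  # identical paired ratios: no error at all
  quant0 <- data.frame(`T1/C1` = c(1.5, 0.8), `T2/C2` = c(1.5, 0.8),
                       check.names = FALSE)
  ev0 <- evaluate_normalization(quant0)
  expect_equal(ev0$mean_S, 0)
  expect_equal(ev0$sd_S, 0)

  # S values {+0.1, -0.1}: mean 0; sd 0.1 population, ~0.1414 sample
  quant1 <- data.frame(`T1/C1` = c(2^0.2, 1), `T2/C2` = c(1, 2^0.2),
                       check.names = FALSE)
  expect_equal(evaluate_normalization(quant1)$mean_S, 0)
  expect_equal(evaluate_normalization(quant1, "population")$sd_S, 0.1)
  expect_equal(evaluate_normalization(quant1, "sample")$sd_S, 0.1 * sqrt(2))

  expect_error(evaluate_normalization(quant0[1, ]), "at least 2")
})

test_that("on null data method 2 drives the mean S toward zero", {
  cfg <- simulation_config(n_proteins = 2000, frac_differential = 0,
                           design_kind = "biological", seed = 10)
  sim <- simulate_psm(cfg)
  q <- qualify_peptides(sim$psm)$qualified
  quant <- rollup(normalize_psm(q, 2)$psm, sim$design)
  ev <- evaluate_normalization(quant)
  expect_lt(abs(ev$mean_S), 0.02)
})

test_that("duplicate-channel reproducibility is the squared correlation", {
  psm <- make_biased_psm(2^rnorm(30, 8, 1))
  expect_equal(evaluate_reproducibility(psm, "114", "114"), 1)
  doubled <- make_biased_psm(2^rnorm(30, 8, 1), bias = c(1, 2, 1, 1))
  expect_equal(evaluate_reproducibility(doubled, "114", "115"), 1)
  expect_error(evaluate_reproducibility(make_psm(2), "114", "115"),
               "constant")

  # technical duplicates with ~5% multiplicative noise stay above 0.97
  cfg <- simulation_config(n_proteins = 500, design_kind = "technical",
                           technical_sd = 0.07, frac_differential = 0,
                           channel_bias = c(1, 1, 1, 1), seed = 12)
  q <- qualify_peptides(simulate_psm(cfg)$psm)$qualified
  expect_gt(evaluate_reproducibility(q, "114", "115"), 0.97)
  expect_gt(evaluate_reproducibility(q, "116", "117"), 0.97)
})
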