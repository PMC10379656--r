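test_that("the generator is deterministic given its config", {
  cfg <- sim_config(n_subjects = 100, n_snps = 20, seed = 99)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$genotypes$genotypes, b$genotypes$genotypes)
  expect_identical(a$cohort, b$cohort)
})

test_that("genotype frequencies follow HWE proportions", {
  cfg <- sim_config(
    n_subjects = 4000, n_snps = 5, maf_range = c(0.5, 0.5), seed = 101
  )
  g <- simulate_genotypes(cfg)$genotypes
  for (j in 1:5) {
    freqs <- tabulate(g[, j] + 1L, nbins = 3) / 4000
    # binomial 3-sigma bands around (0.25, 0.5, 0.25)
    expect_lt(abs(freqs[1] - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))
    expect_lt(abs(freqs[2] - 0.50), 3 * sqrt(0.5 * 0.5 / 4000))
    expect_lt(abs(freqs[3] - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))
  }
})

test_that("simulated SNPs pass the HWE filter essentially always", {
  cfg <- sim_config(n_subjects = 2000, n_snps = 300, seed = 103)
  g <- simulate_genotypes(cfg)$genotypes
  p <- apply(g, 2, function(col) {
    hwe_exact_test(sum(col == 2), sum(col == 1), sum(col == 0))
  })
  expect_equal(mean(p >= 1e-6), 1)
})

test_that("realized variance components converge to their targets", {
  cfg <- sim_config(
    n_subjects = 50000, n_snps = 6, covariate_r2 = 0.093,
    planted_pairs = list(list(snp1 = 1, snp2 = 2, frac = 0.056)),
    planted_mains = list(list(snp = 3, frac = 0.02)),
    seed = 107
  )
  st <- simulate_study(cfg)
  truth <- st$truth
  G <- st$genotypes$genotypes
  maf <- st$genotypes$snps$maf
  # realized variance of each planted component, scaled back from the log
  # phenotype to the unit-variance latent scale
  int_comp <- truth$coef$interactions[1] *
    (G[, 1] - 2 * maf[1]) * (G[, 2] - 2 * maf[2])
  main_comp <- truth$coef$mains[1] * (G[, 3] - 2 * maf[3])
  expect_equal(var(int_comp), 0.056, tolerance = 0.10)
  expect_equal(var(main_comp), 0.02, tolerance = 0.10)
  # total latent variance near 1 (components are mutually uncorrelated)
  y <- normalize_phenotype(st$cohort$ptau, "log")
  latent <- (y - truth$transform[["mu_log"]]) / truth$transform[["scale"]]
  expect_equal(var(latent), 1, tolerance = 0.05)
})

test_that("cds groups mirror the configured cohort proportions", {
  cfg <- sim_config(n_subjects = 20000, n_snps = 2, seed = 109)
  st <- simulate_study(cfg)
  frac <- table(st$cohort$cds)[c("CN", "SMC", "EMCI", "LMCI", "AD")] / 20000
  target <- c(201, 84, 251, 209, 115) / 860
  expect_lt(max(abs(frac - target)), 4 * sqrt(max(target) * (1 - min(target)) / 20000))
  expect_true(all(st$cohort$ptau > 0))
})

test_that("fitted interaction coefficients are unbiased across replicates", {
  alphas <- numeric(60)
  truths <- numeric(60)
  for (r in 1:60) {
    cfg <- sim_config(
      n_subjects = 400, n_snps = 4,
      planted_pairs = list(list(snp1 = 1, snp2 = 2, frac = 0.05)),
      seed = 300 + r
    )
    st <- simulate_study(cfg)
    y <- normalize_phenotype(st$cohort$ptau, "log")
    covs <- build_design(st$cohort)
    fit <- pair_interaction_test(
      st$genotypes$genotypes[, 1], st$genotypes$genotypes[, 2], y, covs
    )
    alphas[r] <- fit$coefficients[["alpha12"]]
    truths[r] <- st$truth$coef$interactions[1] * st$truth$transform[["scale"]]
  }
  bias <- mean(alphas - truths)
  mc_se <- sd(alphas - truths) / sqrt(60)
  expect_lt(abs(bias), 2 * mc_se + 1e-12)
})

test_that("an infeasible variance budget is rejected", {
  expect_error(
    sim_config(
      covariate_r2 = 0.5,
      planted_pairs = list(list(snp1 = 1, snp2 = 2, frac = 0.6))
    ),
    "infeasible"
  )
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(
    sim_config(n_snps = 5, planted_pairs = list(list(snp1 = 1, snp2 = 9, frac = 0.1))),
    "out of range"
  )
})

test_that("power is near alpha with no effect and high for a strong effect", {
  cfg0 <- sim_config(
    n_subjects = 200, n_snps = 10,
    planted_pairs = list(list(snp1 = 1, snp2 = 2, frac = 0)), seed = 113
  )
  out0 <- estimate_power_and_type1(cfg0,
    n_reps = 60, power_alpha = 0.05, n_null_pairs = 4
  )
  p0 <- out0$rate[out0$kind == "power"]
  expect_lt(p0, 0.25) # null effect: power collapses toward alpha
  t1 <- out0$rate[out0$kind == "type1"]
  band <- qbinom(c(0.005, 0.995), out0$n[out0$kind == "type1"], 0.05) /
    out0$n[out0$kind == "type1"]
  expect_gte(t1, band[1])
  expect_lte(t1, band[2])

  cfg1 <- sim_config(
    n_subjects = 500, n_snps = 10,
    planted_pairs = list(list(snp1 = 1, snp2 = 2, frac = 0.1)), seed = 127
  )
  out1 <- estimate_power_and_type1(cfg1,
    n_reps = 40, power_alpha = 1e-6, n_null_pairs = 0
  )
  expect_gte(out1$rate[out1$kind == "power"], 0.9)
})

test_that("block-LD mode induces correlation while preserving HWE", {
  cfg <- sim_config(
    n_subjects = 3000, n_snps = 10, maf_range = c(0.3, 0.3),
    ld = list(block_size = 5, rho = 0.9), seed = 131
  )
  g <- simulate_genotypes(cfg)$genotypes
  # strong correlation within a block, none across blocks
  expect_gt(cor(g[, 1], g[, 2]), 0.5)
  expect_lt(abs(cor(g[, 5], g[, 6])), 0.1)
  p <- apply(g, 2, function(col) {
    hwe_exact_test(sum(col == 2), sum(col == 1), sum(col == 0))
  })
  expect_true(all(p > 1e-6))
})

test_that("missingness injection is seeded and bounded", {
  cfg <- sim_config(n_subjects = 200, n_snps = 20, seed = 137)
  g <- simulate_genotypes(cfg)
  gm1 <- add_missingness(g, 0.05, seed = 7)
  gm2 <- add_missingness(g, 0.05, seed = 7)
  expect_identical(gm1$genotypes, gm2$genotypes)
  expect_equal(mean(is.na(gm1$genotypes)), 0.05, tolerance = 0.3)
})
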