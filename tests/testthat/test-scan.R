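test_that("degenerate panels give empty results", {
  cfg <- sim_config(n_subjects = 50, n_snps = 1, seed = 2)
  st <- simulate_study(cfg)
  y <- normalize_phenotype(st$cohort$ptau, "log")
  covs <- build_design(st$cohort)
  out <- scan_all_pairs(st$genotypes, y, covs)
  expect_s3_class(out, "epi_scan")
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "n_tests"), 0)
})

test_that("blocked scan equals the naive oracle on every pair", {
  cfg <- sim_config(
    n_subjects = 200, n_snps = 20,
    planted_pairs = list(list(snp1 = 3, snp2 = 7, frac = 0.15)), seed = 5
  )
  st <- simulate_study(cfg)
  y <- normalize_phenotype(st$cohort$ptau, "log")
  covs <- build_design(st$cohort)
  out <- scan_all_pairs(st$genotypes, y, covs,
    p_threshold = 1, block_size = 6, refit_coefficients = FALSE
  )
  expect_equal(nrow(out), choose(20, 2))
  G <- st$genotypes$genotypes
  id <- st$genotypes$snps$snp_id
  for (k in seq_len(nrow(out))) {
    o <- oracle_pair_ols(G[, match(out$snp1[k], id)], G[, match(out$snp2[k], id)], y, covs)
    expect_equal(out$F[k], o$F, tolerance = 1e-8)
    expect_equal(out$p[k], o$p, tolerance = 1e-10)
  }
  # planted pair is the most significant
  expect_setequal(c(out$snp1[1], out$snp2[1]), id[c(3, 7)])
})

test_that("block size never changes reported statistics", {
  cfg <- sim_config(n_subjects = 120, n_snps = 15, seed = 13)
  st <- simulate_study(cfg)
  g <- add_missingness(st$genotypes, 0.04, seed = 4)
  y <- normalize_phenotype(st$cohort$ptau, "log")
  covs <- build_design(st$cohort)
  runs <- lapply(c(1, 7, 1000), function(b) {
    scan_all_pairs(g, y, covs, p_threshold = 1, block_size = b)
  })
  expect_identical(runs[[1]]$F, runs[[2]]$F)
  expect_identical(runs[[2]]$F, runs[[3]]$F)
  expect_identical(runs[[1]]$p, runs[[3]]$p)
})

test_that("pairs with missing genotypes use their own complete-case subsets", {
  cfg <- sim_config(n_subjects = 100, n_snps = 8, seed = 19)
  st <- simulate_study(cfg)
  g <- add_missingness(st$genotypes, 0.1, seed = 6)
  y <- normalize_phenotype(st$cohort$ptau, "log")
  covs <- build_design(st$cohort)
  out <- scan_all_pairs(g, y, covs, p_threshold = 1)
  G <- g$genotypes
  id <- g$snps$snp_id
  for (k in seq_len(nrow(out))) {
    i <- match(out$snp1[k], id)
    j <- match(out$snp2[k], id)
    expect_equal(out$n_used[k], sum(!is.na(G[, i]) & !is.na(G[, j])))
    o <- oracle_pair_ols(G[, i], G[, j], y, covs)
    expect_equal(out$F[k], o$F, tolerance = 1e-8)
  }
})

test_that("scan results are symmetric under SNP order reversal", {
  cfg <- sim_config(n_subjects = 150, n_snps = 10, seed = 23)
  st <- simulate_study(cfg)
  y <- normalize_phenotype(st$cohort$ptau, "log")
  covs <- build_design(st$cohort)
  fwd <- scan_all_pairs(st$genotypes, y, covs, p_threshold = 1)
  rev_g <- st$genotypes[, 10:1]
  bwd <- scan_all_pairs(rev_g, y, covs, p_threshold = 1)
  key <- function(x) paste(pmin(x$snp1, x$snp2), pmax(x$snp1, x$snp2))
  expect_setequal(key(fwd), key(bwd))
  expect_equal(fwd$F[order(key(fwd))], bwd$F[order(key(bwd))], tolerance = 1e-10)
  # alpha1/alpha2 swap when the pair order flips
  k_f <- which(key(fwd) == key(fwd)[1])
  k_b <- which(key(bwd) == key(fwd)[1])
  if (fwd$snp1[k_f] != bwd$snp1[k_b]) {
    expect_equal(fwd$alpha1[k_f], bwd$alpha2[k_b], tolerance = 1e-8)
    expect_equal(fwd$alpha2[k_f], bwd$alpha1[k_b], tolerance = 1e-8)
  }
})

test_that("F and p are invariant to affine transformations of the phenotype", {
  cfg <- sim_config(n_subjects = 120, n_snps = 8, seed = 29)
  st <- simulate_study(cfg)
  y <- normalize_phenotype(st$cohort$ptau, "log")
  covs <- build_design(st$cohort)
  a <- scan_all_pairs(st$genotypes, y, covs, p_threshold = 1)
  b <- scan_all_pairs(st$genotypes, 3.7 * y + 11, covs, p_threshold = 1)
  expect_equal(a$F, b$F, tolerance = 1e-9)
  expect_equal(a$p, b$p, tolerance = 1e-9)
})

test_that("significance threshold filters and bonferroni default applies", {
  cfg <- sim_config(
    n_subjects = 300, n_snps = 12,
    planted_pairs = list(list(snp1 = 1, snp2 = 2, frac = 0.15)), seed = 37
  )
  st <- simulate_study(cfg)
  y <- normalize_phenotype(st$cohort$ptau, "log")
  covs <- build_design(st$cohort)
  out <- scan_all_pairs(st$genotypes, y, covs) # bonferroni
  expect_equal(attr(out, "p_threshold"), 0.05 / choose(12, 2))
  expect_true(all(out$p < attr(out, "p_threshold") | out$flag != "ok"))
  expect_true(nrow(out) >= 1)
  expect_equal(out$snp1[1], "snp00001")
  expect_equal(out$snp2[1], "snp00002")
  # scan p equals the single-pair fit
  fit <- pair_interaction_test(
    st$genotypes$genotypes[, 1], st$genotypes$genotypes[, 2], y, covs
  )
  expect_equal(out$F[1], fit$f_stat, tolerance = 1e-10)
})
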