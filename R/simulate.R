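CDS_PROBS <- c(CN = 201, SMC = 84, EMCI = 251, LMCI = 209, AD = 115) / 860
CDS_PATTERN <- c(CN = 0, SMC = 0.15, EMCI = 0.3, LMCI = 0.5, AD = 1)
COV_SHARES <- c(age = 0.35, gender = 0.05, cds = 0.60)

#' Simulation configuration
#'
#' Describes a synthetic cohort with the statistical structure the
#' interaction analysis assumes: biallelic autosomal SNPs in
#' Hardy-Weinberg proportions with MAF drawn uniformly from `maf_range`,
#' covariates (age, gender, clinical diagnostic status) explaining a target
#' fraction of phenotype variance, optional planted additive and epistatic
#' effects with specified population variance fractions, and Gaussian noise
#' absorbing the remainder so the latent phenotype has unit variance. The
#' defaults mirror the cohort the analysis targets: 860 subjects, a 9.3%
#' covariate variance share, and diagnostic-group proportions
#' (201, 84, 251, 209, 115)/860.
#'
#' @param n_subjects Number of subjects (default 860).
#' @param n_snps Number of SNPs (default 100).
#' @param maf_range Lower/upper bound for the per-SNP minor allele
#'   frequency, a subset of (0, 0.5] (default `c(0.05, 0.5)`, the post-QC
#'   spectrum).
#' @param covariate_r2 Fraction of phenotype variance carried by the
#'   covariates jointly (default 0.093), split age/gender/cds as
#'   0.35/0.05/0.60 of the total.
#' @param planted_pairs List of `list(snp1 =, snp2 =, frac =)` entries: SNP
#'   column indices and the fraction of phenotype variance the pair's
#'   interaction term explains beyond the main effects.
#' @param planted_mains List of `list(snp =, frac =)` entries for additive
#'   single-SNP effects.
#' @param ld List `list(block_size =, rho =)` to simulate autoregressive
#'   allele correlation within consecutive SNP blocks (default `NULL`:
#'   independent SNPs).
#' @param seed Integer seed; the whole generation chain is deterministic
#'   given the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 860, n_snps = 100,
                       maf_range = c(0.05, 0.5), covariate_r2 = 0.093,
                       planted_pairs = list(), planted_mains = list(),
                       ld = NULL, seed = 1) {
  stopifnot(
    n_subjects >= 1, n_snps >= 1,
    length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2],
    covariate_r2 >= 0, covariate_r2 < 1
  )
  planted <- c(
    purrr::map_dbl(planted_pairs, "frac"),
    purrr::map_dbl(planted_mains, "frac")
  )
  if (length(planted) > 0 && any(planted < 0)) abort("variance fractions must be >= 0")
  if (covariate_r2 + sum(planted) >= 1) {
    abort("variance budget infeasible: covariate_r2 + planted fractions must be < 1")
  }
  idx <- c(
    unlist(purrr::map(planted_pairs, ~ c(.x$snp1, .x$snp2))),
    purrr::map_dbl(planted_mains, "snp")
  )
  if (length(idx) > 0 && (any(idx < 1) || any(idx > n_snps))) {
    abort("planted SNP indices out of range")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), n_snps = as.integer(n_snps),
      maf_range = maf_range, covariate_r2 = covariate_r2,
      planted_pairs = planted_pairs, planted_mains = planted_mains,
      ld = ld, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a genotype panel in Hardy-Weinberg proportions
#'
#' Each SNP's allele-1 frequency is drawn uniformly from the configured MAF
#' range and each genotype is the sum of two independent allele draws, so
#' genotype frequencies follow HWE proportions (p^2, 2pq, q^2) exactly in
#' expectation. With `ld` set, the allele draws of consecutive SNPs within
#' a block are correlated through a first-order autoregressive Gaussian
#' copula, preserving per-SNP HWE while inducing linkage disequilibrium.
#'
#' @param config A [sim_config()].
#' @return A [geno_matrix()] with the drawn `maf` recorded as an extra
#'   column of the SNP tibble.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  m <- config$n_snps
  maf <- runif(m, config$maf_range[1], config$maf_range[2])

  if (is.null(config$ld)) {
    g <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), nrow = n, ncol = m)
  } else {
    rho <- config$ld$rho
    bs <- config$ld$block_size
    draw_alleles <- function() {
      z <- matrix(rnorm(n * m), nrow = n, ncol = m)
      for (j in seq_len(m)[-1]) {
        if ((j - 1) %/% bs == (j - 2) %/% bs) { # same block as predecessor
          z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
        }
      }
      sweep(z, 2, qnorm(maf), `<`) * 1L
    }
    g <- draw_alleles() + draw_alleles()
  }

  chr <- rep_len(1:22, m)
  snps <- tibble(
    snp_id = sprintf("snp%05d", seq_len(m)),
    chr = chr,
    pos = 10000L * (seq_len(m) + 100L),
    a1 = "A", a2 = "G",
    maf = maf
  )
  geno_matrix(g, snps = snps, subjects = sprintf("subj%05d", seq_len(n)))
}

#' Simulate a cohort with a planted phenotype architecture
#'
#' Draws age uniformly on 55-90 years, gender Bernoulli(0.5), and clinical
#' diagnostic status from the configured group proportions, then builds a
#' unit-variance latent phenotype as the sum of scaled covariate effects,
#' planted additive effects on mean-centred genotypes, planted interaction
#' effects on centred genotype products, and Gaussian noise.
#'
#' Coefficients are solved analytically from population variances: a
#' centred genotype with allele frequency p has variance 2p(1-p), and the
#' centred product of two independent HWE genotypes has variance
#' 4 p1 (1-p1) p2 (1-p2) and is uncorrelated with both main-effect columns,
#' so a planted fraction f yields coefficient sqrt(f / variance) and the
#' hierarchical interaction delta R-squared converges to f. The reported
#' P-tau concentration is `exp(log(25) + 0.35 * latent)` pg/mL, so the
#' default log phenotype transform of the QC module recovers the linear
#' model exactly (R-squared fractions are affine-invariant).
#'
#' @param config The [sim_config()] used for [simulate_genotypes()].
#' @param genotypes The matching [geno_matrix()].
#' @return A cohort tibble (`subject_id`, `ptau`, `age`, `gender`, `cds`,
#'   `complete`) with the latent truth (coefficients, component variances,
#'   noise variance, transform constants) in attribute `truth`.
#' @export
simulate_cohort <- function(config, genotypes) {
  stopifnot(inherits(config, "sim_config"), inherits(genotypes, "geno_matrix"))
  set.seed(config$seed + 1L)
  n <- config$n_subjects
  stopifnot(n_subjects(genotypes) == n)

  age <- runif(n, 55, 90)
  gender <- rbinom(n, 1L, 0.5)
  cds <- sample(names(CDS_PROBS), n, replace = TRUE, prob = CDS_PROBS)

  # covariate effects scaled to their analytic population variances
  var_age <- (90 - 55)^2 / 12
  var_gender <- 0.25
  t_mean <- sum(CDS_PROBS * CDS_PATTERN)
  var_pattern <- sum(CDS_PROBS * CDS_PATTERN^2) - t_mean^2
  b_age <- sqrt(config$covariate_r2 * COV_SHARES[["age"]] / var_age)
  b_gender <- sqrt(config$covariate_r2 * COV_SHARES[["gender"]] / var_gender)
  b_cds <- sqrt(config$covariate_r2 * COV_SHARES[["cds"]] / var_pattern)
  cds_effect <- b_cds * (CDS_PATTERN[cds] - t_mean)
  latent <- b_age * (age - 72.5) + b_gender * (gender - 0.5) + cds_effect

  G <- genotypes$genotypes
  maf <- genotypes$snps$maf
  if (is.null(maf)) abort("genotypes must come from simulate_genotypes() (maf column required)")
  v_g <- 2 * maf * (1 - maf)

  beta_main <- purrr::map_dbl(config$planted_mains, function(pm) {
    sqrt(pm$frac / v_g[pm$snp])
  })
  for (k in seq_along(config$planted_mains)) {
    pm <- config$planted_mains[[k]]
    latent <- latent + beta_main[k] * (G[, pm$snp] - 2 * maf[pm$snp])
  }
  alpha_int <- purrr::map_dbl(config$planted_pairs, function(pp) {
    sqrt(pp$frac / (v_g[pp$snp1] * v_g[pp$snp2]))
  })
  for (k in seq_along(config$planted_pairs)) {
    pp <- config$planted_pairs[[k]]
    latent <- latent +
      alpha_int[k] * (G[, pp$snp1] - 2 * maf[pp$snp1]) * (G[, pp$snp2] - 2 * maf[pp$snp2])
  }

  planted_total <- sum(purrr::map_dbl(config$planted_pairs, "frac")) +
    sum(purrr::map_dbl(config$planted_mains, "frac"))
  sigma2 <- 1 - config$covariate_r2 - planted_total
  latent <- latent + rnorm(n, 0, sqrt(sigma2))

  mu_log <- log(25)
  scale_log <- 0.35
  cohort <- tibble(
    subject_id = genotypes$subjects,
    ptau = exp(mu_log + scale_log * latent),
    age = age,
    gender = gender,
    cds = cds,
    complete = TRUE
  )
  attr(cohort, "truth") <- list(
    covariate_r2 = config$covariate_r2,
    coef = list(
      age = unname(b_age), gender = unname(b_gender), cds = unname(b_cds),
      mains = beta_main, interactions = alpha_int
    ),
    planted_pairs = config$planted_pairs,
    planted_mains = config$planted_mains,
    sigma2 = sigma2,
    transform = c(mu_log = mu_log, scale = scale_log)
  )
  cohort
}

#' Simulate genotypes and cohort in one call
#'
#' @param config A [sim_config()].
#' @return List with `genotypes`, `cohort` and `truth`.
#' @export
simulate_study <- function(config) {
  genotypes <- simulate_genotypes(config)
  cohort <- simulate_cohort(config, genotypes)
  list(genotypes = genotypes, cohort = cohort, truth = attr(cohort, "truth"))
}

#' Punch missing-at-random holes into a genotype matrix
#'
#' @param genotypes A [geno_matrix()].
#' @param rate Per-entry missingness probability.
#' @param seed Integer seed.
#' @return The [geno_matrix()] with entries set to `NA` at random.
#' @export
add_missingness <- function(genotypes, rate, seed = 1) {
  stopifnot(inherits(genotypes, "geno_matrix"), rate >= 0, rate < 1)
  set.seed(seed)
  g <- genotypes$genotypes
  g[runif(length(g)) < rate] <- NA_integer_
  geno_matrix(g, snps = genotypes$snps, subjects = genotypes$subjects)
}

#' Empirical power and type-I error of the interaction test
#'
#' Replicates the generator, applies the default log phenotype transform,
#' and records for every planted pair the fraction of replicates whose
#' interaction p-value falls below `power_alpha`, and across replicates the
#' fraction of evaluated null pairs (disjoint pairs of non-planted SNPs)
#' below `null_alpha`. Binomial standard errors are attached.
#'
#' @param config A [sim_config()]; replicate r uses seed `seed + 2*r`.
#' @param n_reps Number of replicates (>= 100 recommended for stable
#'   estimates).
#' @param power_alpha Significance level for the power estimate (default
#'   1e-8, a genome-wide scale).
#' @param null_alpha Nominal level for the type-I estimate (default 0.05).
#' @param n_null_pairs Null pairs evaluated per replicate (default 50).
#' @return Tibble with columns `kind` ("power"/"type1"), `label`, `alpha`,
#'   `n`, `rate`, `se`.
#' @export
estimate_power_and_type1 <- function(config, n_reps = 100, power_alpha = 1e-8,
                                     null_alpha = 0.05, n_null_pairs = 50) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1)
  planted_idx <- unique(unlist(purrr::map(
    config$planted_pairs, ~ c(.x$snp1, .x$snp2)
  )))
  free <- setdiff(seq_len(config$n_snps), planted_idx)
  null_i <- free[c(TRUE, FALSE)][seq_len(min(n_null_pairs, length(free) %/% 2))]
  null_j <- free[c(FALSE, TRUE)][seq_len(length(null_i))]

  hits <- matrix(0L, nrow = n_reps, ncol = length(config$planted_pairs))
  null_hits <- 0L
  null_total <- 0L
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + 2L * r
    study <- simulate_study(cfg)
    y <- normalize_phenotype(study$cohort$ptau, "log")
    covs <- build_design(study$cohort)
    G <- study$genotypes$genotypes
    for (k in seq_along(config$planted_pairs)) {
      pp <- config$planted_pairs[[k]]
      fit <- pair_interaction_test(G[, pp$snp1], G[, pp$snp2], y, covs)
      hits[r, k] <- as.integer(!is.na(fit$p_value) && fit$p_value < power_alpha)
    }
    for (k in seq_along(null_i)) {
      fit <- pair_interaction_test(G[, null_i[k]], G[, null_j[k]], y, covs)
      if (!is.na(fit$p_value)) {
        null_total <- null_total + 1L
        null_hits <- null_hits + (fit$p_value < null_alpha)
      }
    }
  }

  power_rows <- purrr::imap(config$planted_pairs, function(pp, k) {
    rate <- mean(hits[, k])
    tibble(
      kind = "power",
      label = sprintf("pair_%d_%d", pp$snp1, pp$snp2),
      alpha = power_alpha, n = n_reps, rate = rate,
      se = sqrt(rate * (1 - rate) / n_reps)
    )
  })
  t1_rate <- if (null_total > 0) null_hits / null_total else NA_real_
  dplyr::bind_rows(c(power_rows, list(tibble(
    kind = "type1", label = "null_pairs", alpha = null_alpha,
    n = null_total, rate = t1_rate,
    se = if (null_total > 0) sqrt(t1_rate * (1 - t1_rate) / null_total) else NA_real_
  ))))
}
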