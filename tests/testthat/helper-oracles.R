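# Independent oracles and fixture builders shared across tests.

# Naive per-pair least-squares oracle: explicit normal-equation solves for
# the reduced and full interaction models with a full-rank check. Kept
# deliberately independent of the package's QR/FWL code paths.
oracle_pair_ols <- function(g1, g2, y, covariates) {
  covariates <- as.matrix(covariates)
  keep <- !is.na(g1) & !is.na(g2) & !is.na(y) & complete.cases(covariates)
  X <- cbind(1, g1, g2, g1 * g2, covariates)[keep, , drop = FALSE]
  Xr <- X[, -4, drop = FALSE]
  yk <- y[keep]
  n <- sum(keep)
  if (qr(X)$rank < ncol(X)) {
    return(list(F = 0, p = 1, n_used = n, rank_deficient = TRUE))
  }
  bf <- solve(crossprod(X), crossprod(X, yk))
  br <- solve(crossprod(Xr), crossprod(Xr, yk))
  rss_f <- sum((yk - X %*% bf)^2)
  rss_r <- sum((yk - Xr %*% br)^2)
  f <- (rss_r - rss_f) / (rss_f / (n - 10))
  list(
    F = f, p = pf(f, 1, n - 10, lower.tail = FALSE),
    n_used = n, coef = drop(bf), rank_deficient = FALSE
  )
}

# Exhaustive enumeration oracle for the HWE exact test: closed-form
# conditional probability of each attainable heterozygote count via
# log-factorials, then a two-sided tail sum. Same 1e-10 relative tie guard
# as the implementation so mathematically equal probabilities are
# classified identically.
oracle_hwe <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  rare <- 2L * min(n_hom1, n_hom2) + n_het
  if (rare == 0L) return(1)
  hs <- seq.int(rare %% 2L, min(rare, 2L * n - rare), by = 2L)
  logp <- vapply(hs, function(h) {
    nr <- (rare - h) / 2
    nc <- n - nr - h
    h * log(2) + lfactorial(n) - lfactorial(nr) - lfactorial(h) - lfactorial(nc) +
      lfactorial(rare) + lfactorial(2 * n - rare) - lfactorial(2 * n)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

# Wrap a plain integer matrix as a geno_matrix with synthetic metadata.
make_geno <- function(g, chr = NULL, maf = NULL) {
  g <- as.matrix(g)
  m <- ncol(g)
  snps <- tibble::tibble(
    snp_id = sprintf("rs%04d", seq_len(m)),
    chr = if (is.null(chr)) rep_len(1:22, m) else as.integer(chr),
    pos = 1000L * seq_len(m),
    a1 = "A", a2 = "G"
  )
  if (!is.null(maf)) snps$maf <- maf
  epiqt::geno_matrix(g, snps = snps, subjects = sprintf("s%04d", seq_len(nrow(g))))
}

# Small deterministic cohort covering all five diagnostic groups.
make_cohort <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("s%04d", seq_len(n)),
    ptau = exp(rnorm(n, log(25), 0.3)),
    age = runif(n, 55, 90),
    gender = rbinom(n, 1, 0.5),
    cds = sample(c("CN", "SMC", "EMCI", "LMCI", "AD"), n, replace = TRUE),
    complete = TRUE
  )
}

# A genotype column with genotype counts drawn near HWE proportions.
hwe_column <- function(n, p, seed) {
  set.seed(seed)
  rbinom(n, 2, p)
}

# 10-SNP variant-QC fixture with disjoint planted failures:
# SNPs 1-2 on chromosome 23, SNPs 3-4 below the call-rate threshold,
# SNPs 5-6 below the MAF threshold, SNP 7 failing HWE, SNPs 8-10 clean.
make_variant_qc_fixture <- function(n = 40) {
  pass_col <- function(seed) {
    g <- hwe_column(n, 0.3, seed)
    while (epiqt::hwe_exact_test(sum(g == 2), sum(g == 1), sum(g == 0)) < 1e-3 ||
      epiqt::minor_allele_frequency(g) < 0.1) {
      seed <- seed + 1000
      g <- hwe_column(n, 0.3, seed)
    }
    g
  }
  low_call <- function(seed) {
    g <- pass_col(seed)
    g[1:3] <- NA # 37/40 = 0.925 < 0.95
    g
  }
  low_maf <- c(rep(0L, n - 1), 1L) # MAF 1/(2n) = 0.0125
  hwe_fail <- rep(1L, n) # all heterozygous: strong HWE violation
  g <- cbind(
    pass_col(11), pass_col(12), # chr 23 -> removed at chromosome stage
    low_call(13), low_call(14),
    low_maf, low_maf,
    hwe_fail,
    pass_col(15), pass_col(16), pass_col(17)
  )
  make_geno(g, chr = c(23L, 23L, rep(1L, 8)))
}
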