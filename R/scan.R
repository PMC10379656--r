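#' Exhaustive pairwise interaction scan
#'
#' Evaluates the two-SNP interaction F test of [pair_interaction_test()]
#' for every unordered SNP pair exactly once, returning the pairs whose
#' interaction p-value falls below the significance threshold. Pairs are
#' canonicalised to `i < j` in panel order, so the result is symmetric by
#' construction.
#'
#' The scan pre-residualises the phenotype and every genotype column
#' against the covariate block (one QR factorisation), then sweeps blocks
#' of product columns with dense matrix algebra; by the
#' Frisch-Waugh-Lovell theorem this reproduces the per-pair nested-model
#' fit exactly, and `block_size` only controls memory traffic, never any
#' reported statistic. Pairs with missing genotypes, near-singular
#' two-SNP blocks or a collinear interaction column fall back to the
#' per-pair QR fit so complete-case sizes and degeneracy flags are always
#' those of [pair_interaction_test()].
#'
#' @param genotypes A [geno_matrix()] (subject QC already applied; `y` and
#'   `covariates` must be complete).
#' @param y Numeric phenotype vector, one value per subject.
#' @param covariates Covariate block from [build_design()].
#' @param p_threshold Either a number in (0, 1] or `"bonferroni"` (default):
#'   `alpha` divided by the number of tests `m(m-1)/2`.
#' @param alpha Family-wise rate used when `p_threshold = "bonferroni"`.
#' @param block_size Number of product columns processed per matrix sweep.
#' @param refit_coefficients If `TRUE` (default), significant pairs are
#'   refit singly to attach full-model coefficients; set to `FALSE` in
#'   large calibration runs where only F and p are needed.
#' @return A tibble of class `epi_scan` with columns `snp1`, `snp2`,
#'   `chr1`, `chr2`, `alpha0`, `alpha1`, `alpha2`, `alpha12`, `F`, `p`,
#'   `n_used`, `flag`, sorted by ascending p. Degenerate pairs
#'   (`flag != "ok"`) are always reported, whatever the threshold, so no
#'   pair is dropped silently. Attributes `n_tests`, `p_threshold`,
#'   `n_subjects`, `n_snps` record the run.
#' @export
scan_all_pairs <- function(genotypes, y, covariates,
                           p_threshold = "bonferroni", alpha = 0.05,
                           block_size = 256, refit_coefficients = TRUE) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  covariates <- as.matrix(covariates)
  y <- as.numeric(y)
  if (anyNA(y) || anyNA(covariates)) {
    abort("phenotype and covariates must be complete; run subject QC first")
  }
  m <- n_snps(genotypes)
  n <- n_subjects(genotypes)
  if (length(y) != n) abort("length(y) must equal the number of subjects")
  n_tests <- m * (m - 1) / 2
  if (identical(p_threshold, "bonferroni")) {
    p_threshold <- if (n_tests > 0) alpha / n_tests else alpha
  }
  stopifnot(is.numeric(p_threshold), p_threshold > 0, p_threshold <= 1)

  empty_result <- function() {
    structure(
      tibble(
        snp1 = character(), snp2 = character(),
        chr1 = integer(), chr2 = integer(),
        alpha0 = double(), alpha1 = double(), alpha2 = double(),
        alpha12 = double(), F = double(), p = double(),
        n_used = integer(), flag = character()
      ),
      n_tests = n_tests, p_threshold = p_threshold,
      n_subjects = n, n_snps = m,
      class = c("epi_scan", class(tibble()))
    )
  }
  if (m < 2) return(empty_result())

  G <- genotypes$genotypes
  storage.mode(G) <- "double"
  has_na <- apply(G, 2, anyNA)
  df_resid <- n - 10L

  # covariate projection, computed once per scan
  C1 <- cbind(1, covariates)
  qrC <- qr(C1)
  Q <- qr.Q(qrC)[, seq_len(qrC$rank), drop = FALSE]
  ey <- y - Q %*% crossprod(Q, y)
  G0 <- G
  G0[is.na(G0)] <- 0 # placeholders; NA pairs are delegated below
  EG <- G0 - Q %*% crossprod(Q, G0)
  S <- crossprod(EG)
  v <- drop(crossprod(EG, ey))
  yy <- sum(ey^2)

  f_all <- numeric(n_tests)
  p_all <- numeric(n_tests)
  delegate <- logical(n_tests)
  pair_pos <- function(i, j) {
    # linear index of pair (i, j), i < j, in row-major upper-triangle order
    (i - 1) * m - i * (i - 1) / 2 + (j - i)
  }

  for (i in seq_len(m - 1)) {
    J_all <- seq.int(i + 1, m)
    for (J in split(J_all, ceiling(seq_along(J_all) / block_size))) {
      pos <- pair_pos(i, J)
      if (has_na[i]) {
        delegate[pos] <- TRUE
        next
      }
      na_j <- has_na[J]
      P <- G0[, i] * G0[, J, drop = FALSE]
      EP <- P - Q %*% crossprod(Q, P)
      b1 <- drop(crossprod(EG[, i], EP))
      b2 <- colSums(EG[, J, drop = FALSE] * EP)
      pp <- colSums(EP^2)
      pe <- drop(crossprod(EP, ey))
      a11 <- S[i, i]
      a22 <- diag(S)[J]
      a12 <- S[i, J]
      det <- a11 * a22 - a12^2

      bad <- na_j | det <= 1e-10 * pmax(a11 * a22, .Machine$double.xmin)
      det[bad] <- 1 # avoid 0/0; flagged pairs are recomputed singly
      d1 <- (a22 * v[i] - a12 * v[J]) / det
      d2 <- (a11 * v[J] - a12 * v[i]) / det
      rss_red <- yy - (d1 * v[i] + d2 * v[J])
      c1 <- (a22 * b1 - a12 * b2) / det
      c2 <- (a11 * b2 - a12 * b1) / det
      ep2 <- pp - (c1 * b1 + c2 * b2)
      epy <- pe - (c1 * v[i] + c2 * v[J])
      bad <- bad | ep2 <= 1e-10 * pmax(pp, .Machine$double.xmin)
      ep2[bad] <- 1
      ss_int <- epy^2 / ep2
      rss_full <- pmax(rss_red - ss_int, 0)
      f <- ifelse(rss_full > 0, ss_int / (rss_full / df_resid), Inf)

      delegate[pos] <- bad
      f_all[pos] <- f
      p_all[pos] <- pf(f, 1, df_resid, lower.tail = FALSE)
    }
  }

  idx <- which(delegate | p_all < p_threshold)
  if (length(idx) == 0) return(empty_result())

  # recover (i, j) from linear index
  row_starts <- cumsum(c(0, (m - 1):1))
  ii <- findInterval(idx - 1, row_starts)
  jj <- idx - row_starts[ii] + ii

  nk <- length(idx)
  f_out <- f_all[idx]
  p_out <- p_all[idx]
  n_used <- rep.int(n, nk)
  flag <- rep.int("ok", nk)
  co_out <- matrix(NA_real_, nrow = nk, ncol = 4,
    dimnames = list(NULL, PAIR_TERMS[1:4])
  )
  needs_fit <- which(delegate[idx] | refit_coefficients)
  for (k in needs_fit) {
    fit <- pair_interaction_test(G[, ii[k]], G[, jj[k]], y, covariates)
    f_out[k] <- fit$f_stat
    p_out[k] <- fit$p_value
    n_used[k] <- fit$n_used
    flag[k] <- fit$flag
    co_out[k, ] <- fit$coefficients[1:4]
  }

  out <- tibble(
    snp1 = genotypes$snps$snp_id[ii], snp2 = genotypes$snps$snp_id[jj],
    chr1 = genotypes$snps$chr[ii], chr2 = genotypes$snps$chr[jj],
    alpha0 = co_out[, "alpha0"], alpha1 = co_out[, "alpha1"],
    alpha2 = co_out[, "alpha2"], alpha12 = co_out[, "alpha12"],
    F = f_out, p = p_out, n_used = as.integer(n_used), flag = flag
  )
  # degenerate pairs are reported with their flag, never dropped silently
  out <- dplyr::filter(
    out,
    .data$flag != "ok" | (!is.na(.data$p) & .data$p < p_threshold)
  )
  out <- dplyr::arrange(out, .data$p, .data$snp1, .data$snp2)
  structure(
    out,
    n_tests = n_tests, p_threshold = p_threshold,
    n_subjects = n, n_snps = m,
    class = c("epi_scan", class(tibble()))
  )
}
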