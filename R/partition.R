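#' Hierarchical variance partition for one SNP pair
#'
#' Decomposes the phenotypic variance explained by three nested least
#' squares models on the pair's complete-case subset: covariates only
#' (age, gender, cds), covariates plus the two additive main effects, and
#' the full model adding the interaction product. Each R-squared is
#' `1 - RSS/TSS`; the two deltas are successive differences, so the
#' components sum to the full-model R-squared by construction. This mirrors
#' the hierarchical "R square" columns reported by general-linear-model
#' software.
#'
#' @param g1,g2 Genotype columns.
#' @param y Numeric phenotype.
#' @param covariates Covariate block from [build_design()].
#' @return An object of class `epi_vpart`: a list with `r2_cov`,
#'   `delta_r2_main`, `delta_r2_int`, `r2_full`, `n_used`, `df_resid` and
#'   `flag`. Supports [tidy()] and [glance()].
#' @export
hierarchical_r2 <- function(g1, g2, y, covariates) {
  covariates <- as.matrix(covariates)
  keep <- !is.na(g1) & !is.na(g2) & !is.na(y) & stats::complete.cases(covariates)
  n_used <- sum(keep)
  if (n_used <= 10) {
    return(structure(
      list(
        r2_cov = NA_real_, delta_r2_main = NA_real_, delta_r2_int = NA_real_,
        r2_full = NA_real_, n_used = n_used, df_resid = NA_integer_,
        flag = "insufficient_df"
      ),
      class = "epi_vpart"
    ))
  }
  g1 <- as.numeric(g1[keep])
  g2 <- as.numeric(g2[keep])
  yk <- as.numeric(y[keep])
  C <- covariates[keep, , drop = FALSE]
  tss <- sum((yk - mean(yk))^2)
  if (tss <= 0) abort("phenotype has zero variance on the complete-case subset")

  X_full <- cbind(1, g1, g2, g1 * g2, C)
  colnames(X_full) <- PAIR_TERMS
  rss <- function(X) {
    fit <- stats::lm.fit(X, yk)
    sum(fit$residuals^2)
  }
  rss_cov <- rss(X_full[, -(2:4), drop = FALSE])
  rss_main <- rss(X_full[, -4, drop = FALSE])
  rss_full_fit <- stats::lm.fit(X_full, yk)
  rss_full <- sum(rss_full_fit$residuals^2)

  r2_cov <- 1 - rss_cov / tss
  delta_main <- (rss_cov - rss_main) / tss
  delta_int <- (rss_main - rss_full) / tss
  # nesting guarantees non-negative deltas up to floating point
  for (d in c("delta_main", "delta_int")) {
    val <- get(d)
    if (val < 0) {
      if (val < -1e-12) warn(sprintf("%s negative beyond tolerance (%.3g)", d, val))
      assign(d, 0)
    }
  }
  structure(
    list(
      r2_cov = r2_cov, delta_r2_main = delta_main, delta_r2_int = delta_int,
      r2_full = r2_cov + delta_main + delta_int,
      n_used = n_used, df_resid = n_used - rss_full_fit$rank,
      flag = if (rss_full_fit$rank < ncol(X_full)) "rank_deficient" else "ok"
    ),
    class = "epi_vpart"
  )
}

#' @export
print.epi_vpart <- function(x, ...) {
  cat(sprintf(
    "<epi_vpart> R2: covariates %.4f, +mains %.4f, +interaction %.4f (full %.4f), n = %d\n",
    x$r2_cov, x$delta_r2_main, x$delta_r2_int, x$r2_full, x$n_used
  ))
  invisible(x)
}

#' @rdname hierarchical_r2
#' @param x An `epi_vpart` object.
#' @param ... Unused.
#' @export
tidy.epi_vpart <- function(x, ...) {
  tibble(
    component = c("covariates", "main_effects", "interaction"),
    r_squared = c(x$r2_cov, x$delta_r2_main, x$delta_r2_int)
  )
}

#' @rdname hierarchical_r2
#' @export
glance.epi_vpart <- function(x, ...) {
  tibble(
    r2_cov = x$r2_cov, delta_r2_main = x$delta_r2_main,
    delta_r2_int = x$delta_r2_int, r2_full = x$r2_full,
    n_used = x$n_used, flag = x$flag
  )
}

#' Variance partitions for the top-ranked pairs
#'
#' Computes [hierarchical_r2()] for every scanned pair, ranks by the
#' interaction delta R-squared (descending, ties broken by ascending
#' interaction p-value) and keeps the top `top_n`, attaching each SNP's
#' single-locus association p-value for context.
#'
#' @param pairs An `epi_scan` tibble (or any tibble with `snp1`, `snp2`,
#'   `p` columns).
#' @param genotypes The [geno_matrix()] the scan used.
#' @param y Numeric phenotype.
#' @param covariates Covariate block from [build_design()].
#' @param top_n Number of pairs to keep (default 10); if fewer pairs are
#'   available, all are returned.
#' @return A tibble with one row per kept pair: identifiers, per-SNP GWAS
#'   p-values, interaction p, and the three R-squared components.
#' @export
partition_top_pairs <- function(pairs, genotypes, y, covariates, top_n = 10) {
  if (nrow(pairs) == 0) {
    return(tibble(
      snp1 = character(), snp2 = character(),
      gwas_p1 = double(), gwas_p2 = double(), p_int = double(),
      r2_cov = double(), delta_r2_main = double(), delta_r2_int = double(),
      r2_full = double(), n_used = integer()
    ))
  }
  G <- genotypes$genotypes
  id <- genotypes$snps$snp_id
  main_p <- new.env()
  gwas_p <- function(s) {
    if (is.null(main_p[[s]])) {
      main_p[[s]] <- gwas_main_effect(G[, match(s, id)], y, covariates)$p
    }
    main_p[[s]]
  }
  rows <- purrr::pmap(
    list(pairs$snp1, pairs$snp2, pairs$p),
    function(s1, s2, p_int) {
      vp <- hierarchical_r2(G[, match(s1, id)], G[, match(s2, id)], y, covariates)
      tibble(
        snp1 = s1, snp2 = s2,
        gwas_p1 = gwas_p(s1), gwas_p2 = gwas_p(s2), p_int = p_int,
        r2_cov = vp$r2_cov, delta_r2_main = vp$delta_r2_main,
        delta_r2_int = vp$delta_r2_int, r2_full = vp$r2_full,
        n_used = as.integer(vp$n_used)
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, dplyr::desc(.data$delta_r2_int), .data$p_int)
  head(out, top_n)
}
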