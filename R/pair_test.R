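PAIR_TERMS <- c(
  "alpha0", "alpha1", "alpha2", "alpha12",
  "age", "gender", "cdsSMC", "cdsEMCI", "cdsLMCI", "cdsAD"
)

#' Two-SNP interaction F test
#'
#' Fits the nested pair of linear models for one SNP pair on the
#' complete-case subset: the reduced model
#' `y ~ SNP1 + SNP2 + age + gender + cds` and the full model adding the
#' product term `SNP1 x SNP2`. The interaction is tested with the 1-df
#' nested-model F statistic
#' `F = (RSS_reduced - RSS_full) / (RSS_full / (n_used - 10))`
#' against `F(1, n_used - 10)`; with one added term this equals the squared
#' t of the interaction coefficient. Both models are fit by pivoted QR
#' least squares.
#'
#' Degenerate inputs are flagged rather than dropped: if the interaction
#' column is collinear with the remaining columns (e.g. a constant SNP or
#' perfect LD) the result carries `flag = "rank_deficient"` with `F = 0`,
#' `p = 1` by convention; if the complete-case subset has 10 or fewer
#' subjects the flag is `"insufficient_df"` and the statistics are `NA`.
#'
#' @param g1,g2 Genotype columns (additive codes, `NA` missing).
#' @param y Numeric phenotype (already transformed as desired).
#' @param covariates Covariate block from [build_design()].
#' @return An object of class `epi_pair_fit` with the fitted coefficients,
#'   `f_stat`, `p_value`, `n_used`, residual variance `sigma2` and the
#'   degeneracy `flag`. Supports [tidy()] and [glance()].
#' @export
pair_interaction_test <- function(g1, g2, y, covariates) {
  covariates <- as.matrix(covariates)
  keep <- !is.na(g1) & !is.na(g2) & !is.na(y) & stats::complete.cases(covariates)
  n_used <- sum(keep)

  empty <- function(flag) {
    structure(
      list(
        coefficients = setNames(rep(NA_real_, 10), PAIR_TERMS),
        std_errors = setNames(rep(NA_real_, 10), PAIR_TERMS),
        f_stat = if (flag == "rank_deficient") 0 else NA_real_,
        p_value = if (flag == "rank_deficient") 1 else NA_real_,
        n_used = n_used, df_resid = NA_integer_,
        rss_full = NA_real_, rss_reduced = NA_real_, sigma2 = NA_real_,
        flag = flag
      ),
      class = "epi_pair_fit"
    )
  }
  if (n_used <= 10) return(empty("insufficient_df"))

  g1 <- as.numeric(g1[keep])
  g2 <- as.numeric(g2[keep])
  yk <- as.numeric(y[keep])
  C <- covariates[keep, , drop = FALSE]
  X_full <- cbind(1, g1, g2, g1 * g2, C)
  colnames(X_full) <- PAIR_TERMS
  X_red <- X_full[, -4, drop = FALSE]

  fit_full <- stats::lm.fit(X_full, yk)
  fit_red <- stats::lm.fit(X_red, yk)
  if (fit_full$rank <= fit_red$rank) {
    out <- empty("rank_deficient")
    out$n_used <- n_used
    return(out)
  }

  rss_full <- sum(fit_full$residuals^2)
  rss_red <- sum(fit_red$residuals^2)
  df_resid <- n_used - fit_full$rank
  sigma2 <- rss_full / df_resid
  f_stat <- max(rss_red - rss_full, 0) / sigma2
  p_value <- pf(f_stat, 1, df_resid, lower.tail = FALSE)

  coefs <- setNames(fit_full$coefficients[PAIR_TERMS], PAIR_TERMS)
  se <- setNames(rep(NA_real_, 10), PAIR_TERMS)
  if (fit_full$rank == ncol(X_full)) {
    R <- qr.R(fit_full$qr)
    XtX_inv <- chol2inv(R)
    piv <- fit_full$qr$pivot
    se[PAIR_TERMS[piv]] <- sqrt(diag(XtX_inv) * sigma2)
  }

  structure(
    list(
      coefficients = coefs, std_errors = se,
      f_stat = f_stat, p_value = p_value,
      n_used = n_used, df_resid = df_resid,
      rss_full = rss_full, rss_reduced = rss_red, sigma2 = sigma2,
      flag = "ok"
    ),
    class = "epi_pair_fit"
  )
}

#' @export
print.epi_pair_fit <- function(x, ...) {
  cat(sprintf(
    "<epi_pair_fit> F = %.4g, p = %.3g, n_used = %d, flag = %s\n",
    x$f_stat, x$p_value, x$n_used, x$flag
  ))
  invisible(x)
}

#' Tidy a pair fit
#'
#' @param x An `epi_pair_fit`.
#' @param ... Unused.
#' @return A tibble with one row per full-model term: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.epi_pair_fit <- function(x, ...) {
  stat <- x$coefficients / x$std_errors
  tibble(
    term = PAIR_TERMS,
    estimate = unname(x$coefficients),
    std.error = unname(x$std_errors),
    statistic = unname(stat),
    p.value = unname(2 * pt(abs(stat), df = x$df_resid, lower.tail = FALSE))
  )
}

#' Glance at a pair fit
#'
#' @param x An `epi_pair_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `f.statistic`, `p.value`, `n.used`,
#'   `df.residual`, `sigma2`, `flag`.
#' @export
glance.epi_pair_fit <- function(x, ...) {
  tibble(
    f.statistic = x$f_stat, p.value = x$p_value,
    n.used = x$n_used, df.residual = x$df_resid,
    sigma2 = x$sigma2, flag = x$flag
  )
}

#' Single-SNP additive association test
#'
#' Covariate-adjusted main-effect model `y ~ g + age + gender + cds`
#' (8 columns with intercept); returns the additive coefficient and its
#' two-sided t-test p-value, equivalent to the 1-df F test on
#' `F(1, n_used - 8)`.
#'
#' @param g Genotype column.
#' @param y Numeric phenotype.
#' @param covariates Covariate block from [build_design()].
#' @return One-row tibble: `beta`, `se`, `p`, `n_used`, `flag`.
#' @export
gwas_main_effect <- function(g, y, covariates) {
  covariates <- as.matrix(covariates)
  keep <- !is.na(g) & !is.na(y) & stats::complete.cases(covariates)
  n_used <- sum(keep)
  degenerate <- tibble(
    beta = NA_real_, se = NA_real_, p = NA_real_,
    n_used = n_used, flag = "degenerate"
  )
  if (n_used <= 8) return(degenerate)

  gk <- as.numeric(g[keep])
  X <- cbind(1, g = gk, covariates[keep, , drop = FALSE])
  fit <- stats::lm.fit(X, as.numeric(y[keep]))
  if (fit$rank < ncol(X) || length(unique(gk)) == 1L) return(degenerate)

  df_resid <- n_used - fit$rank
  sigma2 <- sum(fit$residuals^2) / df_resid
  XtX_inv <- chol2inv(qr.R(fit$qr))
  piv <- fit$qr$pivot
  se_all <- sqrt(diag(XtX_inv) * sigma2)[order(piv)]
  beta <- unname(fit$coefficients["g"])
  se <- se_all[2]
  tval <- beta / se
  tibble(
    beta = beta, se = se,
    p = 2 * pt(abs(tval), df = df_resid, lower.tail = FALSE),
    n_used = n_used, flag = "ok"
  )
}
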