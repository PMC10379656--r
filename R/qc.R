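#' Per-SNP call rate
#'
#' Fraction of subjects with a non-missing genotype at one SNP.
#'
#' @param g Genotype column (integer vector with `NA` for missing).
#' @return Fraction in `[0, 1]`.
#' @export
snp_call_rate <- function(g) {
  if (length(g) == 0) abort("empty genotype column")
  mean(!is.na(g))
}

#' Minor allele frequency
#'
#' Frequency of the rarer allele computed from non-missing additive codes:
#' the A1 frequency is `sum(g) / (2 * n_nonmissing)` and the MAF is the
#' smaller of that and its complement.
#'
#' @param g Genotype column (codes 0/1/2, `NA` missing).
#' @return Fraction in `[0, 0.5]`, or `NA_real_` when every genotype is
#'   missing (undefined).
#' @export
minor_allele_frequency <- function(g) {
  g <- g[!is.na(g)]
  if (length(g) == 0) return(NA_real_)
  freq <- sum(g) / (2 * length(g))
  min(freq, 1 - freq)
}

qc_report_row <- function(name, n_before, n_removed) {
  tibble(
    filter = name, n_before = as.integer(n_before),
    n_removed = as.integer(n_removed),
    n_after = as.integer(n_before - n_removed)
  )
}

#' Variant quality control
#'
#' Applies the standard variant filters in order: autosomal chromosomes
#' 1-22, SNP call rate, minor allele frequency and the Hardy-Weinberg exact
#' test, each with an inclusive threshold (a SNP at MAF exactly 0.05 or HWE
#' p exactly 1e-6 is retained). Per-stage counts are reported so every
#' removal is auditable; MAF and HWE are computed on the subjects present
#' in `genotypes`, so run subject QC first if the analysis cohort differs.
#'
#' @param genotypes A [geno_matrix()].
#' @param min_call_rate Minimum per-SNP call rate (default 0.95).
#' @param min_maf Minimum minor allele frequency (default 0.05).
#' @param min_hwe_p Minimum HWE exact p-value (default 1e-6).
#' @return A list with elements `genotypes` (the filtered [geno_matrix()])
#'   and `report` (a tibble with columns `filter`, `n_before`, `n_removed`,
#'   `n_after`, one row per stage in application order).
#' @export
apply_variant_qc <- function(genotypes, min_call_rate = 0.95,
                             min_maf = 0.05, min_hwe_p = 1e-6) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  g <- genotypes
  report <- list()

  keep <- g$snps$chr >= 1L & g$snps$chr <= 22L
  report <- c(report, list(qc_report_row("chromosome_1_22", n_snps(g), sum(!keep))))
  g <- g[, keep]

  cr <- apply(g$genotypes, 2, snp_call_rate)
  keep <- cr >= min_call_rate
  report <- c(report, list(qc_report_row("snp_call_rate", n_snps(g), sum(!keep))))
  g <- g[, keep]

  maf <- apply(g$genotypes, 2, minor_allele_frequency)
  keep <- !is.na(maf) & maf >= min_maf
  report <- c(report, list(qc_report_row("maf", n_snps(g), sum(!keep))))
  g <- g[, keep]

  hwe_p <- apply(g$genotypes, 2, function(col) {
    col <- col[!is.na(col)]
    hwe_exact_test(sum(col == 2L), sum(col == 1L), sum(col == 0L))
  })
  keep <- hwe_p >= min_hwe_p
  report <- c(report, list(qc_report_row("hwe", n_snps(g), sum(!keep))))
  g <- g[, keep]

  list(genotypes = g, report = dplyr::bind_rows(report))
}

#' Subject quality control
#'
#' Removes subjects on an optional external exclusion list (e.g. population
#' stratification outliers identified by other tools), subjects below the
#' per-subject genotype call-rate threshold, and subjects lacking a
#' phenotype or any covariate (a subject genotyped but absent from the
#' cohort table counts as lacking a phenotype). The genotype matrix and
#' cohort table are re-aligned to the surviving intersection, preserving
#' the genotype (fam) subject order.
#'
#' @param genotypes A [geno_matrix()].
#' @param cohort A cohort tibble from [read_cohort()] (or equivalent, with a
#'   logical `complete` column; if absent it is computed).
#' @param min_call_rate Minimum per-subject call rate (default 0.90).
#' @param exclude Character vector of subject ids to drop first (default
#'   none).
#' @return A list with `genotypes`, `cohort` (aligned, same order) and
#'   `report` (per-stage counts over genotyped subjects).
#' @export
apply_subject_qc <- function(genotypes, cohort, min_call_rate = 0.90,
                             exclude = character()) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  if (!"complete" %in% names(cohort)) {
    cohort$complete <- stats::complete.cases(
      cohort[c("subject_id", "ptau", "age", "gender", "cds")]
    )
  }
  if (length(intersect(genotypes$subjects, cohort$subject_id)) == 0) {
    abort("no subject ids shared between genotypes and cohort")
  }
  g <- genotypes
  report <- list()

  keep <- !(g$subjects %in% exclude)
  report <- c(report, list(qc_report_row("exclusion_list", n_subjects(g), sum(!keep))))
  g <- g[keep, ]

  cr <- apply(g$genotypes, 1, function(row) mean(!is.na(row)))
  keep <- cr >= min_call_rate
  report <- c(report, list(qc_report_row("subject_call_rate", n_subjects(g), sum(!keep))))
  g <- g[keep, ]

  ok_ids <- cohort$subject_id[cohort$complete]
  keep <- g$subjects %in% ok_ids
  report <- c(report, list(qc_report_row(
    "phenotype_and_covariates_present", n_subjects(g), sum(!keep)
  )))
  g <- g[keep, ]

  cohort_out <- cohort[match(g$subjects, cohort$subject_id), , drop = FALSE]
  list(genotypes = g, cohort = as_tibble(cohort_out), report = dplyr::bind_rows(report))
}

#' Phenotype normalisation
#'
#' P-tau concentrations are positive and right-skewed, so the default is a
#' natural-log transform; `rin` applies a rank-based inverse-normal (Blom)
#' transform, and `none` leaves the values untouched. The choice is
#' recorded by callers in run metadata.
#'
#' @param x Numeric phenotype values.
#' @param mode One of `"log"` (default), `"none"`, `"rin"`.
#' @return Transformed numeric vector.
#' @export
normalize_phenotype <- function(x, mode = c("log", "none", "rin")) {
  mode <- match.arg(mode)
  switch(mode,
    none = x,
    log = {
      if (any(x <= 0, na.rm = TRUE)) abort("log transform requires positive values")
      log(x)
    },
    rin = {
      n <- sum(!is.na(x))
      qnorm((rank(x, na.last = "keep") - 0.375) / (n + 0.25))
    }
  )
}

#' Enforce one baseline record per subject
#'
#' Consistency check for longitudinal sources: the analysis expects exactly
#' one (baseline) phenotype row per subject, so duplicated ids are an
#' error rather than silently averaged.
#'
#' @param cohort Cohort tibble.
#' @return Invisibly `cohort` if unique; errors otherwise.
#' @export
check_baseline_unique <- function(cohort) {
  dup <- unique(cohort$subject_id[duplicated(cohort$subject_id)])
  if (length(dup) > 0) {
    abort(paste0(
      "multiple rows per subject violate the one-baseline-record rule: ",
      paste(dup, collapse = ", ")
    ))
  }
  invisible(cohort)
}
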