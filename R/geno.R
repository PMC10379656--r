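#' Genotype matrix container
#'
#' Bundles an additively coded genotype matrix (subjects in rows, SNPs in
#' columns, entries counting copies of the A1 allele: 0, 1, 2 or `NA` for
#' missing) with its per-SNP metadata and subject identifiers. This is the
#' object every genotype-consuming function in the package accepts.
#'
#' @param genotypes Integer (or coercible) matrix, `n_subjects` rows by
#'   `n_snps` columns, entries in `{0, 1, 2, NA}`.
#' @param snps Tibble (or data frame) with one row per SNP and columns
#'   `snp_id`, `chr`, `pos`, `a1`, `a2`. `chr` is the numeric chromosome code
#'   (1-26 as PLINK writes them), `pos` the 1-based base-pair position, `a1`
#'   the counted allele.
#' @param subjects Character vector of unique subject identifiers, one per row.
#'
#' @return An object of class `geno_matrix`: a list with elements
#'   `genotypes`, `snps` and `subjects`.
#' @export
#' @examples
#' g <- geno_matrix(
#'   matrix(c(0L, 1L, 2L, NA, 1L, 1L), nrow = 3),
#'   snps = tibble::tibble(
#'     snp_id = c("rs1", "rs2"), chr = c(1L, 2L),
#'     pos = c(100L, 200L), a1 = c("A", "C"), a2 = c("G", "T")
#'   ),
#'   subjects = c("s1", "s2", "s3")
#' )
#' dim(g)
geno_matrix <- function(genotypes, snps, subjects) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  snps <- as_tibble(snps)
  subjects <- as.character(subjects)

  required <- c("snp_id", "chr", "pos", "a1", "a2")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols) > 0) {
    abort(paste0("`snps` lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(genotypes) != length(subjects)) {
    abort("number of genotype rows must equal number of subjects")
  }
  if (ncol(genotypes) != nrow(snps)) {
    abort("number of genotype columns must equal number of SNP records")
  }
  if (nrow(genotypes) == 0L) abort("a genotype matrix needs at least one subject")
  if (anyDuplicated(subjects)) abort("subject ids must be unique")
  if (anyDuplicated(snps$snp_id)) abort("snp ids must be unique")
  if (any(snps$pos < 1L)) abort("positions must be >= 1 (1-based)")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) > 0 && (min(bad) < 0L || max(bad) > 2L)) {
    abort("genotype codes must be 0, 1, 2 or NA")
  }
  dimnames(genotypes) <- list(subjects, snps$snp_id)

  structure(
    list(genotypes = genotypes, snps = snps, subjects = subjects),
    class = "geno_matrix"
  )
}

#' @export
dim.geno_matrix <- function(x) dim(x$genotypes)

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d subjects x %d SNPs (%.2f%% missing)\n",
    nrow(x$genotypes), ncol(x$genotypes),
    100 * mean(is.na(x$genotypes))
  ))
  print(head(x$snps, 5))
  invisible(x)
}

#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$subjects)
  if (missing(j)) j <- seq_len(nrow(x$snps))
  geno_matrix(
    x$genotypes[i, j, drop = FALSE],
    snps = x$snps[j, , drop = FALSE],
    subjects = x$subjects[i]
  )
}

n_snps <- function(x) ncol(x$genotypes)
n_subjects <- function(x) nrow(x$genotypes)
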