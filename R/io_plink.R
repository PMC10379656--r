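#' Read a PLINK 1 binary genotype set
#'
#' Decodes a SNP-major bed/bim/fam triple into a [geno_matrix()]. The 2-bit
#' codes are mapped to counts of the bim A1 allele, the PLINK convention:
#' `00` = two copies of A1, `10` = one copy, `11` = zero copies, `01` =
#' missing. Subject order follows the fam file, SNP order the bim file;
#' neither is ever reordered.
#'
#' @param bed_path,bim_path,fam_path Paths to the three files. `bim_path`
#'   and `fam_path` default to the bed path with swapped extensions.
#' @return A [geno_matrix()].
#' @export
read_plink <- function(bed_path,
                       bim_path = sub("\\.bed$", ".bim", bed_path),
                       fam_path = sub("\\.bed$", ".fam", bed_path)) {
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  bim <- read.table(bim_path,
    col.names = c("chr", "snp_id", "cm", "pos", "a1", "a2"),
    colClasses = c("integer", "character", "numeric", "integer", "character", "character")
  )
  fam <- read.table(fam_path,
    col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
    colClasses = c("character", "character", "character", "character", "integer", "character")
  )
  n <- nrow(fam)
  m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)

  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    abort("not a PLINK bed file (bad magic bytes)")
  }
  if (raw[3] != as.raw(0x01)) {
    abort("unsupported bed mode byte: only SNP-major (0x01) is supported")
  }
  payload <- raw[-(1:3)]
  if (length(payload) != bytes_per_snp * m) {
    abort(sprintf(
      "bed payload is %d bytes but bim/fam dimensions imply %d (truncated or mismatched files)",
      length(payload), bytes_per_snp * m
    ))
  }

  # 2-bit fields, subject 1 in the lowest-order bits of each byte
  ints <- as.integer(payload)
  dim(ints) <- c(bytes_per_snp, m)
  subj <- seq_len(n)
  byte_idx <- (subj - 1L) %/% 4L + 1L
  shift <- 4L^((subj - 1L) %% 4L)
  decode <- c(2L, NA_integer_, 1L, 0L) # codes 0b00, 0b01, 0b10, 0b11
  geno <- matrix(NA_integer_, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    two_bit <- (ints[byte_idx, j] %/% shift) %% 4L
    geno[, j] <- decode[two_bit + 1L]
  }

  geno_matrix(geno, snps = as_tibble(bim[, c("snp_id", "chr", "pos", "a1", "a2")]),
              subjects = fam$iid)
}

#' Write a PLINK 1 binary genotype set
#'
#' Inverse of [read_plink()]: emits a SNP-major bed with the standard magic
#' bytes plus matching bim/fam files so the round trip through
#' `read_plink(write_plink(x))` reproduces `x` exactly, missing genotypes
#' included.
#'
#' @param genotypes A [geno_matrix()] with at least one subject.
#' @param out_prefix Output path prefix; `.bed`, `.bim` and `.fam` are
#'   appended.
#' @return Invisibly, a named character vector with the three file paths.
#' @export
write_plink <- function(genotypes, out_prefix) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  g <- genotypes$genotypes
  n <- nrow(g)
  m <- ncol(g)
  if (n == 0L) abort("refusing to write a genotype set with zero subjects")

  # genotype code -> 2-bit field (00 hom A1, 10 het, 11 hom A2, 01 missing)
  enc <- c(3L, 2L, 0L)
  codes <- matrix(1L, nrow = 4L * ceiling(n / 4), ncol = m) # pad fills as missing
  codes[seq_len(n), ] <- ifelse(is.na(g), 1L, enc[g + 1L])
  codes[seq.int(n + 1L, length.out = nrow(codes) - n), ] <- 0L # zero padding bits
  i4 <- seq(1L, nrow(codes), by = 4L)
  bytes <- codes[i4, , drop = FALSE] +
    4L * codes[i4 + 1L, , drop = FALSE] +
    16L * codes[i4 + 2L, , drop = FALSE] +
    64L * codes[i4 + 3L, , drop = FALSE]

  paths <- c(
    bed = paste0(out_prefix, ".bed"),
    bim = paste0(out_prefix, ".bim"),
    fam = paste0(out_prefix, ".fam")
  )
  con <- file(paths[["bed"]], "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)

  s <- genotypes$snps
  writeLines(
    paste(s$chr, s$snp_id, 0, s$pos, s$a1, s$a2, sep = "\t"),
    paths[["bim"]]
  )
  writeLines(
    paste(genotypes$subjects, genotypes$subjects, 0, 0, 0, -9, sep = "\t"),
    paths[["fam"]]
  )
  invisible(paths)
}
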