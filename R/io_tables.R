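CDS_LEVELS <- c("CN", "SMC", "EMCI", "LMCI", "AD")

#' Read a phenotype and covariate table
#'
#' Reads the per-subject cohort TSV: subject id, CSF P-tau concentration
#' (pg/mL), age in years, gender as a 0/1 code and clinical diagnostic
#' status (`cds`, one of CN, SMC, EMCI, LMCI, AD). Rows with a missing
#' phenotype or covariate are retained and flagged in the `complete`
#' column; dropping them is the subject-QC step's job, so counts stay
#' auditable.
#'
#' @param tsv_path Path to a TSV with header columns `subject_id`, `ptau`,
#'   `age`, `gender`, `cds`.
#' @return A tibble with the five typed columns plus a logical `complete`
#'   flag.
#' @export
read_cohort <- function(tsv_path) {
  raw <- readr::read_tsv(tsv_path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      ptau = readr::col_double(),
      age = readr::col_double(),
      gender = readr::col_integer(),
      cds = readr::col_character()
    )
  )
  required <- c("subject_id", "ptau", "age", "gender", "cds")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  dup <- raw$subject_id[duplicated(raw$subject_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicated subject_id: ", paste(unique(dup), collapse = ", ")))
  }
  bad_cds <- !is.na(raw$cds) & !(raw$cds %in% CDS_LEVELS)
  if (any(bad_cds)) {
    row <- which(bad_cds)[1]
    abort(sprintf(
      "row %d: cds value '%s' is not one of %s",
      row, raw$cds[row], paste(CDS_LEVELS, collapse = "/")
    ))
  }
  if (any(!is.na(raw$gender) & !(raw$gender %in% c(0L, 1L)))) {
    abort("gender must be coded 0/1")
  }
  if (any(!is.na(raw$ptau) & raw$ptau <= 0)) {
    abort("ptau must be a positive concentration")
  }
  dplyr::mutate(
    raw[required],
    complete = stats::complete.cases(raw[required])
  )
}

#' Read a gene annotation in BED format
#'
#' Accepts BED with at least four columns (chrom, start, end, name) in the
#' standard 0-based half-open convention and converts to the package's
#' internal 1-based inclusive coordinates in this one place:
#' `start_bp = BED start + 1`, `end_bp = BED end`. Chromosome names may
#' carry a `chr` prefix, which is stripped.
#'
#' @param bed_path Path to the BED file (tab- or space-separated, no header).
#' @return A tibble with columns `gene_symbol`, `chr`, `start_bp`, `end_bp`.
#' @export
read_gene_bed <- function(bed_path) {
  lines <- readLines(bed_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(
      gene_symbol = character(), chr = integer(),
      start_bp = integer(), end_bp = integer()
    ))
  }
  fields <- strsplit(lines, "[ \t]+")
  n_col <- vapply(fields, length, integer(1))
  if (any(n_col < 4)) {
    abort(sprintf(
      "line %d has %d column(s); BED4 (chrom, start, end, gene symbol) required",
      which(n_col < 4)[1], min(n_col)
    ))
  }
  chr_txt <- sub("^chr", "", vapply(fields, `[[`, character(1), 1))
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3)))
  if (anyNA(start0) || anyNA(end0)) {
    abort("non-numeric BED coordinates")
  }
  out <- tibble(
    gene_symbol = vapply(fields, `[[`, character(1), 4),
    chr = suppressWarnings(as.integer(chr_txt)),
    start_bp = start0 + 1L,
    end_bp = end0
  )
  if (any(out$start_bp > out$end_bp)) {
    abort("BED interval with start >= end after 1-based conversion")
  }
  out
}

#' Read a gene list (one symbol per line)
#'
#' @param path Path to a plain-text file, one gene symbol per line; blank
#'   lines ignored, surrounding whitespace trimmed.
#' @return A character vector of unique symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}

#' Read a protein-protein interaction edge list
#'
#' Two-column TSV (`gene_a`, `gene_b`, header optional) of undirected
#' edges. Symbols are whitespace-trimmed; self-edges are rejected because
#' an interaction pair is always between two distinct genes.
#'
#' @param path Path to the edge list.
#' @return A tibble with columns `gene_a`, `gene_b`.
#' @export
read_ppi_edges <- function(path) {
  raw <- read.table(path, header = FALSE, sep = "\t", colClasses = "character")
  if (ncol(raw) < 2) abort("PPI edge list must have two columns")
  if (identical(tolower(trimws(raw[1, 1])), "gene_a")) raw <- raw[-1, , drop = FALSE]
  out <- tibble(gene_a = trimws(raw[[1]]), gene_b = trimws(raw[[2]]))
  if (any(out$gene_a == out$gene_b)) {
    abort("self-edges are not allowed in the PPI edge list")
  }
  out
}

#' Write a pair-result table
#'
#' Writes scan results as a TSV with columns `snp1`, `snp2`, `chr1`,
#' `chr2`, `alpha1`, `alpha2`, `alpha12`, `F`, `p`, `n_used`, sorted by
#' ascending p-value with ties broken lexicographically on (snp1, snp2).
#' Coefficients are on the A1-count coding (documented in a header
#' comment line).
#'
#' @param results Tibble of pair results as produced by [scan_all_pairs()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_pair_results <- function(results, path) {
  cols <- c("snp1", "snp2", "chr1", "chr2", "alpha1", "alpha2", "alpha12", "F", "p", "n_used")
  if (nrow(results) == 0) {
    out <- tibble::as_tibble(setNames(
      c(rep(list(character()), 2), rep(list(integer()), 2), rep(list(double()), 5), list(integer())),
      cols
    ))
  } else {
    out <- results
    if (!"F" %in% names(out) && "f_stat" %in% names(out)) out$F <- out$f_stat
    if (!"p" %in% names(out) && "p_value" %in% names(out)) out$p <- out$p_value
    out <- dplyr::arrange(out[cols], .data$p, .data$snp1, .data$snp2)
  }
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines("# additive coding counts the bim A1 allele", con)
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(out) > 0) {
    fmt <- function(x) {
      if (is.double(x)) sprintf("%.15g", x) else as.character(x)
    }
    body <- do.call(paste, c(lapply(out, fmt), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read back a pair-result table written by [write_pair_results()]
#'
#' @param path Path to the TSV.
#' @return A tibble with the ten result columns.
#' @export
read_pair_results <- function(path) {
  readr::read_tsv(path,
    comment = "#",
    col_types = readr::cols(
      snp1 = readr::col_character(), snp2 = readr::col_character(),
      chr1 = readr::col_integer(), chr2 = readr::col_integer(),
      alpha1 = readr::col_double(), alpha2 = readr::col_double(),
      alpha12 = readr::col_double(), F = readr::col_double(),
      p = readr::col_double(), n_used = readr::col_integer()
    )
  )
}

#' Write a cohort table as TSV
#'
#' @param cohort Cohort tibble (the `complete` flag column, if present, is
#'   dropped on output).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(cohort[c("subject_id", "ptau", "age", "gender", "cds")], path)
  invisible(path)
}
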