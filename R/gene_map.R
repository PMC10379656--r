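#' Map a SNP to genes by position
#'
#' A SNP inside one or more gene bodies (1-based inclusive coordinates)
#' maps to all containing genes. A SNP outside every gene body maps to the
#' nearest gene whose boundary lies within `window_bp` (inclusive at
#' exactly `window_bp`); genes tied at the minimal distance are all
#' returned. With `mode = "all_in_window"` every gene within the window is
#' returned instead of only the nearest. A SNP with no gene in range maps
#' to nothing (intergenic).
#'
#' @param chr,pos SNP chromosome (integer code) and 1-based position.
#' @param annotation Gene annotation tibble from [read_gene_bed()].
#' @param window_bp Maximum distance from SNP to gene boundary (default
#'   100000).
#' @param mode `"nearest"` (default) or `"all_in_window"`.
#' @return Character vector of gene symbols (possibly empty), in
#'   annotation-independent (alphabetical) order.
#' @export
map_snp_to_genes <- function(chr, pos, annotation, window_bp = 100000,
                             mode = c("nearest", "all_in_window")) {
  mode <- match.arg(mode)
  ann <- annotation[annotation$chr == chr, , drop = FALSE]
  if (nrow(ann) == 0) return(character())

  inside <- ann$start_bp <= pos & pos <= ann$end_bp
  if (any(inside)) return(sort(unique(ann$gene_symbol[inside])))

  dist <- ifelse(pos < ann$start_bp, ann$start_bp - pos, pos - ann$end_bp)
  in_window <- dist <= window_bp
  if (!any(in_window)) return(character())
  hits <- if (mode == "nearest") {
    ann$gene_symbol[in_window & dist == min(dist[in_window])]
  } else {
    ann$gene_symbol[in_window]
  }
  sort(unique(hits))
}

#' Expand SNP pairs to gene pairs
#'
#' Maps both SNPs of every pair with [map_snp_to_genes()] and expands to
#' the cross-product of the two gene lists. Gene pairs are unordered:
#' (A, B) and (B, A) collapse to one record whose `supporting_pairs`
#' list-column accumulates every SNP pair that produced it. Pairs whose two
#' SNPs map only to one and the same gene are intragenic, reported in the
#' `intragenic` attribute rather than counted; SNP pairs with an unmapped
#' (intergenic) SNP are listed in the `unmapped` attribute.
#'
#' @param pairs Tibble with `snp1`, `snp2` columns (e.g. an `epi_scan`).
#' @param snps SNP metadata tibble (`snp_id`, `chr`, `pos`), typically
#'   `genotypes$snps`.
#' @param annotation Gene annotation from [read_gene_bed()].
#' @inheritParams map_snp_to_genes
#' @return A tibble with columns `gene1`, `gene2` (alphabetical within
#'   pair), `n_supporting` and `supporting_pairs` (list of `snp1|snp2`
#'   strings); attributes `intragenic` and `unmapped` carry the excluded
#'   SNP pairs.
#' @export
pairs_to_gene_pairs <- function(pairs, snps, annotation, window_bp = 100000,
                                mode = c("nearest", "all_in_window")) {
  mode <- match.arg(mode)
  snp_genes <- setNames(
    purrr::map(seq_len(nrow(snps)), function(k) {
      map_snp_to_genes(snps$chr[k], snps$pos[k], annotation, window_bp, mode)
    }),
    snps$snp_id
  )
  records <- list()
  intragenic <- character()
  unmapped <- character()
  for (k in seq_len(nrow(pairs))) {
    s1 <- pairs$snp1[k]
    s2 <- pairs$snp2[k]
    genes1 <- snp_genes[[s1]] %||% character()
    genes2 <- snp_genes[[s2]] %||% character()
    pair_key <- paste0(s1, "|", s2)
    if (length(genes1) == 0 || length(genes2) == 0) {
      unmapped <- c(unmapped, pair_key)
      next
    }
    grid <- expand.grid(g1 = genes1, g2 = genes2, stringsAsFactors = FALSE)
    distinct <- grid$g1 != grid$g2
    if (!any(distinct)) {
      intragenic <- c(intragenic, pair_key)
      next
    }
    grid <- grid[distinct, , drop = FALSE]
    keys <- paste(pmin(grid$g1, grid$g2), pmax(grid$g1, grid$g2), sep = "\r")
    for (key in unique(keys)) {
      records[[key]] <- c(records[[key]], pair_key)
    }
  }
  if (length(records) == 0) {
    out <- tibble(
      gene1 = character(), gene2 = character(),
      n_supporting = integer(), supporting_pairs = list()
    )
  } else {
    split_keys <- strsplit(names(records), "\r", fixed = TRUE)
    out <- tibble(
      gene1 = vapply(split_keys, `[[`, character(1), 1),
      gene2 = vapply(split_keys, `[[`, character(1), 2),
      n_supporting = unname(vapply(records, length, integer(1))),
      supporting_pairs = unname(records)
    )
    out <- dplyr::arrange(out, .data$gene1, .data$gene2)
  }
  attr(out, "intragenic") <- unique(intragenic)
  attr(out, "unmapped") <- unique(unmapped)
  out
}

#' Categorise gene pairs by disease-gene membership
#'
#' Splits gene pairs three ways by how many members belong to a
#' user-supplied disease-related gene set: `both_ad`, `one_ad`, `none_ad`.
#' Counts over the three categories always sum to the number of distinct
#' pairs.
#'
#' @param gene_pairs Tibble from [pairs_to_gene_pairs()].
#' @param ad_genes Character vector of disease-related gene symbols; an
#'   empty set sends every pair to `none_ad`.
#' @return The input tibble with a `category` factor column added;
#'   attribute `category_counts` holds the named count vector.
#' @export
categorize_pairs <- function(gene_pairs, ad_genes) {
  ad_genes <- trimws(ad_genes)
  n_in <- (gene_pairs$gene1 %in% ad_genes) + (gene_pairs$gene2 %in% ad_genes)
  out <- dplyr::mutate(
    gene_pairs,
    category = factor(
      c("none_ad", "one_ad", "both_ad")[n_in + 1],
      levels = c("both_ad", "one_ad", "none_ad")
    )
  )
  attr(out, "category_counts") <- table(out$category)
  attr(out, "intragenic") <- attr(gene_pairs, "intragenic")
  attr(out, "unmapped") <- attr(gene_pairs, "unmapped")
  out
}

#' Flag gene pairs present in a protein-protein interaction network
#'
#' Marks each gene pair that appears (in either orientation) in the edge
#' list. Matching is case-sensitive exact after whitespace trimming, and
#' the overlap count is invariant to duplicated or flipped edges.
#'
#' @param gene_pairs Tibble from [pairs_to_gene_pairs()] or
#'   [categorize_pairs()].
#' @param edges Tibble of PPI edges from [read_ppi_edges()].
#' @return The input tibble with a logical `ppi_overlap` column; attribute
#'   `n_overlap` holds the overlap count.
#' @export
overlap_with_ppi <- function(gene_pairs, edges) {
  edge_keys <- unique(paste(
    pmin(trimws(edges$gene_a), trimws(edges$gene_b)),
    pmax(trimws(edges$gene_a), trimws(edges$gene_b)),
    sep = "\r"
  ))
  keys <- paste(
    pmin(gene_pairs$gene1, gene_pairs$gene2),
    pmax(gene_pairs$gene1, gene_pairs$gene2),
    sep = "\r"
  )
  out <- dplyr::mutate(gene_pairs, ppi_overlap = keys %in% edge_keys)
  attr(out, "n_overlap") <- sum(out$ppi_overlap)
  attr(out, "intragenic") <- attr(gene_pairs, "intragenic")
  attr(out, "unmapped") <- attr(gene_pairs, "unmapped")
  attr(out, "category_counts") <- attr(gene_pairs, "category_counts")
  out
}
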