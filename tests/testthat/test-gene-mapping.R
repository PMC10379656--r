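toy_annotation <- function() {
  tibble::tibble(
    gene_symbol = c("GENEA", "GENEB", "GENEC", "GENED"),
    chr = c(1L, 1L, 1L, 2L),
    start_bp = c(1000L, 300000L, 300000L, 5000L),
    end_bp = c(10000L, 400000L, 400000L, 9000L)
  )
}

test_that("containment and the 100 kb window boundary are inclusive", {
  ann <- toy_annotation()
  expect_equal(map_snp_to_genes(1, 5000, ann), "GENEA")
  expect_equal(map_snp_to_genes(1, 110000, ann), "GENEA") # 100,000 bp away exactly
  expect_equal(map_snp_to_genes(1, 110001, ann), character()) # 100,001: out
  expect_equal(map_snp_to_genes(3, 5000, ann), character()) # no annotation on chr
  # equidistant genes are all returned
  expect_equal(map_snp_to_genes(1, 305000, ann), c("GENEB", "GENEC"))
})

test_that("nearest-gene mode differs from all-in-window mode", {
  ann <- tibble::tibble(
    gene_symbol = c("NEAR", "FAR"),
    chr = 1L, start_bp = c(20000L, 60000L), end_bp = c(25000L, 65000L)
  )
  expect_equal(map_snp_to_genes(1, 30000, ann), "NEAR")
  expect_equal(
    map_snp_to_genes(1, 30000, ann, mode = "all_in_window"),
    c("FAR", "NEAR")
  )
})

test_that("mapping is independent of annotation record order", {
  ann <- toy_annotation()
  shuffled <- ann[c(3, 1, 4, 2), ]
  for (pos in c(5000, 110000, 305000)) {
    expect_identical(
      map_snp_to_genes(1, pos, ann),
      map_snp_to_genes(1, pos, shuffled)
    )
  }
})

gene_pair_fixture <- function() {
  snps <- tibble::tibble(
    snp_id = c("rsA", "rsB", "rsC", "rsD", "rsE"),
    chr = c(1L, 1L, 1L, 2L, 1L),
    pos = c(5000L, 350000L, 6000L, 7000L, 9000000L)
  )
  pairs <- tibble::tibble(
    snp1 = c("rsA", "rsC", "rsA", "rsA", "rsA"),
    snp2 = c("rsB", "rsB", "rsD", "rsC", "rsE")
  )
  list(snps = snps, pairs = pairs)
}

test_that("SNP pairs expand to deduplicated unordered gene pairs", {
  fx <- gene_pair_fixture()
  gp <- pairs_to_gene_pairs(fx$pairs, fx$snps, toy_annotation())
  # rsA->GENEA, rsB->{GENEB,GENEC}, rsC->GENEA, rsD->GENED, rsE unmapped
  # (rsA,rsB) and (rsC,rsB) both give (GENEA,GENEB) and (GENEA,GENEC)
  expect_equal(gp$gene1, c("GENEA", "GENEA", "GENEA"))
  expect_equal(gp$gene2, c("GENEB", "GENEC", "GENED"))
  expect_equal(gp$n_supporting, c(2L, 2L, 1L))
  expect_setequal(gp$supporting_pairs[[1]], c("rsA|rsB", "rsC|rsB"))
  # same-gene pair (rsA, rsC) is intragenic, not counted
  expect_equal(attr(gp, "intragenic"), "rsA|rsC")
  # pair with an unmapped SNP is excluded and reported
  expect_equal(attr(gp, "unmapped"), "rsA|rsE")
})

test_that("cross-products cover multi-gene mappings", {
  snps <- tibble::tibble(
    snp_id = c("rs1", "rs2"), chr = c(1L, 2L), pos = c(350000L, 7000L)
  )
  pairs <- tibble::tibble(snp1 = "rs1", snp2 = "rs2")
  gp <- pairs_to_gene_pairs(pairs, snps, toy_annotation())
  expect_equal(nrow(gp), 2) # {GENEB,GENEC} x {GENED}
  expect_setequal(gp$gene1, c("GENEB", "GENEC"))
  expect_equal(unique(gp$gene2), "GENED")
})

test_that("categorisation splits pairs by disease-set membership", {
  gp <- tibble::tibble(
    gene1 = c("A", "B", "C", "D", "E", "F"),
    gene2 = c("B", "C", "G", "H", "I", "J"),
    n_supporting = 1L,
    supporting_pairs = as.list(sprintf("p%d", 1:6))
  )
  # planned split: both in set (3), one in set (2), none (1)
  ad <- c("A", "B", "C", "D", "E")
  out <- categorize_pairs(gp, ad)
  counts <- attr(out, "category_counts")
  expect_equal(as.integer(counts[c("both_ad", "one_ad", "none_ad")]), c(2L, 3L, 1L))
  expect_equal(sum(counts), nrow(gp))
  expect_equal(as.character(out$category[out$gene1 == "A"]), "both_ad")
  expect_equal(as.character(out$category[out$gene1 == "F"]), "none_ad")

  # empty disease set sends every pair to none_ad
  all_none <- categorize_pairs(gp, character())
  expect_true(all(all_none$category == "none_ad"))
})

test_that("PPI overlap is unordered and invariant to edge duplication", {
  gp <- tibble::tibble(
    gene1 = c("A", "C", "E", "G", "I"),
    gene2 = c("B", "D", "F", "H", "J"),
    n_supporting = 1L, supporting_pairs = as.list(sprintf("p%d", 1:5))
  )
  edges <- tibble::tibble(
    gene_a = c("B", "C", "X"), gene_b = c("A", "D", "Y") # (B,A) flipped
  )
  out <- overlap_with_ppi(gp, edges)
  expect_equal(attr(out, "n_overlap"), 2)
  expect_equal(out$ppi_overlap, c(TRUE, TRUE, FALSE, FALSE, FALSE))

  # duplicated and re-flipped edges change nothing
  edges_dup <- dplyr::bind_rows(edges, tibble::tibble(gene_a = "A", gene_b = "B"))
  expect_equal(attr(overlap_with_ppi(gp, edges_dup), "n_overlap"), 2)

  # empty edge list: no overlap
  empty <- tibble::tibble(gene_a = character(), gene_b = character())
  expect_equal(attr(overlap_with_ppi(gp, empty), "n_overlap"), 0)
})
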