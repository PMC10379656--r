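#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact test of Hardy-Weinberg proportions from the three
#' genotype counts of a biallelic SNP, conditional on the observed allele
#' counts. The p-value sums the probabilities of every attainable
#' heterozygote count whose conditional probability does not exceed that of
#' the observed table, computed by the standard outward recurrence from the
#' modal heterozygote count. This is the plain exact test (no mid-p
#' correction), matching the default used by common genotype QC tools.
#'
#' Probabilities that are mathematically tied with the observed table can
#' differ in the last floating-point bits; the comparison therefore uses a
#' relative guard of 1e-10 so tied configurations always fall in the tail.
#'
#' @param n_hom1,n_het,n_hom2 Non-negative genotype counts (A1 homozygote,
#'   heterozygote, A2 homozygote). Total must be at least 1.
#' @return The exact p-value in (0, 1].
#' @export
#' @examples
#' hwe_exact_test(25, 0, 0) # monomorphic: only one attainable table
#' hwe_exact_test(5, 5, 5)
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  counts <- c(n_hom1, n_het, n_hom2)
  if (anyNA(counts) || any(counts < 0)) abort("genotype counts must be non-negative")
  n <- sum(counts)
  if (n < 1) abort("at least one genotyped subject required")

  rare <- 2L * min(n_hom1, n_hom2) + n_het # copies of the rarer allele
  if (rare == 0L) return(1) # monomorphic: single attainable configuration

  # attainable heterozygote counts share the parity of the rare-allele count
  h_max <- min(rare, 2L * n - rare)
  h_min <- rare %% 2L
  hs <- seq.int(h_min, h_max, by = 2L)

  # unnormalized probabilities by recurrence from the mode of
  # P(het = h | allele counts); mode approx rare*(2n-rare)/(2n)
  h_mode <- round(rare * (2 * n - rare) / (2 * n))
  if ((h_mode %% 2L) != h_min) h_mode <- h_mode + 1L
  h_mode <- min(max(h_mode, h_min), h_max)

  probs <- numeric(length(hs))
  i_mode <- match(h_mode, hs)
  probs[i_mode] <- 1
  # moving down: P(h-2) = P(h) * h*(h-1) / (4 * (n_r+1) * (n_c+1))
  # where at het count h the rare homs are (rare-h)/2 and common homs
  # (2n - rare - h)/2
  if (i_mode > 1) {
    for (i in seq(i_mode - 1, 1)) {
      h <- hs[i + 1]
      nr <- (rare - h) / 2
      nc <- (2 * n - rare - h) / 2
      probs[i] <- probs[i + 1] * h * (h - 1) / (4 * (nr + 1) * (nc + 1))
    }
  }
  # moving up: P(h+2) = P(h) * 4*nr*nc / ((h+2)*(h+1))
  if (i_mode < length(hs)) {
    for (i in seq(i_mode + 1, length(hs))) {
      h <- hs[i - 1]
      nr <- (rare - h) / 2
      nc <- (2 * n - rare - h) / 2
      probs[i] <- probs[i - 1] * 4 * nr * nc / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}
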