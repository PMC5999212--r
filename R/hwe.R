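#' Conditional exact test of Hardy-Weinberg proportions
#'
#' Computes the exact two-sided p-value for a biallelic genotype table by
#' enumerating every heterozygote count compatible with the observed allele
#' counts. Conditional on `nA` copies of one allele among `2n` alleles in `n`
#' diploids, the probability of `h` heterozygotes is
#' \deqn{P(h) = \frac{n!\,2^h}{n_{AA}!\,h!\,n_{aa}!} \cdot
#'       \frac{n_A!\,n_a!}{(2n)!}}
#' and the two-sided p-value sums the probabilities of all configurations no
#' more probable than the observed one (probability ordering).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative integers).
#' @return Exact p-value in `(0, 1]`; monomorphic tables return 1 by
#'   convention.
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25)   # modal configuration, p >= 0.5
#' hwe_exact_test(0, 100, 0)    # extreme heterozygote excess, tiny p
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop_input("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop_input("at least one genotype required")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  d <- hwe_het_distribution(nA, na)
  p_obs <- d$prob[d$het == n_Aa]
  # probability ordering with a relative tolerance guarding ties
  min(1, sum(d$prob[d$prob <= p_obs * (1 + 1e-9)]))
}

# Exact distribution of the heterozygote count given allele counts nA, na
# (same parity constraint: het steps by 2 from nA mod 2).
hwe_het_distribution <- function(nA, na) {
  n <- (nA + na) / 2
  h <- seq.int(nA %% 2, min(nA, na), by = 2)
  lp <- lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((na - h) / 2) + h * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  list(het = h, prob = exp(lp))
}
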