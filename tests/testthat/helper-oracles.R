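# Independent oracles and small fixture builders shared across tests.

# Exact HWE p-value by a different algebraic route than the implementation:
# P(h) = C(n; nAA, h, naa) 2^h / C(2n, nA), built from products of choose()
# terms rather than log-factorials.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  hs <- seq.int(nA %% 2, min(nA, na), by = 2)
  probs <- vapply(hs, function(h) {
    choose(n, h) * choose(n - h, (nA - h) / 2) * 2^h / choose(2 * n, nA)
  }, numeric(1))
  probs <- probs / sum(probs)  # guard rounding of the choose() products
  p_obs <- probs[hs == n_Aa]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

# Second, scalar transcription of the Weir & Cockerham (1984) two-sample
# variance components, written with explicit r-population sums (r = 2).
oracle_wc <- function(counts1, counts2) {
  n <- c(sum(counts1), sum(counts2))
  p <- c((counts1[2] + 2 * counts1[3]) / (2 * n[1]),
         (counts2[2] + 2 * counts2[3]) / (2 * n[2]))
  h <- c(counts1[2] / n[1], counts2[2] / n[2])
  r <- 2
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# Direct transcription of the depth-based calling rule for the exhaustive
# truth-table comparison.
oracle_call <- function(d1, d2) {
  if (min(d1, d2) >= 2 && d1 + d2 > 10) return(1L)
  if (min(d1, d2) <= 1 && d1 + d2 >= 10) return(if (d2 > d1) 2L else 0L)
  NA_integer_
}

# Wide genotype tibble from a dosage matrix and population labels.
make_geno <- function(X, population, line = sub("_.*", "", population),
                      generation = as.integer(sub(".*_F", "", population)),
                      sex = rep_len(c("F", "M"), nrow(X))) {
  if (is.null(colnames(X))) colnames(X) <- sprintf("L%03d", seq_len(ncol(X)))
  dplyr::bind_cols(
    tibble::tibble(
      individual = sprintf("ind%03d", seq_len(nrow(X))),
      line = rep_len(line, nrow(X)),
      generation = rep_len(generation, nrow(X)),
      population = rep_len(population, nrow(X)),
      sex = sex),
    tibble::as_tibble(X))
}

# HWE genotype matrix at given allele frequencies (one frequency per locus).
hwe_matrix <- function(n, p) {
  L <- length(p)
  matrix(rbinom(n * L, 2L, rep(p, each = n)), nrow = n,
         dimnames = list(NULL, sprintf("L%03d", seq_len(L))))
}
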