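# Depth-based genotype calling and the QC cascade: per-population MAF,
# individual and locus missingness, exact-HWE multi-population screening, and
# population-conditional frequency imputation.

#' Call genotypes from per-allele read depths
#'
#' A call is heterozygous when both alleles reach the minimum depth (default
#' 2) and the combined depth strictly exceeds `min_het_total` (default 10);
#' otherwise homozygous for the majority allele when the minority allele has
#' at most one read and the total reaches `min_hom_depth` (default 10);
#' anything else is missing. Dosage counts copies of allele 2.
#'
#' @param depths Tibble with `depth_a1`, `depth_a2` (and any other columns,
#'   preserved).
#' @param min_het_allele Minimum per-allele depth for a heterozygous call.
#' @param min_het_total Combined depth must be strictly greater than this for
#'   a heterozygous call.
#' @param min_hom_depth Minimum combined depth for a homozygous call.
#' @return The input with a `dosage` column in `{0L, 1L, 2L, NA}`.
#' @export
#' @examples
#' call_genotypes(tibble::tibble(depth_a1 = c(5, 0, 3), depth_a2 = c(6, 12, 7)))
call_genotypes <- function(depths, min_het_allele = 2L, min_het_total = 10L,
                           min_hom_depth = 10L) {
  d1 <- depths$depth_a1
  d2 <- depths$depth_a2
  if (any(d1 < 0 | d2 < 0, na.rm = TRUE)) stop_input("read depths must be >= 0")
  total <- d1 + d2
  lo <- pmin(d1, d2)
  dosage <- rep(NA_integer_, length(d1))
  het <- lo >= min_het_allele & total > min_het_total
  hom <- !het & lo <= 1L & total >= min_hom_depth
  dosage[het] <- 1L
  dosage[hom] <- ifelse(d2[hom] > d1[hom], 2L, 0L)
  depths$dosage <- dosage
  depths
}

#' Assemble a wide genotype table from called depths
#'
#' @param called Output of [call_genotypes()] with `individual` and `locus`.
#' @param design Tibble mapping `individual` to `line`, `generation`,
#'   `population` and `sex` (missing columns are tolerated).
#' @return Wide genotype tibble (see [geno_loci()]).
#' @export
genotypes_from_depths <- function(called, design = NULL) {
  wide <- tidyr::pivot_wider(
    dplyr::select(called, "individual", "locus", "dosage"),
    names_from = "locus", values_from = "dosage")
  if (!is.null(design)) {
    keep <- intersect(names(design), GENO_ID_COLS)
    wide <- dplyr::left_join(wide, dplyr::distinct(design[keep]),
                             by = "individual")
    wide <- dplyr::relocate(wide, dplyr::any_of(GENO_ID_COLS))
  }
  wide
}

# Per-population genotype counts for every locus: a list of 3 x L matrices
# (rows AA/Aa/aa in dosage order 0/1/2) keyed by population label.
pop_genotype_counts <- function(gm) {
  X <- geno_matrix(gm)
  pops <- gm$population %||% rep("all", nrow(gm))
  lapply(split(seq_len(nrow(X)), pops), function(idx) {
    sub <- X[idx, , drop = FALSE]
    rbind(n0 = colSums(sub == 0L, na.rm = TRUE),
          n1 = colSums(sub == 1L, na.rm = TRUE),
          n2 = colSums(sub == 2L, na.rm = TRUE))
  })
}

#' Per-population minor allele frequencies
#'
#' @param gm Wide genotype tibble with a `population` column.
#' @return Tibble `locus`, `population`, `n_called`, `maf` (missing genotypes
#'   are excluded from the denominators; populations with no calls at a locus
#'   contribute `NA`).
#' @export
per_population_maf <- function(gm) {
  counts <- pop_genotype_counts(gm)
  purrr::imap_dfr(counts, function(cn, pop) {
    n <- colSums(cn)
    p <- (cn["n1", ] + 2 * cn["n2", ]) / (2 * n)
    tibble::tibble(locus = colnames(cn), population = pop, n_called = n,
                   maf = ifelse(n > 0, pmin(p, 1 - p), NA_real_))
  })
}

#' Filter loci on per-population minor allele frequency
#'
#' A locus is retained when its MAF reaches `threshold` in at least one
#' population.
#'
#' @param gm Wide genotype tibble with `population`.
#' @param threshold MAF threshold (default 0.05).
#' @return Filtered genotype tibble; removed loci in `attr(, "removed")`.
#' @export
filter_maf <- function(gm, threshold = 0.05) {
  maf <- per_population_maf(gm)
  keep <- dplyr::summarise(
    dplyr::group_by(maf, .data$locus),
    keep = any(.data$maf >= threshold, na.rm = TRUE), .groups = "drop")
  drop <- keep$locus[!keep$keep]
  out <- gm[setdiff(names(gm), drop)]
  attr(out, "removed") <- drop
  out
}

#' Remove individuals with at least 50% missing genotypes
#'
#' @param gm Wide genotype tibble.
#' @param max_missing Individuals with a missing fraction `>=` this value are
#'   removed (default 0.5).
#' @return Filtered tibble; removed individual ids in `attr(, "removed")`.
#' @export
filter_missing_individuals <- function(gm, max_missing = 0.5) {
  X <- geno_matrix(gm)
  frac <- rowMeans(is.na(X))
  out <- gm[frac < max_missing, ]
  attr(out, "removed") <- gm$individual[frac >= max_missing]
  out
}

#' Remove loci not called in at least 50% of individuals in every population
#'
#' @param gm Wide genotype tibble with `population`.
#' @param min_call_rate Per-population call-rate floor (default 0.5; a call
#'   rate exactly at the floor is retained).
#' @return Filtered tibble; removed locus ids in `attr(, "removed")`.
#' @export
filter_missing_loci <- function(gm, min_call_rate = 0.5) {
  X <- geno_matrix(gm)
  pops <- gm$population %||% rep("all", nrow(gm))
  rate <- vapply(split(seq_len(nrow(X)), pops),
                 function(idx) colMeans(!is.na(X[idx, , drop = FALSE])),
                 numeric(ncol(X)))
  if (is.null(dim(rate))) rate <- matrix(rate, nrow = 1)
  keep <- apply(rate >= min_call_rate, 1, all)
  drop <- colnames(X)[!keep]
  out <- gm[setdiff(names(gm), drop)]
  attr(out, "removed") <- drop
  out
}

#' Exact-HWE p-values per locus and population
#'
#' @param gm Wide genotype tibble with `population`.
#' @return Tibble `locus`, `population`, `n_AA`, `n_Aa`, `n_aa`, `p_value`
#'   (populations with no calls at a locus give p = 1).
#' @export
hwe_by_population <- function(gm) {
  counts <- pop_genotype_counts(gm)
  purrr::imap_dfr(counts, function(cn, pop) {
    p <- vapply(seq_len(ncol(cn)), function(j) {
      if (sum(cn[, j]) == 0) return(1)
      hwe_exact_test(cn["n0", j], cn["n1", j], cn["n2", j])
    }, numeric(1))
    tibble::tibble(locus = colnames(cn), population = pop,
                   n_AA = cn["n0", ], n_Aa = cn["n1", ], n_aa = cn["n2", ],
                   p_value = p)
  })
}

#' Remove loci out of Hardy-Weinberg proportions in multiple populations
#'
#' A locus is removed when the exact test is significant at `alpha` in
#' `min_populations` or more populations.
#'
#' @param gm Wide genotype tibble with `population`.
#' @param alpha Significance level (default 0.05).
#' @param min_populations Number of significant populations that triggers
#'   removal (default 2).
#' @return Filtered tibble; removed loci in `attr(, "removed")`, the per
#'   locus/population p-values in `attr(, "hwe")`.
#' @export
filter_hwe <- function(gm, alpha = 0.05, min_populations = 2L) {
  hw <- hwe_by_population(gm)
  sig <- dplyr::summarise(dplyr::group_by(hw, .data$locus),
                          n_sig = sum(.data$p_value < alpha),
                          .groups = "drop")
  drop <- sig$locus[sig$n_sig >= min_populations]
  out <- gm[setdiff(names(gm), drop)]
  attr(out, "removed") <- drop
  attr(out, "hwe") <- hw
  out
}

#' Impute missing genotypes from population genotype frequencies
#'
#' Each missing entry is filled from the genotype-frequency distribution of
#' its own population at that locus (maximum-likelihood frequencies from the
#' called genotypes), either by sampling from it or by taking its mode. A
#' locus with no calls in a population falls back to the frequencies pooled
#' over all individuals (recorded in the log).
#'
#' @param gm Wide genotype tibble with `population`.
#' @param method `"sample"` (default) draws from the genotype distribution;
#'   `"mode"` fills deterministically with the most frequent genotype.
#' @param seed Integer seed used when sampling.
#' @return List with `genotypes` (no missing entries),
#'   `freq_correlation` (Pearson correlation of per-locus allele frequencies
#'   before vs after imputation) and `fallback` (loci x population pairs that
#'   used the global frequencies).
#' @export
impute_missing <- function(gm, method = c("sample", "mode"), seed = 1L) {
  method <- match.arg(method)
  X <- geno_matrix(gm)
  pops <- gm$population %||% rep("all", nrow(gm))
  p_before <- colMeans(X, na.rm = TRUE) / 2
  fallback <- list()
  with_seed(if (method == "sample") seed else NULL, {
    for (pop in unique(pops)) {
      rows <- which(pops == pop)
      sub <- X[rows, , drop = FALSE]
      miss_loci <- which(colSums(is.na(sub)) > 0)
      for (j in miss_loci) {
        obs <- sub[, j]
        tab <- tabulate(obs + 1L, nbins = 3L)
        if (sum(tab) == 0) {
          tab <- tabulate(X[, j] + 1L, nbins = 3L)
          fallback[[length(fallback) + 1L]] <-
            tibble::tibble(locus = colnames(X)[j], population = pop)
        }
        if (sum(tab) == 0) tab <- c(1, 0, 0)  # locus entirely missing
        nas <- which(is.na(obs))
        fill <- if (method == "sample") {
          sample(0:2, length(nas), replace = TRUE, prob = tab / sum(tab))
        } else {
          rep(which.max(tab) - 1L, length(nas))
        }
        X[rows[nas], j] <- as.integer(fill)
      }
    }
  })
  p_after <- colMeans(X) / 2
  ok <- is.finite(p_before)
  r <- if (sum(ok) >= 2 && sd(p_before[ok]) > 0 && sd(p_after[ok]) > 0) {
    cor(p_before[ok], p_after[ok])
  } else 1
  out <- gm
  out[colnames(X)] <- tibble::as_tibble(X)
  list(genotypes = out, freq_correlation = r,
       fallback = dplyr::bind_rows(fallback))
}

#' Per-locus, per-population inbreeding coefficient
#'
#' `F_IS = 1 - H_obs / H_exp` with the small-sample correction
#' `H_exp = 2 p (1 - p) * 2n / (2n - 1)`; undefined (NA) for monomorphic
#' locus/population pairs.
#'
#' @param gm Wide genotype tibble with `population`.
#' @return Tibble `locus`, `population`, `n`, `p`, `h_obs`, `h_exp`, `fis`.
#' @export
compute_fis <- function(gm) {
  counts <- pop_genotype_counts(gm)
  purrr::imap_dfr(counts, function(cn, pop) {
    n <- colSums(cn)
    p <- (cn["n1", ] + 2 * cn["n2", ]) / (2 * n)
    h_obs <- cn["n1", ] / n
    h_exp <- 2 * p * (1 - p) * (2 * n) / (2 * n - 1)
    tibble::tibble(locus = colnames(cn), population = pop, n = n, p = p,
                   h_obs = h_obs, h_exp = h_exp,
                   fis = ifelse(h_exp > 0, 1 - h_obs / h_exp, NA_real_))
  })
}

#' Run the full QC cascade
#'
#' Applies, in order: the per-population MAF screen, removal of individuals
#' with >= 50% missing genotypes, removal of loci under 50% call rate in
#' any population, the multi-population exact-HWE screen, and imputation of
#' the remaining missing genotypes.
#'
#' @param gm Wide genotype tibble with `population` (e.g. from
#'   [genotypes_from_depths()]).
#' @param maf_threshold,max_missing,min_call_rate,hwe_alpha,min_populations
#'   Thresholds of the individual steps (see the step functions).
#' @param impute_method Passed to [impute_missing()].
#' @param seed Seed for the imputation draw.
#' @return List of class `hatch_qc`: `genotypes` (imputed, filtered) and
#'   `report` (a one-row tibble of the cascade bookkeeping), plus the
#'   per-step removal lists in `removed`.
#' @export
qc_pipeline <- function(gm, maf_threshold = 0.05, max_missing = 0.5,
                        min_call_rate = 0.5, hwe_alpha = 0.05,
                        min_populations = 2L,
                        impute_method = "sample", seed = 1L) {
  loci_in <- length(geno_loci(gm))
  ind_in <- nrow(gm)
  g1 <- filter_maf(gm, maf_threshold)
  g2 <- filter_missing_individuals(g1, max_missing)
  g3 <- filter_missing_loci(g2, min_call_rate)
  g4 <- filter_hwe(g3, hwe_alpha, min_populations)
  imp <- impute_missing(g4, method = impute_method, seed = seed)
  removed <- list(maf = attr(g1, "removed"),
                  individuals = attr(g2, "removed"),
                  missing_loci = attr(g3, "removed"),
                  hwe = attr(g4, "removed"))
  report <- tibble::tibble(
    loci_in = loci_in,
    loci_removed_maf = length(removed$maf),
    loci_after_maf = loci_in - length(removed$maf),
    individuals_in = ind_in,
    individuals_removed = length(removed$individuals),
    loci_removed_missingness = length(removed$missing_loci),
    loci_removed_hwe = length(removed$hwe),
    loci_out = length(geno_loci(imp$genotypes)),
    individuals_out = nrow(imp$genotypes),
    imputation_freq_correlation = imp$freq_correlation
  )
  structure(list(genotypes = imp$genotypes, report = report,
                 removed = removed, hwe = attr(g4, "hwe")),
            class = "hatch_qc")
}

#' @export
print.hatch_qc <- function(x, ...) {
  r <- x$report
  cat("Genotype QC cascade\n")
  cat(sprintf("  loci: %d in -> %d after MAF -> -%d missingness -> -%d HWE -> %d out\n",
              r$loci_in, r$loci_after_maf, r$loci_removed_missingness,
              r$loci_removed_hwe, r$loci_out))
  cat(sprintf("  individuals: %d in, %d removed (>=50%% missing)\n",
              r$individuals_in, r$individuals_removed))
  cat(sprintf("  imputation allele-frequency correlation: %.4f\n",
              r$imputation_freq_correlation))
  invisible(x)
}
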