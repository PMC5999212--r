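test_that("the depth caller applies the heterozygote and homozygote rules", {
  d <- tibble::tibble(depth_a1 = c(5, 0, 3, 12, 1, 2),
                      depth_a2 = c(6, 12, 7, 0, 11, 9))
  out <- call_genotypes(d)
  # (5,6): both >= 2, total 11 > 10 -> het
  # (0,12): single allele at depth >= 10 -> hom allele 2
  # (3,7): total 10 not > 10, minority 3 > 1 -> missing
  # (1,11): minority 1, total 12 >= 10 -> hom allele 2
  # (2,9): total 11 > 10, both >= 2 -> het
  expect_equal(out$dosage, c(1L, 2L, NA, 0L, 2L, 1L))
  expect_error(call_genotypes(tibble::tibble(depth_a1 = -1, depth_a2 = 3)),
               "depths")
})

test_that("caller matches a direct transcription over all totals <= 30", {
  grid <- expand.grid(d1 = 0:30, d2 = 0:30)
  grid <- grid[grid$d1 + grid$d2 <= 30, ]
  got <- call_genotypes(tibble::tibble(depth_a1 = grid$d1,
                                       depth_a2 = grid$d2))$dosage
  want <- mapply(oracle_call, grid$d1, grid$d2)
  expect_identical(got, as.integer(want))
})

test_that("caller concordance with simulated truth degrades below depth 12", {
  fn_rate <- vapply(c(8, 10, 12, 20, 40), function(mu) {
    cfg <- sim_config(n_loci = 60, samples_per_population = 40,
                      founder_freq = 0.5,
                      depth_model = list(mean = mu, dispersion = 10,
                                         error = 0.001),
                      seed = 50 + mu)
    sim <- simulate_study(cfg, alignments = FALSE)
    called <- call_genotypes(sim$depths)
    het <- called[called$truth_dosage == 1L, ]
    mean(is.na(het$dosage) | het$dosage != 1L)
  }, numeric(1))
  expect_true(all(diff(fn_rate) < 0))  # monotone improvement with depth
  expect_lt(fn_rate[5], 0.02)
})

test_that("per-population MAF screening keeps loci polymorphic anywhere", {
  # pop A: (18,2,0) -> MAF 0.05; pop B: (20,0,0) -> 0; pop C: (19,1,0) -> 0.025
  X <- rbind(
    matrix(rep(c(rep(0L, 18), 1L, 1L), 1), ncol = 1),
    matrix(rep(0L, 20), ncol = 1),
    matrix(c(rep(0L, 19), 1L), ncol = 1))
  gm <- make_geno(X, population = rep(c("A_F1", "B_F1", "C_F1"), each = 20))
  kept <- filter_maf(gm, 0.05)
  expect_true("L001" %in% geno_loci(kept))

  # monomorphic everywhere is removed
  gm2 <- make_geno(matrix(0L, 30, 1), population = rep(c("A_F1", "B_F1"), 15))
  expect_length(geno_loci(filter_maf(gm2, 0.05)), 0)

  # MAF 0.04 in all but one population at 0.06 -> retained
  mk <- function(nmin, n) c(rep(1L, nmin), rep(0L, n - nmin))
  X3 <- cbind(c(mk(4, 50), mk(6, 50)))  # 0.04 in A, 0.06 in B
  gm3 <- make_geno(X3, population = rep(c("A_F1", "B_F1"), each = 50))
  expect_length(geno_loci(filter_maf(gm3, 0.05)), 1)
})

test_that("missingness filters use the documented boundaries", {
  X <- matrix(0L, 10, 1000)
  X[1, 1:501] <- NA  # 50.1% missing -> removed
  X[2, 1:500] <- NA  # exactly 50% missing -> removed
  X[3, 1:499] <- NA  # 49.9% -> kept
  gm <- make_geno(X, population = rep("A_F1", 10))
  out <- filter_missing_individuals(gm)
  expect_equal(nrow(out), 8)
  expect_setequal(attr(out, "removed"), c("ind001", "ind002"))

  # locus call rate >= 0.5 required in EVERY population
  Y <- matrix(0L, 20, 3)
  Y[1:5, 2] <- NA    # locus 2: 5/10 called in pop A (exactly 0.5) -> kept
  Y[1:6, 3] <- NA    # locus 3: 4/10 in pop A -> removed
  gm2 <- make_geno(Y, population = rep(c("A_F1", "B_F1"), each = 10))
  out2 <- filter_missing_loci(gm2)
  expect_setequal(geno_loci(out2), c("L001", "L002"))
  expect_equal(attr(out2, "removed"), "L003")
})

test_that("multi-population HWE screen removes loci significant twice", {
  withr::with_seed(7, {
    # locus 1: all heterozygotes in two populations (gross violation);
    # locus 2: violation in one population only; locus 3: HWE everywhere
    mk_pop <- function(l1, n = 60) {
      cbind(L001 = l1, L002 = rbinom(n, 2, 0.5), L003 = rbinom(n, 2, 0.5))
    }
    A <- mk_pop(rep(1L, 60))
    B <- mk_pop(rep(1L, 60))
    C <- mk_pop(rbinom(60, 2, 0.5))
    X <- rbind(A, B, C)
    X[121:180, 2] <- rep(1L, 60)  # locus 2 violated in population C only
    gm <- make_geno(X, population = rep(c("A_F1", "B_F1", "C_F1"), each = 60))
    out <- filter_hwe(gm, alpha = 0.05, min_populations = 2)
    expect_equal(attr(out, "removed"), "L001")
    expect_true(all(c("L002", "L003") %in% geno_loci(out)))
  })
})

test_that("imputation preserves allele frequencies and is seed-stable", {
  withr::with_seed(3, {
    X <- hwe_matrix(400, runif(1000, 0.1, 0.9))
    miss <- sample(length(X), round(0.05 * length(X)))
    Xm <- X
    Xm[miss] <- NA
    gm <- make_geno(Xm, population = rep(c("INT_F1", "SEG_F1"), each = 200))
  })
  imp1 <- impute_missing(gm, seed = 42)
  imp2 <- impute_missing(gm, seed = 42)
  expect_identical(imp1$genotypes, imp2$genotypes)
  expect_false(anyNA(geno_matrix(imp1$genotypes)))
  expect_gt(imp1$freq_correlation, 0.99)

  # no missing data: identity and r = 1
  gm_full <- make_geno(hwe_matrix(50, rep(0.4, 20)),
                       population = rep("A_F1", 50))
  imp3 <- impute_missing(gm_full, seed = 1)
  expect_identical(imp3$genotypes, gm_full)
  expect_equal(imp3$freq_correlation, 1)
})

test_that("F_IS is near -1 for full heterozygosity and near 0 under HWE", {
  gm <- make_geno(matrix(1L, 50, 1), population = rep("A_F1", 50))
  fis <- compute_fis(gm)
  expect_lt(fis$fis, -0.9)

  withr::with_seed(11, {
    gm2 <- make_geno(hwe_matrix(200, runif(500, 0.2, 0.8)),
                     population = rep("A_F1", 200))
  })
  med <- median(compute_fis(gm2)$fis, na.rm = TRUE)
  expect_gt(med, -0.05)
  expect_lt(med, 0.05)

  gm3 <- make_geno(matrix(0L, 30, 1), population = rep("A_F1", 30))
  expect_true(is.na(compute_fis(gm3)$fis))
})

test_that("QC cascade bookkeeping reconciles exactly on planted violations", {
  withr::with_seed(19, {
    n_pop <- 40
    base <- hwe_matrix(2 * n_pop, runif(20, 0.3, 0.7))
    colnames(base) <- sprintf("L%03d", 1:20)
    # plant: L001 monomorphic (MAF removal); L002 all-het in both populations
    # (HWE removal); L003 called in under half of population A (missingness);
    # individual 1 missing at >= 50% of loci
    base[, 1] <- 0L
    base[, 2] <- 1L
    base[1:25, 3] <- NA
    base[1, 4:20] <- NA
    gm <- make_geno(base, population = rep(c("A_F1", "B_F1"), each = n_pop))
  })
  qc <- qc_pipeline(gm, seed = 5)
  expect_equal(qc$removed$maf, "L001")
  expect_equal(qc$removed$individuals, "ind001")
  expect_equal(qc$removed$missing_loci, "L003")
  expect_equal(qc$removed$hwe, "L002")
  r <- qc$report
  expect_equal(r$loci_in, 20)
  expect_equal(r$loci_out,
               r$loci_in - r$loci_removed_maf - r$loci_removed_missingness -
                 r$loci_removed_hwe)
  expect_equal(r$individuals_out, r$individuals_in - r$individuals_removed)
  expect_false(anyNA(geno_matrix(qc$genotypes)))
  # tidy/glance surface the same bookkeeping
  expect_equal(glance(qc), r)
  expect_equal(nrow(tidy(qc)), ncol(r))
})

test_that("end-to-end calling from simulated depths is highly concordant", {
  cfg <- sim_config(n_loci = 80, samples_per_population = 40, seed = 23)
  sim <- simulate_study(cfg, alignments = FALSE)
  called <- call_genotypes(sim$depths)
  conc <- mean(called$dosage == called$truth_dosage, na.rm = TRUE)
  expect_gt(conc, 0.99)
  gm <- genotypes_from_depths(called, sim$genotypes[1:5])
  expect_equal(nrow(gm), nrow(sim$genotypes))
  expect_length(geno_loci(gm), 80)
})
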