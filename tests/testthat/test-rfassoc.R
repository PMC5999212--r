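# Small, seeded association scenarios. Forest sizes are kept modest; the
# signal strengths are chosen so the checks are about ranking and purging
# behaviour, not about squeezing maximal power from tiny forests.

sim_assoc <- function(n = 240, L = 200, n_causal = 5, h2 = 0.5,
                      line_effect = 0, seed = 1) {
  withr::with_seed(seed, {
    X <- hwe_matrix(n, runif(L, 0.2, 0.8))
    colnames(X) <- sprintf("L%04d", seq_len(L))
    gm <- make_geno(X, population = rep(c("INT_F1", "INT_F2",
                                          "SEG_F1", "SEG_F2"), each = n / 4))
    causal <- sample(colnames(X), n_causal)
    # effect sizes bounded away from zero so every causal locus is rankable
    eff <- sample(c(-1, 1), n_causal, replace = TRUE) *
      runif(n_causal, 0.7, 1.3)
    g <- X[, causal, drop = FALSE] %*% eff
    y <- if (h2 > 0) {
      sqrt(h2) * as.numeric(scale(g)) + sqrt(1 - h2) * rnorm(n)
    } else {
      rnorm(n)
    }
    y <- y + line_effect * (gm$line == "SEG")
    pheno <- tibble::tibble(
      individual = gm$individual, line = gm$line,
      generation = gm$generation, population = gm$population, sex = gm$sex,
      year = 2000L + gm$generation, age = 4L, return_day = y)
    list(gm = gm, pheno = pheno, causal = causal, y = y,
         gscore = as.numeric(g))
  })
}

test_that("confounder correction is orthogonal and preserves categories", {
  sc <- sim_assoc(seed = 3)
  co <- correct_confounders(sc$pheno, sc$gm, traits = c("age", "return_day"))
  mm <- model.matrix(~ line + sex + year + pc1, co$design)
  # residual phenotypes and genotypes orthogonal to every covariate column
  r <- co$pheno$return_day
  expect_lt(max(abs(crossprod(mm, r))) / length(r), 1e-8)
  expect_lt(max(abs(crossprod(mm, co$geno))) / nrow(mm), 1e-8)
  expect_lt(max(abs(crossprod(mm, co$geno_age))) / nrow(mm), 1e-8)
  expect_s3_class(co$pheno$age, "factor")
  expect_setequal(levels(droplevels(co$pheno$age)), "4")

  # a phenotype that is an exact function of the covariates residualises to 0
  sc2 <- sc
  sc2$pheno$return_day <- 2 * (sc$pheno$line == "SEG") + 3 * (sc$pheno$sex == "M")
  co2 <- correct_confounders(sc2$pheno, sc2$gm, traits = "return_day")
  expect_lt(max(abs(co2$pheno$return_day)), 1e-8)
})

test_that("line-confounded signal is recovered after correction", {
  sc_conf <- sim_assoc(n = 400, line_effect = 3, seed = 7)
  sc_free <- sim_assoc(n = 400, line_effect = 0, seed = 7)
  # identical genotypes/causal loci; only the line effect differs
  co_conf <- correct_confounders(sc_conf$pheno, sc_conf$gm, "return_day")
  co_free <- correct_confounders(sc_free$pheno, sc_free$gm, "return_day")
  g <- sc_conf$gscore[match(co_conf$individuals, sc_conf$gm$individual)]
  r_conf <- cor(co_conf$pheno$return_day, g)
  r_free <- cor(co_free$pheno$return_day, g)
  expect_lt(abs(r_conf - r_free), 0.05)
})

test_that("importances rank noise-free causal loci at the top", {
  sc <- sim_assoc(n = 300, L = 500, n_causal = 5, h2 = 0.999, seed = 11)
  co <- correct_confounders(sc$pheno, sc$gm, "return_day")
  imp <- grow_importances(co, "return_day", ntree = 800, seed = 4)
  top2pct <- imp$locus[seq_len(ceiling(0.02 * nrow(imp)))]
  expect_true(all(sc$causal %in% top2pct))
  expect_gt(min(attr(imp, "pairwise_cor")), 0.8)
  expect_gt(attr(imp, "metric"), 20)  # strong OOB signal (%)
})

test_that("permuted phenotypes yield importances centred at zero", {
  sc <- sim_assoc(n = 200, L = 300, h2 = 0, seed = 13)
  co <- correct_confounders(sc$pheno, sc$gm, "return_day")
  imp <- grow_importances(co, "return_day", ntree = 500, seed = 6)
  se <- sd(imp$importance) / sqrt(nrow(imp))
  expect_lt(abs(mean(imp$importance)), 2 * se + 1e-6)
})

test_that("ntree tuning returns the smallest stable candidate", {
  sc <- sim_assoc(n = 240, L = 150, n_causal = 5, h2 = 0.9, seed = 17)
  co <- correct_confounders(sc$pheno, sc$gm, "return_day")
  nt <- tune_ntree(co, "return_day", candidate_ntrees = c(400, 800),
                   threshold = 0.8, seed = 8)
  expect_true(nt %in% c(400L, 800L))
  stab <- attr(nt, "stability")
  expect_true(all(c("ntree", "min_cor") %in% names(stab)))
  # an unreachable threshold falls back to the largest candidate, warning
  expect_warning(
    nt2 <- tune_ntree(co, "return_day", candidate_ntrees = c(50, 100),
                      threshold = 0.999999, seed = 8),
    "largest")
  expect_equal(as.integer(nt2), 100L)
})

test_that("top-fraction screening records a metric per usable fraction", {
  sc <- sim_assoc(n = 240, L = 400, n_causal = 2, h2 = 0.95, seed = 19)
  co <- correct_confounders(sc$pheno, sc$gm, "return_day")
  imp <- grow_importances(co, "return_day", ntree = 600, seed = 9)
  screen <- evaluate_top_fractions(co, "return_day", imp, ntree = 600,
                                   fractions = c(0.005, 0.01, 0.05),
                                   seed = 10)
  expect_equal(nrow(screen$metrics), 3)
  expect_equal(screen$metric_kind, "percent_variation_explained")
  # signal concentrated in the top handful of loci: small fraction wins
  expect_lte(screen$best_fraction, 0.01)

  # pure noise: metrics collapse far below the signal case; the smallest
  # fraction (heaviest overfit) goes non-positive, larger fractions retain
  # only the optimistic bias of importance-based pre-selection
  scn <- sim_assoc(n = 400, L = 300, h2 = 0, seed = 23)
  con <- correct_confounders(scn$pheno, scn$gm, "return_day")
  impn <- grow_importances(con, "return_day", ntree = 500, seed = 11)
  scrn <- evaluate_top_fractions(con, "return_day", impn, ntree = 500,
                                 fractions = c(0.01, 0.05), seed = 12)
  expect_lt(scrn$metrics$metric[scrn$metrics$fraction == 0.01], 5)
  expect_true(all(scrn$metrics$metric < screen$metrics$metric[1] - 20))
})

test_that("backward purging keeps causal loci and records its trajectory", {
  sc <- sim_assoc(n = 300, L = 200, n_causal = 5, h2 = 0.999, seed = 29)
  co <- correct_confounders(sc$pheno, sc$gm, "return_day")
  imp <- grow_importances(co, "return_day", ntree = 800, seed = 13)
  candidates <- union(sc$causal, imp$locus[1:30])
  ps <- backward_purge(co, "return_day", candidates, ntree = 600, seed = 14)
  expect_true(all(sc$causal %in% ps$loci))
  # metric of the chosen set is close to the all-candidates ceiling
  ceiling_metric <- ps$trajectory$metric[1]
  expect_gt(ps$metric, ceiling_metric - 5)
  # trajectory covers every purge step down to two loci
  expect_equal(ps$trajectory$size,
               seq(length(candidates), 2))
  expect_equal(length(ps$removal_order), length(candidates) - 2)
  expect_s3_class(autoplot(ps), "ggplot")

  # tiny candidate sets are returned unpurged with a warning
  expect_warning(ps2 <- backward_purge(co, "return_day", sc$causal[1:2],
                                       ntree = 300, seed = 15),
                 "unpurged")
  expect_equal(ps2$loci, sc$causal[1:2])
})

test_that("noise loci do not lift a purged optimum appreciably", {
  sc <- sim_assoc(n = 240, L = 150, n_causal = 5, h2 = 0.95, seed = 31)
  co <- correct_confounders(sc$pheno, sc$gm, "return_day")
  base <- backward_purge(co, "return_day", sc$causal, ntree = 600, seed = 16)
  noisy <- backward_purge(co, "return_day",
                          c(sc$causal, setdiff(co$loci, sc$causal)[1:10]),
                          ntree = 600, seed = 16)
  expect_lt(noisy$metric - base$metric, 3)
})

test_that("the full association chain is reproducible and classifies age", {
  cfg <- sim_config(
    n_loci = 150, samples_per_population = 40, n_generations = 2,
    founder_freq = 0.5,
    trait_architectures = list(return_day = list(h2 = 0.8, n_causal = 5)),
    seed = 37)
  sim <- simulate_study(cfg, depths = FALSE, alignments = FALSE)
  # a single small ntree candidate may not stabilise the age importances;
  # the documented fallback (largest candidate, with a warning) is fine here
  res <- suppressWarnings(
    run_association(sim$phenotypes, sim$genotypes,
                    traits = c("age", "return_day"), map = sim$map,
                    candidate_ntrees = 400,
                    fractions = c(0.02, 0.05), seed = 5))
  expect_named(res$predictors, c("age", "return_day"))
  expect_equal(nrow(res$summary), 2)
  expect_equal(res$summary$metric_kind,
               c("oob_classification_error", "percent_variation_explained"))
  expect_true(all(res$summary$n_mapped <= res$summary$n_predictors))
  # founders excluded from the analysed design
  expect_equal(res$summary$n_individuals[1], 160)
  res2 <- suppressWarnings(
    run_association(sim$phenotypes, sim$genotypes,
                    traits = c("age", "return_day"), map = sim$map,
                    candidate_ntrees = 400,
                    fractions = c(0.02, 0.05), seed = 5))
  expect_identical(res$predictors$return_day$loci,
                   res2$predictors$return_day$loci)
  expect_identical(res$summary, res2$summary)
  # a trait missing from the table is skipped with a warning
  expect_warning(
    res3 <- run_association(sim$phenotypes[setdiff(names(sim$phenotypes),
                                                   "dgc")],
                            sim$genotypes, traits = c("return_day", "dgc"),
                            candidate_ntrees = 300, fractions = 0.05,
                            seed = 6),
    "skipped")
  expect_named(res3$predictors, "return_day")
})

test_that("importance ranking agrees with an independent forest implementation", {
  skip_if_not_installed("randomForest")
  sc <- sim_assoc(n = 240, L = 120, n_causal = 4, h2 = 0.9, seed = 43)
  co <- correct_confounders(sc$pheno, sc$gm, "return_day")
  imp <- grow_importances(co, "return_day", ntree = 600, seed = 21)
  rf <- withr::with_seed(21, randomForest::randomForest(
    x = co$geno, y = co$pheno$return_day, ntree = 600, importance = TRUE))
  alt <- randomForest::importance(rf, type = 1)[, 1]
  # the two implementations agree on which loci matter
  top_ours <- utils::head(imp$locus, 6)
  top_alt <- names(sort(alt, decreasing = TRUE))[1:6]
  expect_gte(length(intersect(top_ours, top_alt)), 4)
  expect_true(all(sc$causal %in% top_ours))
  expect_true(all(sc$causal %in% top_alt))
})
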