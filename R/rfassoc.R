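# Random-forest association with confounder correction, ntree stability
# tuning, importance averaging, top-fraction screening and backward purging.

#' Correct phenotypes and genotypes for confounding structure
#'
#' Computes PC1 of the centred (imputed) dosage matrix and replaces every
#' continuous phenotype and every locus dosage column by its OLS residual
#' against hatchery line, sex, age, year and PC1. The age trait stays
#' categorical; for it, genotypes are corrected with every factor except age.
#' Founders are excluded by default so the analysed design is the paired
#' integrated/segregated contrast.
#'
#' @param pheno Phenotype tibble (see [simulate_phenotypes()] for the shape).
#' @param gm Imputed wide genotype tibble (no missing dosages).
#' @param traits Traits to correct (default [hatch_traits()]).
#' @param exclude_founders Drop the P1 line before correcting (default TRUE).
#' @return List of class `hatch_corrected`: `individuals`, `pheno` (tibble of
#'   residual continuous traits, `age` kept as a factor), `geno` (residual
#'   dosage matrix), `geno_age` (residuals without the age covariate),
#'   `design` (covariate tibble incl. `pc1`), `loci`.
#' @export
correct_confounders <- function(pheno, gm, traits = hatch_traits(),
                                exclude_founders = TRUE) {
  if (exclude_founders) {
    gm <- gm[gm$line != "P1", , drop = FALSE]
  }
  ids <- intersect(gm$individual, pheno$individual)
  gm <- gm[match(ids, gm$individual), , drop = FALSE]
  ph <- pheno[match(ids, pheno$individual), , drop = FALSE]
  X <- geno_matrix(gm)
  if (anyNA(X)) stop_input("genotypes must be imputed before correction")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  pc1 <- prcomp(Xc, center = FALSE, rank. = 1)$x[, 1]
  design <- tibble::tibble(
    line = factor(ph$line), sex = factor(ph$sex),
    age = as.numeric(ph$age), year = factor(ph$year), pc1 = pc1)
  mm_full <- model.matrix(~ line + sex + age + year + pc1, design)
  mm_noage <- model.matrix(~ line + sex + year + pc1, design)
  # drop aliased columns (e.g. year == generation within a single line)
  drop_aliased <- function(mm) {
    q <- qr(mm)
    if (q$rank < ncol(mm)) mm <- mm[, q$pivot[seq_len(q$rank)], drop = FALSE]
    mm
  }
  mm_full <- drop_aliased(mm_full)
  mm_noage <- drop_aliased(mm_noage)
  geno <- qr.resid(qr(mm_full), X)
  geno_age <- qr.resid(qr(mm_noage), X)
  out_ph <- tibble::tibble(.rows = length(ids))
  for (tr in setdiff(traits, "age")) {
    y <- ph[[tr]]
    ok <- !is.na(y)
    r <- rep(NA_real_, length(y))
    r[ok] <- qr.resid(qr(mm_full[ok, , drop = FALSE]), y[ok])
    out_ph[[tr]] <- r
  }
  if ("age" %in% traits) out_ph$age <- factor(ph$age, levels = c(3, 4, 5))
  structure(list(individuals = ids, pheno = out_ph, geno = geno,
                 geno_age = geno_age, design = design, loci = colnames(X)),
            class = "hatch_corrected")
}

# Residual genotype matrix and response for one trait, complete cases only.
trait_xy <- function(corrected, trait, loci = NULL) {
  classification <- trait == "age"
  x <- if (classification) corrected$geno_age else corrected$geno
  if (!is.null(loci)) x <- x[, loci, drop = FALSE]
  y <- corrected$pheno[[trait]]
  ok <- !is.na(y)
  if (classification) y <- droplevels(y)
  list(x = x[ok, , drop = FALSE], y = y[ok], classification = classification)
}

# One ranger forest: permutation importance, OOB metric, balanced classes for
# classification (every class downsampled to the smallest class count).
rf_forest <- function(x, y, classification, ntree, seed) {
  if (classification) {
    cnt <- table(y)
    if (any(cnt < 2)) {
      stop_input("class with fewer than 2 members: ",
                 paste(names(cnt)[cnt < 2], collapse = ", "))
    }
    frac <- rep(min(cnt) / length(y), length(cnt))
    fit <- ranger::ranger(x = x, y = y, num.trees = ntree,
                          importance = "permutation",
                          sample.fraction = frac, replace = TRUE,
                          seed = seed, num.threads = 1)
    metric <- 100 * fit$prediction.error  # OOB misclassification %
  } else {
    fit <- ranger::ranger(x = x, y = y, num.trees = ntree,
                          importance = "permutation",
                          seed = seed, num.threads = 1)
    metric <- 100 * fit$r.squared        # OOB % variation explained
  }
  list(importance = fit$variable.importance, metric = metric)
}

# Grow n_forests seed-replicated forests; average importance and metric.
grow_replicates <- function(x, y, classification, ntree, n_forests, seed) {
  fits <- lapply(seq_len(n_forests), function(f) {
    rf_forest(x, y, classification, ntree, derive_seed(seed, f))
  })
  imp <- vapply(fits, `[[`, numeric(ncol(x)), "importance")
  if (is.null(dim(imp))) imp <- matrix(imp, nrow = ncol(x))
  cors <- if (n_forests > 1) cor(imp)[upper.tri(diag(n_forests))] else 1
  list(importance = rowMeans(imp), pairwise_cor = cors,
       metric = mean(vapply(fits, `[[`, numeric(1), "metric")))
}

#' Choose the number of trees by importance stability
#'
#' Grows `n_forests` replicate forests (differing only in seed) at each
#' candidate ntree, in ascending order, and returns the smallest candidate at
#' which every pairwise Pearson correlation of locus importances exceeds the
#' threshold. If no candidate qualifies the largest is returned with a
#' warning.
#'
#' @param corrected A [correct_confounders()] result.
#' @param trait Trait name.
#' @param candidate_ntrees Ascending integer vector of tree counts.
#' @param threshold Required pairwise importance correlation (default 0.8).
#' @param n_forests Replicate forests per candidate (default 3).
#' @param seed Integer seed.
#' @return The chosen ntree (integer) with the per-candidate correlation
#'   summary in `attr(, "stability")`.
#' @export
tune_ntree <- function(corrected, trait, candidate_ntrees = c(1000, 2500, 5000),
                       threshold = 0.8, n_forests = 3, seed = 1L) {
  stopifnot(!is.unsorted(candidate_ntrees))
  xy <- trait_xy(corrected, trait)
  rows <- list()
  chosen <- NULL
  for (i in seq_along(candidate_ntrees)) {
    nt <- candidate_ntrees[i]
    rep <- grow_replicates(xy$x, xy$y, xy$classification, nt, n_forests,
                           derive_seed(seed, 17L * i))
    rows[[i]] <- tibble::tibble(ntree = nt,
                                min_cor = min(rep$pairwise_cor),
                                mean_cor = mean(rep$pairwise_cor))
    if (is.null(chosen) && all(rep$pairwise_cor > threshold)) {
      chosen <- nt
      break
    }
  }
  if (is.null(chosen)) {
    warning("no candidate ntree reached importance correlation > ", threshold,
            "; using the largest")
    chosen <- max(candidate_ntrees)
  }
  structure(as.integer(chosen), stability = dplyr::bind_rows(rows))
}

#' Average locus importances over replicate forests
#'
#' Grows `n_forests` forests on all loci (regression for continuous traits;
#' balanced classification for age) and averages the permutation importances.
#'
#' @inheritParams tune_ntree
#' @param ntree Trees per forest (e.g. from [tune_ntree()]).
#' @return A `hatch_importance` tibble `locus`, `importance`, sorted
#'   decreasing, with pairwise importance correlations in
#'   `attr(, "pairwise_cor")` and the mean OOB metric in `attr(, "metric")`.
#' @export
grow_importances <- function(corrected, trait, ntree, n_forests = 3,
                             seed = 1L) {
  xy <- trait_xy(corrected, trait)
  rep <- grow_replicates(xy$x, xy$y, xy$classification, ntree, n_forests, seed)
  out <- tibble::tibble(locus = colnames(xy$x), importance = rep$importance)
  out <- dplyr::arrange(out, dplyr::desc(.data$importance))
  attr(out, "pairwise_cor") <- rep$pairwise_cor
  attr(out, "metric") <- rep$metric
  class(out) <- c("hatch_importance", class(out))
  out
}

#' Screen top-importance fractions of loci
#'
#' For each fraction, grows replicate forests on the top loci by averaged
#' importance and records the OOB metric (% variation explained for
#' regression, OOB classification error for age); returns the fraction with
#' the best metric.
#'
#' @inheritParams grow_importances
#' @param importances A [grow_importances()] table.
#' @param fractions Fractions of loci to screen.
#' @return List: `best_fraction`, `metrics` (tibble `fraction`, `n_loci`,
#'   `metric`), `metric_kind`.
#' @export
evaluate_top_fractions <- function(corrected, trait, importances, ntree,
                                   fractions = c(0.005, 0.01, 0.02, 0.03, 0.05),
                                   n_forests = 3, seed = 1L) {
  xy <- trait_xy(corrected, trait)
  L <- nrow(importances)
  rows <- list()
  for (i in seq_along(fractions)) {
    k <- ceiling(fractions[i] * L)
    if (k < 2) {
      message("fraction ", fractions[i], " yields fewer than 2 loci; skipped")
      next
    }
    loci <- importances$locus[seq_len(k)]
    rep <- grow_replicates(xy$x[, loci, drop = FALSE], xy$y,
                           xy$classification, ntree, n_forests,
                           derive_seed(seed, 29L * i))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      fraction = fractions[i], n_loci = k, metric = rep$metric)
  }
  metrics <- dplyr::bind_rows(rows)
  if (!nrow(metrics)) stop_input("no fraction yielded enough loci")
  best <- if (xy$classification) which.min(metrics$metric) else
    which.max(metrics$metric)
  list(best_fraction = metrics$fraction[best], metrics = metrics,
       metric_kind = if (xy$classification) "oob_classification_error"
                     else "percent_variation_explained")
}

#' Backward purging of a candidate locus set
#'
#' Starting from the candidate set, repeatedly grows replicate forests,
#' records the OOB metric, and removes the least-important locus, down to two
#' loci; importance ranks are re-computed at every step. The returned
#' predictor set is the one with the best metric anywhere along the
#' trajectory.
#'
#' @inheritParams grow_importances
#' @param candidate_loci Character vector of locus ids (typically the best
#'   screened fraction expanded by 1.5).
#' @param step_size Loci removed per iteration (default 1; larger values
#'   trade purging resolution for speed).
#' @return A `hatch_predictors` object: `trait`, `loci`, `metric_kind`,
#'   `metric`, `trajectory` (tibble `size`, `metric`), `removal_order`.
#' @export
backward_purge <- function(corrected, trait, candidate_loci, ntree,
                           n_forests = 3, seed = 1L, step_size = 1L) {
  xy <- trait_xy(corrected, trait, loci = candidate_loci)
  classification <- xy$classification
  if (length(candidate_loci) < 3) {
    warning("fewer than 3 candidate loci; returning the set unpurged")
    rep <- grow_replicates(xy$x, xy$y, classification, ntree, n_forests, seed)
    return(new_predictors(trait, candidate_loci, classification, rep$metric,
                          tibble::tibble(size = length(candidate_loci),
                                         metric = rep$metric),
                          character()))
  }
  current <- candidate_loci
  sizes <- integer(); metrics <- numeric(); removal <- character()
  step <- 0L
  while (length(current) >= 2) {
    step <- step + 1L
    rep <- grow_replicates(xy$x[, current, drop = FALSE], xy$y,
                           classification, ntree, n_forests,
                           derive_seed(seed, step))
    sizes <- c(sizes, length(current))
    metrics <- c(metrics, rep$metric)
    if (length(current) == 2) break
    n_drop <- min(step_size, length(current) - 2L)
    worst <- current[order(rep$importance)[seq_len(n_drop)]]
    removal <- c(removal, worst)
    current <- setdiff(current, worst)
  }
  best <- if (classification) which.min(metrics) else which.max(metrics)
  # reconstruct the set that was standing when the best metric was recorded
  n_removed_before_best <- length(candidate_loci) - sizes[best]
  best_set <- setdiff(candidate_loci, head(removal, n_removed_before_best))
  new_predictors(trait, best_set, classification, metrics[best],
                 tibble::tibble(size = sizes, metric = metrics), removal)
}

new_predictors <- function(trait, loci, classification, metric, trajectory,
                           removal_order) {
  structure(list(trait = trait, loci = loci,
                 metric_kind = if (classification)
                   "oob_classification_error" else
                   "percent_variation_explained",
                 metric = metric, trajectory = trajectory,
                 removal_order = removal_order),
            class = "hatch_predictors")
}

#' @export
print.hatch_predictors <- function(x, ...) {
  cat(sprintf("Predictor set for %s: %d loci, %s = %.2f\n", x$trait,
              length(x$loci), x$metric_kind, x$metric))
  invisible(x)
}

#' Run the random-forest association chain for several traits
#'
#' Per trait: confounder correction (shared), ntree stability tuning,
#' importance averaging over replicate forests, top-fraction screening,
#' expansion by `expansion`, and backward purging.
#'
#' @inheritParams correct_confounders
#' @param traits Traits to analyse (skipped with a warning when absent from
#'   the phenotype table).
#' @param map Optional linkage map used to count mapped predictors.
#' @param candidate_ntrees,stability_threshold,n_forests,fractions,expansion
#'   Tuning constants (see the step functions).
#' @param seed Integer seed.
#' @return List of class `hatch_assoc`: `predictors` (named list of
#'   `hatch_predictors`), `summary` (tibble `trait`, `n_individuals`,
#'   `n_predictors`, `n_mapped`, `metric_kind`, `metric`), `corrected`.
#' @export
run_association <- function(pheno, gm, traits = hatch_traits(), map = NULL,
                            candidate_ntrees = c(1000, 2500, 5000),
                            stability_threshold = 0.8, n_forests = 3,
                            fractions = c(0.005, 0.01, 0.02, 0.03, 0.05),
                            expansion = 1.5, seed = 1L,
                            exclude_founders = TRUE) {
  missing_tr <- setdiff(traits, names(pheno))
  if (length(missing_tr)) {
    warning("traits absent from the phenotype table, skipped: ",
            paste(missing_tr, collapse = ", "))
    traits <- setdiff(traits, missing_tr)
  }
  corrected <- correct_confounders(pheno, gm, traits, exclude_founders)
  L <- length(corrected$loci)
  preds <- list()
  rows <- list()
  for (i in seq_along(traits)) {
    tr <- traits[i]
    sd_tr <- derive_seed(seed, 1000L * i)
    nt <- tune_ntree(corrected, tr, candidate_ntrees, stability_threshold,
                     n_forests, seed = sd_tr)
    imp <- grow_importances(corrected, tr, nt, n_forests,
                            seed = derive_seed(sd_tr, 1L))
    screen <- evaluate_top_fractions(corrected, tr, imp, nt, fractions,
                                     n_forests, seed = derive_seed(sd_tr, 2L))
    k <- min(L, ceiling(screen$best_fraction * expansion * L))
    candidates <- imp$locus[seq_len(k)]
    ps <- backward_purge(corrected, tr, candidates, nt, n_forests,
                         seed = derive_seed(sd_tr, 3L))
    ps$ntree <- nt
    ps$best_fraction <- screen$best_fraction
    ps$fraction_metrics <- screen$metrics
    preds[[tr]] <- ps
    n_ind <- sum(!is.na(corrected$pheno[[tr]]))
    positioned <- if (is.null(map)) character() else {
      on_map <- if ("mapped" %in% names(map)) map$mapped else TRUE
      if ("inferred" %in% names(map)) on_map <- on_map | map$inferred
      map$locus[on_map]
    }
    rows[[i]] <- tibble::tibble(
      trait = tr, n_individuals = n_ind, n_predictors = length(ps$loci),
      n_mapped = if (is.null(map)) NA_integer_ else
        sum(ps$loci %in% positioned),
      metric_kind = ps$metric_kind, metric = ps$metric)
  }
  structure(list(predictors = preds, summary = dplyr::bind_rows(rows),
                 corrected = corrected),
            class = "hatch_assoc")
}
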