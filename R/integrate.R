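# Phenotype contrasts between lines, PCA trajectories of trait-associated
# loci, and the trait-by-outlier overlap report.

#' Daily growth coefficient
#'
#' `DGC = 100 * (final^(1/3) - initial^(1/3)) / days`, the standard
#' cube-root growth measure; negative when weight is lost over the holding
#' period.
#'
#' @param initial_weight,final_weight Weights in kg (must be positive).
#' @param days Days between the two weighings (>= 1).
#' @return Numeric DGC (unitless), vectorised.
#' @export
#' @examples
#' compute_dgc(8, 7, 20)
compute_dgc <- function(initial_weight, final_weight, days) {
  if (any(initial_weight <= 0 | final_weight <= 0)) {
    stop_input("weights must be positive")
  }
  if (any(days < 1)) stop_input("days must be >= 1")
  100 * (final_weight^(1 / 3) - initial_weight^(1 / 3)) / days
}

#' Line-contrast models for the six traits
#'
#' Fits `y ~ line + sex + line:sex` with a Gaussian identity link for return
#' timing, spawn timing, fork length and DGC; a Poisson log link for age at
#' maturity; and the allometric form
#' `log(weight) ~ line + sex + line:sex + log(fork length)` for weight.
#' All traits except age are restricted to age-4 fish. The reference level
#' is integrated-line females.
#'
#' @param pheno Phenotype tibble with `line`, `sex`, `age` and the trait
#'   columns; founders (line `P1`) are dropped.
#' @param trait One of [hatch_traits()].
#' @return A `hatch_line_fit`: the underlying `lm`/`glm` plus `trait` and
#'   `family` fields; use [generics::tidy()] / [generics::glance()].
#' @export
fit_line_models <- function(pheno, trait = hatch_traits()) {
  trait <- match.arg(trait)
  d <- dplyr::filter(pheno, .data$line %in% c("INT", "SEG"))
  d$line <- factor(d$line, levels = c("INT", "SEG"))
  d$sex <- factor(d$sex, levels = c("F", "M"))
  if (trait != "age") d <- dplyr::filter(d, .data$age == 4)
  fit <- switch(
    trait,
    age = glm(age ~ line + sex + line:sex, data = d, family = poisson("log")),
    weight_kg = lm(log(weight_kg) ~ line + sex + line:sex + log(length_cm),
                   data = d),
    lm(stats::reformulate(c("line", "sex", "line:sex"), trait), data = d)
  )
  if (any(is.na(coef(fit)))) {
    warning("aliased terms in the ", trait, " model (empty line x sex cell?)")
  }
  fit$trait <- trait
  fit$family_label <- if (trait == "age") "poisson_log" else "gaussian_identity"
  class(fit) <- c("hatch_line_fit", class(fit))
  fit
}

#' PCA trajectories of trait-associated loci across lines and generations
#'
#' Runs a PCA on the dosage matrix restricted to a trait's predictor loci,
#' projecting every line x generation group together, and summarises each
#' group by its centroid on the leading components plus the per-generation
#' centroid distance between the two lines (with a bootstrap standard error).
#'
#' @param gm Imputed wide genotype tibble with `population` labels.
#' @param predictor_loci Character vector of locus ids (e.g.
#'   `predictors$loci` from [run_association()]).
#' @param n_boot Bootstrap replicates for the centroid-distance SE.
#' @param seed Integer seed for the bootstrap.
#' @return List of class `hatch_pca`: `scores` (individual PC1/PC2 with
#'   labels), `centroids` (per population), `distances` (per generation:
#'   SEG-INT centroid distance on the retained PCs and its bootstrap SE).
#' @export
pca_trajectories <- function(gm, predictor_loci, n_boot = 200L, seed = 1L) {
  loci <- intersect(predictor_loci, geno_loci(gm))
  if (!length(loci)) stop_input("no predictor loci present in the genotypes")
  if (length(loci) == 1) {
    message("single-locus predictor set: one-dimensional projection")
  }
  X <- geno_matrix(gm)[, loci, drop = FALSE]
  pc <- prcomp(X, center = TRUE, scale. = FALSE,
               rank. = min(2L, ncol(X)))
  sc <- tibble::as_tibble(pc$x)
  names(sc) <- paste0("PC", seq_len(ncol(sc)))
  if (!"PC2" %in% names(sc)) sc$PC2 <- 0
  scores <- dplyr::bind_cols(
    gm[intersect(GENO_ID_COLS, names(gm))], sc)
  centroids <- dplyr::summarise(
    dplyr::group_by(scores, .data$line, .data$generation, .data$population),
    PC1 = mean(.data$PC1), PC2 = mean(.data$PC2), n = dplyr::n(),
    .groups = "drop")
  gens <- sort(intersect(unique(scores$generation[scores$line == "INT"]),
                         unique(scores$generation[scores$line == "SEG"])))
  dist_one <- function(sc_int, sc_seg) {
    sqrt(sum((colMeans(sc_int) - colMeans(sc_seg))^2))
  }
  with_seed(seed, {
    distances <- purrr::map_dfr(gens, function(g) {
      a <- as.matrix(scores[scores$line == "INT" & scores$generation == g,
                            c("PC1", "PC2")])
      b <- as.matrix(scores[scores$line == "SEG" & scores$generation == g,
                            c("PC1", "PC2")])
      boot <- vapply(seq_len(n_boot), function(i) {
        dist_one(a[sample.int(nrow(a), replace = TRUE), , drop = FALSE],
                 b[sample.int(nrow(b), replace = TRUE), , drop = FALSE])
      }, numeric(1))
      tibble::tibble(generation = g, distance = dist_one(a, b),
                     boot_se = sd(boot))
    })
    structure(list(scores = scores, centroids = centroids,
                   distances = distances,
                   sdev = pc$sdev, loci = loci),
              class = "hatch_pca")
  })
}

#' Overlap of trait-associated loci with outlier calls
#'
#' Reports (a) exact locus-identity overlaps between a trait's predictor
#' loci and outlier locus calls, (b) predictor loci within `proximity_cM` of
#' an outlier locus on the same chromosome, and (c) predictor loci falling
#' inside outlier regions. Unmapped predictor loci are eligible for identity
#' overlap only.
#'
#' @param predictor_sets Named list of `hatch_predictors` (or of character
#'   locus vectors), one per trait.
#' @param outlier_calls Call tibble as produced by [scan_lines()] (`$calls`),
#'   optionally extended with [merge_external_outliers()].
#' @param map Linkage map with `locus`, `chromosome`, `cM` (positions for
#'   proximity and containment logic).
#' @param proximity_cM Proximity radius in cM (default 1).
#' @return A `hatch_overlap` tibble: `trait`, `locus`, `overlap_type`
#'   (`identity`/`proximity`/`region`), `method`, `line`, `generation`,
#'   `outlier_locus`, `chromosome`, `distance_cM`; deterministic row order.
#' @export
overlap_report <- function(predictor_sets, outlier_calls, map,
                           proximity_cM = 1.0) {
  rows <- list()
  locus_calls <- dplyr::filter(outlier_calls, .data$kind == "locus")
  region_calls <- dplyr::filter(outlier_calls, .data$kind == "region")
  pos <- map[c("locus", "chromosome", "cM")]
  for (tr in names(predictor_sets)) {
    ps <- predictor_sets[[tr]]
    loci <- if (inherits(ps, "hatch_predictors")) ps$loci else ps
    tl <- dplyr::left_join(tibble::tibble(locus = loci), pos, by = "locus")
    # (a) identity
    ident <- dplyr::inner_join(tl, locus_calls,
                               by = "locus", suffix = c("", "_call"))
    if (nrow(ident)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        trait = tr, locus = ident$locus, overlap_type = "identity",
        method = ident$method, line = ident$line,
        generation = ident$generation, outlier_locus = ident$locus,
        chromosome = ident$chromosome, distance_cM = 0)
    }
    # (b) proximity to outlier loci on the same chromosome
    tl_m <- dplyr::filter(tl, !is.na(.data$cM))
    lc_m <- dplyr::filter(locus_calls, !is.na(.data$cM_start))
    if (nrow(tl_m) && nrow(lc_m)) {
      prox <- dplyr::inner_join(tl_m, lc_m, by = "chromosome",
                                suffix = c("", "_call"),
                                relationship = "many-to-many")
      prox <- dplyr::mutate(prox, distance_cM = abs(.data$cM - .data$cM_start))
      prox <- dplyr::filter(prox, .data$distance_cM <= proximity_cM,
                            .data$locus != .data$locus_call)
      if (nrow(prox)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          trait = tr, locus = prox$locus, overlap_type = "proximity",
          method = prox$method, line = prox$line,
          generation = prox$generation, outlier_locus = prox$locus_call,
          chromosome = prox$chromosome, distance_cM = prox$distance_cM)
      }
    }
    # (c) containment in outlier regions
    if (nrow(tl_m) && nrow(region_calls)) {
      inreg <- dplyr::inner_join(tl_m, region_calls, by = "chromosome",
                                 suffix = c("", "_call"),
                                 relationship = "many-to-many")
      inreg <- dplyr::filter(inreg, .data$cM >= .data$cM_start,
                             .data$cM <= .data$cM_end)
      if (nrow(inreg)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          trait = tr, locus = inreg$locus, overlap_type = "region",
          method = inreg$method, line = inreg$line,
          generation = inreg$generation, outlier_locus = NA_character_,
          chromosome = inreg$chromosome, distance_cM = 0)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble::tibble(trait = character(), locus = character(),
                          overlap_type = character(), method = character(),
                          line = character(), generation = integer(),
                          outlier_locus = character(),
                          chromosome = integer(), distance_cM = numeric())
  }
  out <- dplyr::arrange(out, .data$trait, .data$overlap_type, .data$locus,
                        .data$line, .data$generation)
  class(out) <- c("hatch_overlap", class(out))
  out
}
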