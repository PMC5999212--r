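# Wright-Fisher simulator of the paired integrated/segregated hatchery design:
# founders, line propagation, phenotypes, read depths and proxy-genome
# alignments, all seeded from one sim_config.

locus_ids <- function(n) sprintf("L%05d", seq_len(n))

# Sample `n` diploid individuals at Hardy-Weinberg proportions given per-locus
# allele frequencies `p` (dosage counts copies of the alternate allele).
sample_population <- function(p, n, line, generation) {
  L <- length(p)
  m <- matrix(rbinom(n * L, 2L, rep(p, each = n)), nrow = n)
  colnames(m) <- names(p)
  pop <- paste0(line, "_F", generation)
  out <- tibble::tibble(
    individual = sprintf("%s_%03d", pop, seq_len(n)),
    line = line,
    generation = as.integer(generation),
    population = pop,
    sex = sample(c("F", "M"), n, replace = TRUE)
  )
  dplyr::bind_cols(out, tibble::as_tibble(m))
}

#' Simulate the wild founder population and its linkage map
#'
#' Founder allele frequencies are drawn from the configured Beta distribution
#' (or taken from `founder_freq`); genotypes follow Hardy-Weinberg proportions
#' given those frequencies; loci are assigned uniformly at random to
#' chromosomes with uniform centimorgan positions, and a configurable fraction
#' is flagged as carried on the linkage map.
#'
#' @param config A [sim_config()].
#' @return A list of class `hatch_founders` with elements `genotypes` (wide
#'   genotype tibble for the P1 founders), `freq` (named founder allele
#'   frequencies) and `map` (tibble `locus`, `chromosome`, `cM`, `mapped`).
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    L <- config$n_loci
    p <- if (!is.null(config$founder_freq)) {
      rep_len(as.numeric(config$founder_freq), L)
    } else {
      rbeta(L, config$founder_maf_dist[1], config$founder_maf_dist[2])
    }
    names(p) <- locus_ids(L)
    map <- tibble::tibble(
      locus = names(p),
      chromosome = sample.int(config$n_chromosomes, L, replace = TRUE),
      cM = round(runif(L, 0, 100), 3),
      mapped = runif(L) < config$mapped_fraction
    )
    genotypes <- sample_population(p, config$samples_per_population, "P1", 0L)
    structure(list(genotypes = genotypes, freq = p, map = map),
              class = "hatch_founders")
  })
}

#' @importFrom stats rbeta
NULL

# Deterministic viability selection update for allele frequency p with
# genotype fitnesses (1, 1 + s/2, 1 + s) for 0/1/2 copies of the selected
# allele (selection acts before the drift draw).
select_freq <- function(p, s) {
  w2 <- 1 + s
  w1 <- 1 + s / 2
  q <- 1 - p
  wbar <- p^2 * w2 + 2 * p * q * w1 + q^2
  (p^2 * w2 + p * q * w1) / wbar
}

#' Propagate the integrated and segregated lines from shared founders
#'
#' The segregated line is a closed Wright-Fisher population: each generation
#' the allele frequency is resampled binomially with `2 * ne_segregated`
#' gametes, after deterministic viability selection at any configured
#' selected loci. The integrated line mixes a fraction
#' `gene_flow_integrated` of parents from a persistent wild pool (itself
#' drifting at `ne_wild`) before its own binomial resampling at
#' `2 * ne_integrated`. Individuals are sampled from each line x generation at
#' Hardy-Weinberg proportions.
#'
#' @param founders Output of [simulate_founders()].
#' @param config The same [sim_config()].
#' @return A list of class `hatch_lines` with `genotypes` (wide tibble over
#'   all populations, founders included), `freq` (tibble `line`, `generation`,
#'   `locus`, `p` with the full trajectories, wild pool included) and `map`.
#' @export
propagate_lines <- function(founders, config) {
  stopifnot(inherits(founders, "hatch_founders"))
  with_seed(derive_seed(config$seed, 2L), {
    p0 <- founders$freq
    L <- length(p0)
    sel <- rep(0, L)
    if (nrow(config$selected_loci)) {
      idx <- config$selected_loci$locus
      if (is.character(idx)) idx <- match(idx, names(p0))
      sel[idx] <- config$selected_loci$s
    }
    p_int <- p_seg <- p_wild <- p0
    traj <- list(tibble::tibble(line = "P1", generation = 0L,
                                locus = names(p0), p = unname(p0)))
    pops <- list(founders$genotypes)
    for (g in seq_len(config$n_generations)) {
      p_wild <- rbinom(L, round(2 * config$ne_wild), p_wild) /
        round(2 * config$ne_wild)
      p_seg_sel <- ifelse(sel != 0, select_freq(p_seg, sel), p_seg)
      p_seg <- rbinom(L, round(2 * config$ne_segregated), p_seg_sel) /
        round(2 * config$ne_segregated)
      p_mix <- (1 - config$gene_flow_integrated) * p_int +
        config$gene_flow_integrated * p_wild
      p_int <- rbinom(L, round(2 * config$ne_integrated), p_mix) /
        round(2 * config$ne_integrated)
      traj <- c(traj, list(
        tibble::tibble(line = "WILD", generation = g, locus = names(p0),
                       p = p_wild),
        tibble::tibble(line = "INT", generation = g, locus = names(p0),
                       p = p_int),
        tibble::tibble(line = "SEG", generation = g, locus = names(p0),
                       p = p_seg)))
      pops <- c(pops,
                list(sample_population(setNames(p_int, names(p0)),
                                       config$samples_per_population,
                                       "INT", g),
                     sample_population(setNames(p_seg, names(p0)),
                                       config$samples_per_population,
                                       "SEG", g)))
    }
    structure(list(genotypes = dplyr::bind_rows(pops),
                   freq = dplyr::bind_rows(traj),
                   map = founders$map),
              class = "hatch_lines")
  })
}

# Build one continuous trait with realized heritability pinned to the target:
# the causal genetic score is standardised in-sample, so genetic and
# environmental variance fractions are h2 and 1 - h2 by construction.
standardised_trait <- function(g, h2, n) {
  force(g)  # evaluate the genetic score (and record its truth) even at h2 = 0
  z <- rnorm(n)
  if (h2 > 0 && sd(g) > 0) {
    gs <- as.numeric(scale(g))
    # orthogonalise the noise against the genetic score so the realised
    # variance split is exactly h2 : (1 - h2)
    z <- z - gs * sum(gs * z) / sum(gs^2)
    sqrt(h2) * gs + sqrt(1 - h2) * as.numeric(scale(z))
  } else {
    z
  }
}

#' Simulate the six fitness traits with line/sex/year confounding
#'
#' Each continuous trait is the sum of a standardised additive genetic score
#' over its causal loci (scaled so the realised heritability matches the
#' architecture's `h2`), Gaussian environmental noise, and fixed effects of
#' hatchery line, sex and year. Age at maturity is an ordinal trait obtained
#' by thresholding a latent liability so that about 75% of individuals
#' mature at age four (15% at three, 10% at five). Weight is allometric:
#' `weight_kg = 1.1e-5 * length_cm^3 * exp(residual)` with the architecture
#' acting on the log-scale residual. DGC is realised through initial/final
#' weights and holding days so that the growth-coefficient formula recovers
#' it exactly.
#'
#' @param lines Output of [propagate_lines()] (or a wide genotype tibble).
#' @param config The [sim_config()].
#' @return A `hatch_pheno` tibble (individual, line, generation, population,
#'   sex, year, the six traits, and the DGC ingredients
#'   `initial_weight_kg`, `final_weight_kg`, `holding_days`), with the causal
#'   architecture in `attr(, "truth")` (named list of tibbles `locus`,
#'   `effect` per trait).
#' @export
simulate_phenotypes <- function(lines, config) {
  gm <- if (inherits(lines, "hatch_lines")) lines$genotypes else lines
  with_seed(derive_seed(config$seed, 3L), {
    X <- geno_matrix(gm)
    n <- nrow(X)
    poly <- colnames(X)[apply(X, 2, function(v) var(v) > 0)]
    is_seg <- as.numeric(gm$line == "SEG")
    is_male <- as.numeric(gm$sex == "M")
    gen <- gm$generation
    truth <- list()
    ph <- tibble::tibble(
      individual = gm$individual, line = gm$line,
      generation = gm$generation, population = gm$population,
      sex = gm$sex, year = 2000L + gm$generation
    )
    gscore <- function(tr) {
      a <- config$trait_architectures[[tr]]
      causal <- if (!is.null(a$causal)) {
        # explicit causal loci (ids or indices), e.g. to align a trait's
        # architecture with configured selection targets
        if (is.numeric(a$causal)) colnames(X)[a$causal] else a$causal
      } else {
        sample(poly, min(a$n_causal, length(poly)))
      }
      dist <- a$effect_dist %||% "normal"
      eff <- if (is.function(dist)) {
        dist(length(causal))
      } else {
        switch(dist,
               normal = rnorm(length(causal)),
               equal = sample(c(-1, 1), length(causal), replace = TRUE),
               stop_input("unknown effect_dist: ", dist))
      }
      truth[[tr]] <<- tibble::tibble(locus = causal, effect = eff)
      X[, causal, drop = FALSE] %*% eff
    }
    fixed <- function(a) {
      a$line_effect * is_seg + a$sex_effect * is_male + a$year_effect * gen
    }

    # age: ordinal via latent liability; thresholds at the 15th/90th normal
    # quantiles give ~75% age-4
    a <- config$trait_architectures$age
    latent <- standardised_trait(gscore("age"), a$h2, n) + fixed(a)
    ph$age <- 4L
    ph$age[latent < qnorm(0.15)] <- 3L
    ph$age[latent > qnorm(0.90)] <- 5L

    for (tr in c("return_day", "spawn_day", "length_cm")) {
      a <- config$trait_architectures[[tr]]
      ph[[tr]] <- a$base + a$total_sd * standardised_trait(gscore(tr), a$h2, n) +
        fixed(a)
    }

    # allometric weight: architecture acts on the log-scale residual
    a <- config$trait_architectures$weight_kg
    resid_w <- a$base + a$total_sd * standardised_trait(gscore("weight_kg"), a$h2, n) +
      fixed(a)
    ph$weight_kg <- 1.1e-5 * ph$length_cm^3 * exp(resid_w)

    # DGC realised through its ingredients so compute_dgc() inverts exactly
    a <- config$trait_architectures$dgc
    ph$dgc <- a$base + a$total_sd * standardised_trait(gscore("dgc"), a$h2, n) +
      fixed(a)
    ph$holding_days <- sample(40:100, n, replace = TRUE)
    ph$initial_weight_kg <- ph$weight_kg
    ph$final_weight_kg <-
      (ph$initial_weight_kg^(1 / 3) + ph$dgc * ph$holding_days / 100)^3

    attr(ph, "truth") <- truth
    class(ph) <- c("hatch_pheno", class(ph))
    ph
  })
}

#' Simulate per-allele RAD read depths for every genotype
#'
#' Total depth per (individual, locus) is negative binomial with the
#' configured mean and dispersion; heterozygotes split reads
#' `Binomial(total, 1/2)` between alleles, homozygotes receive off-allele
#' reads at the allelic error rate.
#'
#' @param lines Output of [propagate_lines()] (or a wide genotype tibble).
#' @param config The [sim_config()].
#' @return Long tibble `individual`, `locus`, `depth_a1`, `depth_a2` with the
#'   true dosage in `truth_dosage`.
#' @export
simulate_depths <- function(lines, config) {
  gm <- if (inherits(lines, "hatch_lines")) lines$genotypes else lines
  with_seed(derive_seed(config$seed, 4L), {
    X <- geno_matrix(gm)
    dm <- config$depth_model
    long <- tibble::tibble(
      individual = rep(gm$individual, times = ncol(X)),
      locus = rep(colnames(X), each = nrow(X)),
      truth_dosage = as.integer(X)
    )
    total <- rnbinom(nrow(long), size = dm$dispersion, mu = dm$mean)
    # allele-2 read probability by dosage: error, 1/2, 1 - error
    p2 <- c(dm$error, 0.5, 1 - dm$error)[long$truth_dosage + 1L]
    d2 <- rbinom(nrow(long), total, p2)
    long$depth_a1 <- total - d2
    long$depth_a2 <- d2
    long
  })
}

#' Simulate proxy-genome alignments with known anchoring truth
#'
#' Mapped loci are placed on per-chromosome contigs of each proxy genome in
#' linkage-map order (1 cM to `bp_per_cM` bp); each unmapped locus is placed
#' at a controlled gap distance from a donor mapped locus with a controlled
#' mapping quality, so that the correct anchoring outcome is known. Donors
#' are chosen with enough clearance that the intended donor is the nearest
#' mapped locus.
#'
#' @param map Linkage-map tibble with `locus`, `chromosome`, `cM`, `mapped`.
#' @param genomes Character vector of proxy genome labels.
#' @param bp_per_cM Physical scale of the proxy genome.
#' @param tag_bp RAD-tag length in bp (alignment interval width).
#' @param distance_range Range (bp) from which unmapped-locus gap distances
#'   are drawn.
#' @param mapq Mapping quality given to alignments by default.
#' @param overrides Optional tibble (`locus`, optionally `genome`, `distance`,
#'   `mapq`) forcing the placement of particular unmapped loci, e.g. to plant
#'   violations of the distance or quality rules.
#' @param seed Integer seed.
#' @return Alignment tibble `locus`, `genome`, `contig`, `start`, `end`
#'   (0-based half-open), `mapq`, with ground truth in `attr(, "truth")`
#'   (`locus`, `genome`, `donor`, `distance`, `mapq`, `donor_cM`,
#'   `recoverable` under the default 100 kb / mapq 10 rule).
#' @export
simulate_alignments <- function(map, genomes = c("A", "B"),
                                bp_per_cM = 1e6, tag_bp = 74L,
                                distance_range = c(1e3, 8e4),
                                mapq = 42L, overrides = NULL,
                                seed = 1L) {
  with_seed(seed, {
    out <- list()
    truth <- list()
    for (gnm in genomes) {
      mapped <- dplyr::arrange(dplyr::filter(map, .data$mapped),
                               .data$chromosome, .data$cM)
      mapped$contig <- paste0("chr", mapped$chromosome, "_", gnm)
      mapped$start <- round(mapped$cM * bp_per_cM)
      mapped$end <- mapped$start + tag_bp
      # clearance to the next mapped locus on the same contig
      mapped <- dplyr::group_by(mapped, .data$contig)
      mapped <- dplyr::mutate(mapped,
        gap_right = dplyr::lead(.data$start, default = Inf) - .data$end)
      mapped <- dplyr::ungroup(mapped)
      out[[paste0("m", gnm)]] <- tibble::tibble(
        locus = mapped$locus, genome = gnm, contig = mapped$contig,
        start = mapped$start, end = mapped$end, mapq = as.integer(mapq))

      unm <- dplyr::filter(map, !.data$mapped)
      if (!nrow(unm)) next
      d <- round(runif(nrow(unm), distance_range[1], distance_range[2]))
      q <- rep(as.integer(mapq), nrow(unm))
      if (!is.null(overrides)) {
        ov <- overrides
        if ("genome" %in% names(ov)) ov <- ov[ov$genome == gnm, ]
        hit <- match(ov$locus, unm$locus)
        ok <- !is.na(hit)
        if ("distance" %in% names(ov)) d[hit[ok]] <- ov$distance[ok]
        if ("mapq" %in% names(ov)) q[hit[ok]] <- as.integer(ov$mapq[ok])
      }
      # donor: a mapped locus on the same chromosome whose right-hand
      # clearance exceeds twice the planted distance, so the donor stays
      # the nearest mapped neighbour of the placed interval
      donor_idx <- vapply(seq_len(nrow(unm)), function(i) {
        cand <- which(mapped$chromosome == unm$chromosome[i] &
                        mapped$gap_right > 2 * d[i] + tag_bp + 1)
        if (!length(cand)) {
          cand <- which(mapped$chromosome == unm$chromosome[i])
        }
        if (!length(cand)) return(NA_integer_)
        cand[sample.int(length(cand), 1L)]
      }, integer(1))
      keep <- !is.na(donor_idx)
      unm <- unm[keep, ]; d <- d[keep]; q <- q[keep]
      donor <- mapped[donor_idx[keep], ]
      out[[paste0("u", gnm)]] <- tibble::tibble(
        locus = unm$locus, genome = gnm, contig = donor$contig,
        start = donor$end + d, end = donor$end + d + tag_bp,
        mapq = q)
      truth[[gnm]] <- tibble::tibble(
        locus = unm$locus, genome = gnm, donor_cM = donor$cM,
        donor = donor$locus, distance = d, mapq = q,
        recoverable = d <= 1e5 & q >= 10L)
    }
    aln <- dplyr::bind_rows(out)
    attr(aln, "truth") <- dplyr::bind_rows(truth)
    aln
  })
}

#' Run the whole study-design simulator
#'
#' Chains [simulate_founders()], [propagate_lines()],
#' [simulate_phenotypes()], [simulate_depths()] and
#' [simulate_alignments()] under one config.
#'
#' @param config A [sim_config()].
#' @param depths,alignments Set `FALSE` to skip the corresponding (larger)
#'   outputs.
#' @return List of class `hatch_sim`: `genotypes`, `phenotypes`, `map`,
#'   `freq` (trajectories), and optionally `depths` and `alignments`;
#'   ground truth under `truth` (`causal`, `selected`, `alignment`).
#' @export
simulate_study <- function(config, depths = TRUE, alignments = TRUE) {
  founders <- simulate_founders(config)
  lines <- propagate_lines(founders, config)
  pheno <- simulate_phenotypes(lines, config)
  out <- list(genotypes = lines$genotypes, phenotypes = pheno,
              map = lines$map, freq = lines$freq,
              truth = list(causal = attr(pheno, "truth"),
                           selected = config$selected_loci))
  if (depths) out$depths <- simulate_depths(lines, config)
  if (alignments) {
    aln <- simulate_alignments(lines$map, seed = derive_seed(config$seed, 5L))
    out$alignments <- aln
    out$truth$alignment <- attr(aln, "truth")
  }
  structure(out, class = "hatch_sim")
}
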