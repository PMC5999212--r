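# Divergence scans: Weir-Cockerham (1984) two-population theta from genotype
# counts, the temporal drift-simulation outlier test, Gaussian-kernel
# smoothed FST tracks and resampled window nulls.

# Vectorised 1984 variance components for two samples of genotype counts.
# Inputs: 3 x L matrices (rows n0/n1/n2 = dosage 0/1/2 counts). Returns a
# tibble with a (among populations), b (among individuals within), c (within
# individuals) and theta = a / (a + b + c).
wc_components <- function(cn1, cn2) {
  n1 <- colSums(cn1); n2 <- colSums(cn2)
  p1 <- (cn1[2, ] + 2 * cn1[3, ]) / (2 * n1)
  p2 <- (cn2[2, ] + 2 * cn2[3, ]) / (2 * n2)
  h1 <- cn1[2, ] / n1
  h2 <- cn2[2, ] / n2
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  mono <- (pbar %in% c(0, 1)) & hbar == 0
  theta <- ifelse(mono | denom == 0 | n1 < 2 | n2 < 2, NA_real_, a / denom)
  tibble::tibble(theta = theta, a = a, b = b, c = cc)
}

#' Weir-Cockerham FST between two samples of genotype counts
#'
#' Implements the 1984 two-population theta estimator from genotype counts,
#' returning the among-population (`a`), among-individual (`b`) and
#' within-individual (`c`) variance components so that multi-locus estimates
#' can be aggregated as ratios of component sums. Theta may be negative at
#' weakly divergent loci; a locus monomorphic across both samples is
#' undefined (NA).
#'
#' @param counts1,counts2 For one locus, length-3 vectors `(n0, n1, n2)` of
#'   dosage counts; for many loci, 3 x L matrices or tibbles with rows/columns
#'   `n0`, `n1`, `n2`.
#' @return Tibble with one row per locus: `theta`, `a`, `b`, `c`.
#' @export
#' @examples
#' wc_fst(c(10, 5, 5), c(2, 6, 12))
wc_fst <- function(counts1, counts2) {
  as_cn <- function(x) {
    if (is.data.frame(x)) x <- t(as.matrix(x[c("n0", "n1", "n2")]))
    if (is.null(dim(x))) x <- matrix(x, nrow = 3)
    stopifnot(nrow(x) == 3, all(x >= 0))
    x
  }
  wc_components(as_cn(counts1), as_cn(counts2))
}

# Genotype-count matrix (3 x L) for one population label of a wide table.
population_counts <- function(gm, population) {
  X <- geno_matrix(gm[gm$population == population, , drop = FALSE])
  rbind(n0 = colSums(X == 0L, na.rm = TRUE),
        n1 = colSums(X == 1L, na.rm = TRUE),
        n2 = colSums(X == 2L, na.rm = TRUE))
}

#' Per-locus FST track between two populations
#'
#' @param gm Wide genotype tibble with `population`.
#' @param map Linkage map (`locus`, `chromosome`, `cM`); unmapped loci get NA
#'   positions and are excluded from smoothing but kept in the table.
#' @param pop1,pop2 Population labels to contrast.
#' @return A `hatch_fst_track` tibble: `locus`, `chromosome`, `cM`, `theta`,
#'   `a`, `b`, `c`.
#' @export
fst_track <- function(gm, map, pop1, pop2) {
  cn1 <- population_counts(gm, pop1)
  cn2 <- population_counts(gm, pop2)
  comp <- wc_components(cn1, cn2)
  out <- dplyr::left_join(
    tibble::tibble(locus = colnames(cn1)), map[c("locus", "chromosome", "cM")],
    by = "locus")
  out <- dplyr::bind_cols(out, comp)
  class(out) <- c("hatch_fst_track", class(out))
  attr(out, "populations") <- c(pop1, pop2)
  out
}

#' Temporal drift-simulation outlier test
#'
#' The observed statistic is the Weir-Cockerham theta between a sample of a
#' population at generation 0 and a sample of the same population t
#' generations later. The null distribution is built by Monte Carlo: from the
#' sample-estimated initial frequency, allele frequencies are propagated
#' through t generations of binomial Wright-Fisher drift at the stated
#' effective size, Hardy-Weinberg genotype samples of the stated sizes are
#' drawn at both ends, and the statistic is recomputed. The p-value is
#' `(1 + #\{null >= observed\}) / (1 + n_sims)`; loci whose initial sample is
#' fixed return p = 1 by convention.
#'
#' @param counts0,counts_t Genotype counts at the two time points: length-3
#'   vectors for one locus or 3 x L matrices (rows `n0`, `n1`, `n2`).
#' @param ne Effective population size driving drift.
#' @param generations Number of generations between the samples.
#' @param n_sims Number of null simulations (default 1000; fewer than 100
#'   triggers a warning).
#' @param seed Integer seed.
#' @return Tibble per locus: `theta_obs`, `p_value`.
#' @export
ftemp_test <- function(counts0, counts_t, ne, generations,
                       n_sims = 1000L, seed = 1L) {
  if (n_sims < 100) warning("n_sims < 100 gives a very coarse null")
  as_cn <- function(x) if (is.null(dim(x))) matrix(x, nrow = 3) else x
  cn0 <- as_cn(counts0); cnt <- as_cn(counts_t)
  obs <- wc_components(cn0, cnt)
  n0 <- colSums(cn0); nt <- colSums(cnt)
  p0 <- (cn0[2, ] + 2 * cn0[3, ]) / (2 * n0)
  L <- ncol(cn0)
  two_ne <- round(2 * ne)
  with_seed(seed, {
    pv <- rep(NA_real_, L)
    # HWE genotype sample of n diploids at frequency p (vectorised over sims)
    draw_counts <- function(n, p, S) {
      n2 <- rbinom(S, n, p^2)
      rest <- 1 - p^2
      pr <- ifelse(rest > 0, 2 * p * (1 - p) / rest, 0)
      n1 <- rbinom(S, n - n2, pr)
      rbind(n0 = n - n2 - n1, n1 = n1, n2 = n2)
    }
    for (j in seq_len(L)) {
      if (is.na(obs$theta[j]) || p0[j] %in% c(0, 1)) {
        pv[j] <- 1
        next
      }
      p <- rep(p0[j], n_sims)
      for (g in seq_len(generations)) p <- rbinom(n_sims, two_ne, p) / two_ne
      c0 <- draw_counts(n0[j], rep(p0[j], n_sims), n_sims)
      ct <- draw_counts(nt[j], p, n_sims)
      null_theta <- wc_components(c0, ct)$theta
      pv[j] <- (1 + sum(null_theta >= obs$theta[j], na.rm = TRUE)) /
        (1 + n_sims)
    }
    tibble::tibble(theta_obs = obs$theta, p_value = pv)
  })
}

# Kernel weights and the loci contributing to one evaluation point.
kernel_weights <- function(cM, at, bandwidth, span = 3) {
  d <- abs(cM - at)
  idx <- which(d <= span * bandwidth)
  list(idx = idx, w = exp(-0.5 * (d[idx] / bandwidth)^2))
}

#' Kernel-smoothed moving average of FST along a chromosome
#'
#' Gaussian-kernel smoothing over map distance of the Weir-Cockerham variance
#' components: the smoothed value at a position is the ratio of the
#' kernel-weighted sums, `sum(w a) / sum(w (a + b + c))`. Loci beyond three
#' bandwidths contribute nothing; evaluation points with no contributing
#' locus are missing.
#'
#' @param track A [fst_track()] (or tibble with `chromosome`, `cM`, `a`, `b`,
#'   `c`); loci with missing components or positions are ignored.
#' @param bandwidth Gaussian sigma in cM (default 2.5).
#' @param eval_step Spacing of evaluation points in cM (default 1).
#' @return Tibble `chromosome`, `cM`, `n_loci` (contributing loci),
#'   `smoothed`.
#' @export
smooth_fst <- function(track, bandwidth = 2.5, eval_step = 1) {
  stopifnot(bandwidth > 0, eval_step > 0)
  tr <- dplyr::filter(track, !is.na(.data$cM), !is.na(.data$a))
  if (!nrow(tr)) {
    return(tibble::tibble(chromosome = integer(), cM = numeric(),
                          n_loci = integer(), smoothed = numeric()))
  }
  purrr::map_dfr(split(tr, tr$chromosome), function(ch) {
    at <- seq(floor(min(ch$cM)), ceiling(max(ch$cM)), by = eval_step)
    d <- ch$a + ch$b + ch$c
    res <- purrr::map_dfr(at, function(x) {
      kw <- kernel_weights(ch$cM, x, bandwidth)
      if (!length(kw$idx)) {
        return(tibble::tibble(cM = x, n_loci = 0L, smoothed = NA_real_))
      }
      tibble::tibble(cM = x, n_loci = length(kw$idx),
                     smoothed = sum(kw$w * ch$a[kw$idx]) /
                       sum(kw$w * d[kw$idx]))
    })
    dplyr::bind_cols(tibble::tibble(chromosome = ch$chromosome[1],
                                    .rows = nrow(res)), res)
  })
}

#' Resampled null envelope and outlier regions for a smoothed FST track
#'
#' At each evaluation point with k contributing loci, k loci are drawn with
#' replacement from the genomewide pool of per-locus variance components,
#' the smoothed statistic is recomputed with the same kernel weights, and
#' the 2.5/97.5 percentiles over `n_resamples` draws form the null envelope.
#' Outlier regions are maximal runs of consecutive evaluation points whose
#' observed smoothed value exceeds the upper bound.
#'
#' @inheritParams smooth_fst
#' @param n_resamples Number of null resamples per evaluation point.
#' @param seed Integer seed.
#' @param pool Optional component tibble (`a`, `b`, `c`) to resample from;
#'   defaults to the mapped loci of `track` itself.
#' @return List of class `hatch_window_scan`: `points` (tibble `chromosome`,
#'   `cM`, `n_loci`, `smoothed`, `lower`, `upper`, `outlier`) and `regions`
#'   (tibble `chromosome`, `cM_start`, `cM_end`, `n_points`, `peak`).
#' @export
window_null <- function(track, bandwidth = 2.5, eval_step = 1,
                        n_resamples = 1000L, seed = 1L, pool = NULL) {
  tr <- dplyr::filter(track, !is.na(.data$cM), !is.na(.data$a))
  if (is.null(pool)) pool <- tr
  if (nrow(pool) < 50) warning("component pool smaller than 50 loci")
  pa <- pool$a
  pd <- pool$a + pool$b + pool$c
  with_seed(seed, {
    points <- purrr::map_dfr(split(tr, tr$chromosome), function(ch) {
      at <- seq(floor(min(ch$cM)), ceiling(max(ch$cM)), by = eval_step)
      d <- ch$a + ch$b + ch$c
      res <- purrr::map_dfr(at, function(x) {
        kw <- kernel_weights(ch$cM, x, bandwidth)
        k <- length(kw$idx)
        if (!k) {
          return(tibble::tibble(cM = x, n_loci = 0L, smoothed = NA_real_,
                                lower = NA_real_, upper = NA_real_))
        }
        smoothed <- sum(kw$w * ch$a[kw$idx]) / sum(kw$w * d[kw$idx])
        idx <- matrix(sample.int(length(pa), k * n_resamples, replace = TRUE),
                      nrow = k)
        null <- colSums(kw$w * matrix(pa[idx], nrow = k)) /
          colSums(kw$w * matrix(pd[idx], nrow = k))
        ci <- quantile(null, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
        tibble::tibble(cM = x, n_loci = k, smoothed = smoothed,
                       lower = ci[1], upper = ci[2])
      })
      dplyr::bind_cols(tibble::tibble(chromosome = ch$chromosome[1],
                                      .rows = nrow(res)), res)
    })
    points$outlier <- !is.na(points$smoothed) & !is.na(points$upper) &
      points$smoothed > points$upper
    regions <- purrr::map_dfr(split(points, points$chromosome), function(pp) {
      r <- rle(pp$outlier)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      runs <- which(r$values)
      purrr::map_dfr(runs, function(i) {
        seg <- pp[starts[i]:ends[i], ]
        tibble::tibble(chromosome = seg$chromosome[1],
                       cM_start = min(seg$cM), cM_end = max(seg$cM),
                       n_points = nrow(seg), peak = max(seg$smoothed))
      })
    })
    structure(list(points = points, regions = regions),
              class = "hatch_window_scan")
  })
}

#' Scan both hatchery lines against the founders
#'
#' For every line x generation contrast against the founder population:
#' per-locus theta, the kernel-smoothed track, the resampled null envelope
#' and region calls; plus the temporal drift test per line between the
#' founders and the line's last sampled generation.
#'
#' @param gm QC'd wide genotype tibble with `population` labels of the form
#'   `LINE_Fg` (founders `P1_F0`).
#' @param map Linkage map with `locus`, `chromosome`, `cM`.
#' @param ne Named list/vector of effective sizes per line, e.g.
#'   `c(INT = 150, SEG = 60)`, for the temporal null.
#' @param lines Lines to scan (default INT and SEG).
#' @param founder_population Label of the reference population.
#' @param bandwidth,eval_step,n_resamples Passed to the window scan.
#' @param n_sims Temporal-test null simulations per locus.
#' @param alpha Significance level for temporal-test locus calls.
#' @param fdr_adjust Apply Benjamini-Hochberg adjustment to the temporal
#'   test's p-values before calling loci (default FALSE; the unadjusted
#'   p-values are always reported in `$ftemp`).
#' @param seed Integer seed.
#' @return List of class `hatch_scan`: `tracks` (per-contrast smoothed points
#'   with envelopes, long tibble with `line`, `generation`), `calls` (tibble
#'   of [OutlierCall]-shaped rows: `kind`, `method`, `line`, `generation`,
#'   `chromosome`, `locus`, `cM_start`, `cM_end`, `statistic`, `p_value`) and
#'   `ftemp` (per-locus temporal results per line).
#' @export
scan_lines <- function(gm, map, ne, lines = c("INT", "SEG"),
                       founder_population = "P1_F0",
                       bandwidth = 2.5, eval_step = 1,
                       n_resamples = 500L, n_sims = 1000L,
                       alpha = 0.05, fdr_adjust = FALSE, seed = 1L) {
  pops <- unique(gm$population)
  tracks <- list(); calls <- list(); ftemp <- list()
  k <- 0L
  for (ln in lines) {
    gens <- sort(unique(gm$generation[gm$line == ln & gm$generation > 0]))
    for (g in gens) {
      k <- k + 1L
      tr <- fst_track(gm, map, founder_population, paste0(ln, "_F", g))
      ws <- window_null(tr, bandwidth, eval_step, n_resamples,
                        seed = derive_seed(seed, k))
      tracks[[k]] <- dplyr::bind_cols(
        tibble::tibble(line = ln, generation = g, .rows = nrow(ws$points)),
        ws$points)
      if (nrow(ws$regions)) {
        calls[[length(calls) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(kind = "region", method = "window", line = ln,
                         generation = g, .rows = nrow(ws$regions)),
          ws$regions[c("chromosome", "cM_start", "cM_end", "peak")])
      }
    }
    # temporal test: founders vs the line's last sampled generation
    g_last <- max(gens)
    cn0 <- population_counts(gm, founder_population)
    cnt <- population_counts(gm, paste0(ln, "_F", g_last))
    ft <- ftemp_test(cn0, cnt, ne = ne[[ln]], generations = g_last,
                     n_sims = n_sims, seed = derive_seed(seed, 1000L + k))
    ft <- dplyr::bind_cols(tibble::tibble(locus = colnames(cn0)), ft)
    ftemp[[ln]] <- dplyr::bind_cols(
      tibble::tibble(line = ln, generation = g_last, .rows = nrow(ft)), ft)
    p_call <- if (fdr_adjust) p.adjust(ft$p_value, "BH") else ft$p_value
    sig <- ft[!is.na(p_call) & p_call < alpha, ]
    if (nrow(sig)) {
      sig <- dplyr::left_join(sig, map[c("locus", "chromosome", "cM")],
                              by = "locus")
      calls[[length(calls) + 1L]] <- tibble::tibble(
        kind = "locus", method = "ftemp", line = ln, generation = g_last,
        chromosome = sig$chromosome, locus = sig$locus,
        cM_start = sig$cM, cM_end = sig$cM,
        statistic = sig$theta_obs, p_value = sig$p_value)
    }
  }
  calls <- dplyr::bind_rows(calls)
  if (!nrow(calls)) {
    calls <- tibble::tibble(kind = character(), method = character(),
                            line = character(), generation = integer(),
                            chromosome = integer(), locus = character(),
                            cM_start = numeric(), cM_end = numeric(),
                            statistic = numeric(), p_value = numeric())
  }
  structure(list(tracks = dplyr::bind_rows(tracks), calls = calls,
                 ftemp = dplyr::bind_rows(ftemp)),
            class = "hatch_scan")
}

#' Merge externally supplied outlier calls
#'
#' Calls from external tools (e.g. a Bayesian FST outlier scan) can be folded
#' into the call table with `method = "external"`.
#'
#' @param calls Call tibble from [scan_lines()] (`$calls`).
#' @param external Tibble with at least `locus` and `line`; optional
#'   `statistic`, `p_value`, `generation`.
#' @param map Optional linkage map to attach positions.
#' @return Combined call tibble.
#' @export
merge_external_outliers <- function(calls, external, map = NULL) {
  ext <- tibble::as_tibble(external)
  ext$kind <- "locus"
  ext$method <- "external"
  if (!is.null(map)) {
    ext <- dplyr::left_join(ext, map[c("locus", "chromosome", "cM")],
                            by = "locus")
    ext$cM_start <- ext$cM
    ext$cM_end <- ext$cM
    ext$cM <- NULL
  }
  dplyr::bind_rows(calls, ext)
}
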