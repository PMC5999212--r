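#' Trait names analysed by the pipeline
#'
#' Six adult fitness traits: age at maturity (years, ordinal 3/4/5), day of
#' return to the spawning grounds, spawn day, fork length (cm), weight (kg)
#' and daily growth coefficient (DGC, unitless).
#' @export
hatch_traits <- function() {
  c("age", "return_day", "spawn_day", "length_cm", "weight_kg", "dgc")
}

#' Default trait architectures for the study-design simulator
#'
#' One list per trait with the fields:
#' \describe{
#'   \item{n_causal}{number of causal loci drawn from the polymorphic loci}
#'   \item{h2}{narrow-sense heritability targeted on the trait (for weight,
#'     on the log-scale allometric residual; for age, on the latent liability)}
#'   \item{base, total_sd}{location and scale of the trait in its own units}
#'   \item{line_effect}{fixed effect added to the segregated line}
#'   \item{sex_effect}{fixed effect added to males}
#'   \item{year_effect}{fixed effect per generation (year = 2000 + generation)}
#' }
#' An architecture may also carry `causal` (locus ids or indices) to pin the
#' causal loci instead of sampling them, e.g. to align a trait with
#' configured selection targets, and `effect_dist` (`"normal"` for standard
#' Gaussian effect sizes, `"equal"` for unit effects of random sign, or a
#' function of n) controlling the causal effect-size distribution.
#' Scales follow typical spring Chinook hatchery broodstock: return-day SD
#' near three weeks, spawn-day SD near one week, ~75% maturing at age four.
#'
#' @return Named list of architectures, one per [hatch_traits()] entry.
#' @export
default_trait_architectures <- function() {
  list(
    age        = list(n_causal = 10, h2 = 0.30, base = 0,    total_sd = 1,
                      line_effect = 0,   sex_effect = 0,   year_effect = 0),
    return_day = list(n_causal = 10, h2 = 0.30, base = 160,  total_sd = 22,
                      line_effect = 4,   sex_effect = 3,   year_effect = 1),
    spawn_day  = list(n_causal = 10, h2 = 0.30, base = 260,  total_sd = 8,
                      line_effect = 2,   sex_effect = 1,   year_effect = 0.5),
    length_cm  = list(n_causal = 10, h2 = 0.35, base = 74,   total_sd = 6,
                      line_effect = -1,  sex_effect = 4,   year_effect = 0.3),
    weight_kg  = list(n_causal = 10, h2 = 0.30, base = 0,    total_sd = 0.08,
                      line_effect = -0.03, sex_effect = 0.02, year_effect = 0),
    dgc        = list(n_causal = 10, h2 = 0.30, base = -0.15, total_sd = 0.05,
                      line_effect = -0.01, sex_effect = 0,  year_effect = 0)
  )
}

#' Configuration for the two-line hatchery study simulator
#'
#' Describes a supportive-breeding design: wild founders (P1) give rise to an
#' integrated line (a fraction of parents drawn from a persistent wild pool
#' each generation) and a segregated line (closed), each propagated for
#' `n_generations` generations of Wright-Fisher drift with optional viability
#' selection in the segregated line.
#'
#' @param n_loci Number of biallelic loci.
#' @param n_chromosomes Number of linkage groups (default 34).
#' @param founder_maf_dist Beta shape parameters (length 2) for founder
#'   allele frequencies.
#' @param founder_freq Optional numeric vector of founder allele frequencies
#'   overriding the Beta draw (recycled to `n_loci`).
#' @param n_generations Generations per line after the founders (default 4).
#' @param samples_per_population Individuals sampled per line x generation.
#' @param ne_integrated,ne_segregated,ne_wild Effective sizes of the
#'   integrated line, the segregated line, and the persistent wild pool.
#' @param gene_flow_integrated Fraction of integrated-line parents drawn from
#'   the wild pool each generation, in `[0, 1]`.
#' @param selected_loci Data frame with columns `locus` (index into 1..n_loci)
#'   and `s` (selection coefficient); viability fitnesses are
#'   `(1, 1 + s/2, 1 + s)` for 0/1/2 copies of the selected allele, applied in
#'   the segregated line only.
#' @param trait_architectures Named list as in
#'   [default_trait_architectures()]; entries given here override defaults
#'   field-by-field.
#' @param depth_model List with `mean` (mean total read depth), `dispersion`
#'   (negative-binomial size) and `error` (allelic error rate).
#' @param mapped_fraction Fraction of loci carried on the linkage map.
#' @param seed Integer seed fixing all downstream randomness.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 2000,
                       n_chromosomes = 34,
                       founder_maf_dist = c(1, 1),
                       founder_freq = NULL,
                       n_generations = 4,
                       samples_per_population = 100,
                       ne_integrated = 150,
                       ne_segregated = 60,
                       ne_wild = 1000,
                       gene_flow_integrated = 0.5,
                       selected_loci = NULL,
                       trait_architectures = list(),
                       depth_model = list(mean = 40, dispersion = 10,
                                          error = 0.001),
                       mapped_fraction = 0.7,
                       seed = 1L) {
  arch <- default_trait_architectures()
  for (tr in names(trait_architectures)) {
    if (!tr %in% names(arch)) {
      stop_input("unknown trait in trait_architectures: ", tr)
    }
    arch[[tr]][names(trait_architectures[[tr]])] <- trait_architectures[[tr]]
  }
  cfg <- list(
    n_loci = as.integer(n_loci),
    n_chromosomes = as.integer(n_chromosomes),
    founder_maf_dist = as.numeric(founder_maf_dist),
    founder_freq = founder_freq,
    n_generations = as.integer(n_generations),
    samples_per_population = as.integer(samples_per_population),
    ne_integrated = ne_integrated,
    ne_segregated = ne_segregated,
    ne_wild = ne_wild,
    gene_flow_integrated = gene_flow_integrated,
    selected_loci = if (is.null(selected_loci)) {
      tibble::tibble(locus = integer(), s = numeric())
    } else {
      tibble::as_tibble(selected_loci)
    },
    trait_architectures = arch,
    depth_model = utils::modifyList(
      list(mean = 40, dispersion = 10, error = 0.001), depth_model),
    mapped_fraction = mapped_fraction,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_loci < 1L) stop_input("n_loci must be positive")
  if (length(cfg$founder_maf_dist) != 2 || any(cfg$founder_maf_dist <= 0)) {
    stop_input("founder_maf_dist must be two positive Beta shape parameters")
  }
  if (!is.null(cfg$founder_freq) &&
      any(cfg$founder_freq < 0 | cfg$founder_freq > 1)) {
    stop_input("founder_freq must lie in [0, 1]")
  }
  if (cfg$n_generations < 1L) stop_input("n_generations must be >= 1")
  if (any(c(cfg$ne_integrated, cfg$ne_segregated, cfg$ne_wild) <= 0)) {
    stop_input("effective sizes must be positive")
  }
  if (cfg$gene_flow_integrated < 0 || cfg$gene_flow_integrated > 1) {
    stop_input("gene_flow_integrated must lie in [0, 1]")
  }
  for (tr in names(cfg$trait_architectures)) {
    h2 <- cfg$trait_architectures[[tr]]$h2
    if (h2 < 0 || h2 > 1) stop_input("h2 for ", tr, " must lie in [0, 1]")
  }
  with(cfg$depth_model, {
    if (mean <= 0 || dispersion <= 0) stop_input("depth mean/dispersion must be positive")
    if (error < 0 || error > 1) stop_input("allelic error rate must lie in [0, 1]")
  })
  invisible(cfg)
}
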