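---
title: "Monitoring domestication selection in paired hatchery lines: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring domestication selection in paired hatchery lines: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hatchscan)
```

## The scientific setting

Supportive-breeding programs for Pacific salmon often maintain two captive
lines descended from the same wild founders: an *integrated* line, whose
broodstock includes wild-born parents every generation (managed gene flow),
and a *segregated* line, which is closed after founding. Comparing the two
lines over a handful of generations asks whether hatchery rearing is driving
genetic change at loci that matter for fitness — return timing, spawn
timing, size at return, age at maturity and growth in captivity — faster in
the closed line than in the line anchored to the wild population.

`hatchscan` implements the full analysis chain for that comparison on
reduced-representation (RAD-seq) genotype data, together with a seeded
simulator of the whole study design so that every stage can be checked
against known truth: calibration of outlier tests, power to recover causal
loci, and the end-to-end asymmetry between lines under simulated
domestication selection.

## Genotype calling and quality control

Genotypes are called from per-allele read depths. A call is heterozygous
when both alleles have depth at least 2 and combined depth strictly greater
than 10. The rule's source defines only the heterozygote condition; for the
remaining patterns we call a homozygote when the minority allele has at most
one read and the total is at least 10, and otherwise return a missing
genotype. This is deliberately conservative: a 3/7 split is neither a
credible heterozygote under the rule nor a safe homozygote, so it stays
missing rather than inventing a call.

The QC cascade then applies, in order:

1. **MAF screen** — a locus is kept if its minor allele frequency is at
   least 0.05 in *at least one* population (line x generation), computed on
   called genotypes only;
2. **individual missingness** — individuals with >= 50% missing genotypes
   are removed;
3. **locus missingness** — loci not called in at least 50% of individuals
   in *every* population are removed;
4. **Hardy-Weinberg screen** — loci out of Hardy-Weinberg proportions
   (exact test, below) in two or more populations are removed, a standard
   guard against paralogous RAD tags in salmonids, whose genome retains
   extensive residual tetrasomy;
5. **imputation** — remaining missing genotypes are filled from
   population-conditional genotype frequencies.

We run the Hardy-Weinberg screen on called (pre-imputation) genotypes and
impute last, so the screen never sees imputed entries; the original workflow
imputed before screening. With frequency-based imputation the two orders
give the same screen in expectation, and imputing last guarantees the
delivered matrix is complete.

The Hardy-Weinberg test is the conditional exact test: given the allele
counts, the heterozygote count follows the Levene–Haldane distribution, and
the two-sided p-value sums the probabilities of all configurations no more
probable than the observed one. This replaces a Markov-chain implementation
used historically; exact enumeration is deterministic and testable to
machine precision. The screen's significance level defaults to 0.05 and is
configurable.

Imputation replaces a haplotype-cluster model (fastPhase) with
population-conditional genotype-frequency imputation: each missing entry is
drawn from (or set to the mode of) the maximum-likelihood genotype
distribution of its own population at that locus. For unphased single-locus
genotypes those observed frequencies *are* the EM fixed point, so nothing is
lost at the single-locus level; what the stand-in forgoes is borrowing
information across linked loci. The diagnostic the pipeline reports — the
correlation of per-locus allele frequencies before and after imputation —
is preserved by construction, which is exactly the property the original
validation checked.

## Anchoring unmapped loci

Loci absent from the linkage map are placed by proximity on proxy genomes:
an unmapped locus adopts the map position of the nearest mapped locus on the
same contig of the same genome, provided both alignments have mapping
quality >= 10 and the interval gap is at most 100 kb (overlapping intervals
count as distance 0). Coordinates are 0-based half-open throughout. When two
proxy genomes both anchor a locus, the assignment is kept only if they agree
on the chromosome, taking the smaller-distance donor's position; chromosome
conflicts are dropped and logged. Ties in distance break deterministically
on the smaller donor id. Cross-genome chaining (an unmapped locus near a
mapped locus of a *different* genome) is not allowed.

## Random-forest association

Polygenic traits call for a multivariate association method; random forests
handle correlated predictors and non-additivity without per-locus testing.
The chain per trait:

1. **Confounder correction.** PC1 of the centred dosage matrix captures the
   dominant axis of population structure. Each continuous phenotype and each
   locus dosage column is replaced by its OLS residual against hatchery
   line, sex, age, year and PC1. Age at maturity stays categorical (its
   discreteness is the point), so for the age analysis only the genotypes
   are corrected, with every factor except age. Founders are excluded so the
   design is the paired line comparison.
2. **ntree tuning.** Replicate forests differing only in seed are grown at
   increasing tree counts; the smallest count at which all pairwise Pearson
   correlations of locus importances exceed 0.8 is used.
3. **Importance averaging.** Three forests are grown on all loci and their
   permutation importances averaged (increase in MSE for regression; mean
   decrease in accuracy for the age classification, with every class
   downsampled to the smallest class count per tree to balance the heavily
   age-4-skewed distribution).
4. **Top-fraction screening.** Forests are re-grown on the top 0.5%, 1%,
   2%, 3% and 5% of loci; the fraction with the best out-of-bag metric
   wins. "Percent variation explained" is operationalised as out-of-bag
   R^2, `100 * (1 - OOB-MSE / Var(y))`; negative values are allowed and
   meaningful.
5. **Backward purging.** The best fraction, expanded by 1.5x, seeds the
   purge: at each step three forests are grown, the metric recorded, and
   the least-important locus removed (importances re-computed every step),
   down to two loci. The reported predictor set is the one with the best
   metric anywhere along the trajectory, which is retained in full.

Forests are fitted with `ranger` with a fixed seed and one thread, so every
stochastic step is exactly reproducible.

**A known limitation worth stating plainly:** the out-of-bag metric of a
locus set that was itself selected by importance on the same individuals is
optimistically biased. Out-of-bag error protects against overfitting the
*trees*, not the *feature selection*. In simulations with a heritability-zero
trait, 400 individuals and 2000 loci, the backward-purged set still shows a
median out-of-bag "variance explained" around 15–20%. The package reports
the metric as defined, and the acceptance suite measures this bias rather
than hiding it; absolute values of percent-variation-explained from this
procedure should be read as upper bounds, while comparisons between traits
analysed identically remain informative.

## Divergence scans

**Per-locus FST.** The two-population Weir–Cockerham (1984) theta is
computed from genotype counts, returning the variance components *a* (among
populations), *b* (among individuals within populations) and *c* (within
individuals) so multi-locus estimates aggregate as ratios of component sums
— never means of ratios. Negative estimates at weakly divergent loci are
expected with finite samples and are retained.

**Temporal drift test.** For a single population sampled at generation 0
and generation t, the observed statistic is theta between the two samples.
The null conditions on the sample-estimated initial frequency: each of
`n_sims` replicates propagates that frequency through t generations of
binomial drift at the stated effective size, draws Hardy–Weinberg genotype
samples of the observed sizes at both ends, and recomputes the statistic.
`p = (1 + #{null >= observed}) / (1 + n_sims)`; a fixed initial sample gives
p = 1 by convention. The effective sizes are required inputs — they are
properties of the monitored program, not constants of the method. No
multiple-testing adjustment is applied by default; Benjamini–Hochberg
adjustment is available as an option.

**Smoothed tracks and window nulls.** Along each chromosome, a Gaussian
kernel over map distance (default sigma 2.5 cM, evaluated every 1 cM, both
configurable; loci beyond three bandwidths contribute nothing) smooths the
variance components as a weighted component ratio. The null envelope at
each evaluation point resamples, with replacement from the genomewide pool
of per-locus components, as many loci as contribute to that point,
recomputing the smoothed value with the same kernel weights; the 2.5th and
97.5th percentiles over the resamples form the envelope. An outlier region
is a maximal run of consecutive points whose observed smoothed value
exceeds the upper bound — only elevated divergence is called, and the
envelope itself is the error control (no further correction). The defaults
(bandwidth 2.5 cM, 1 cM step, 400–1000 resamples) match the spatial scale
at which a handful of linked RAD loci inform a window on a ~100 cM linkage
group.

`scan_lines()` assembles the study's comparison set: every line x
generation against the founders for window scans, plus the temporal test
per line between founders and the line's last sampled generation.
Externally produced outlier calls (e.g. from a Bayesian FST method, which
this package consumes rather than reimplements) can be merged into the call
table.

## Phenotype models and integration

The daily growth coefficient is
`DGC = 100 * (final^(1/3) - initial^(1/3)) / days`, a cube-root growth
measure largely independent of initial weight; here it is typically
negative, measuring weight loss during broodstock holding.

Line contrasts use `y ~ line + sex + line:sex` with a Gaussian identity
link for return timing, spawn timing, fork length and DGC, and a Poisson
log link for age at maturity; weight adds allometry:
`log(weight) ~ line + sex + line:sex + log(fork length)`. The intercept's
reference level is integrated-line females. All traits except age are fitted
on age-4 fish only, since age-4 is the dominant maturity class and removes
age-size confounding; the age model uses all fish.

PCA trajectories project all line x generation groups onto the leading
principal components of the dosage matrix restricted to one trait's
predictor loci; the per-generation distance between the two lines' centroids
(with a bootstrap standard error) quantifies what would otherwise be a
visual judgment of overlap.

The overlap report crosses trait-associated loci with outlier calls three
ways: exact locus identity, proximity within a configurable radius (default
1.0 cM — co-mapping conventions in the literature range from 0.01 cM to
multi-cM regions, so the radius is reported with every row), and
containment in outlier regions. Unmapped trait loci participate in identity
overlap only.

## The simulator: what it emulates and what it does not

`simulate_study()` generates the full study design from one seeded config:

- **Founders** with allele frequencies from a configurable Beta
  distribution, Hardy–Weinberg genotypes, and loci placed uniformly over 34
  linkage groups (the Chinook karyotype) with uniform cM positions.
- **Two lines** propagated as allele-frequency processes: the segregated
  line is a closed Wright–Fisher population (binomial resampling of
  `2 * Ne` gametes per generation), with optional viability selection
  (fitnesses 1, 1+s/2, 1+s — the simplest scheme that produces directional
  change for power studies); the integrated line mixes a configurable
  fraction of parents (default 0.5) from a persistent wild pool that drifts
  at its own, larger Ne. The factorial mating scheme of real broodstock
  management is abstracted to parent sampling; there is no explicit
  pedigree.
- **Phenotypes** built from a standardised additive genetic score over
  causal loci plus orthogonalised Gaussian noise, so realised heritability
  equals the target exactly in-sample, plus line/sex/year fixed effects.
  Age is an ordinal trait cut from a latent liability at the 15th and 90th
  normal quantiles, so about 75% of fish mature at age four with realistic
  minorities at three and five. Weight is allometric in length
  (`1.1e-5 * length^3`, condition factor ~1.1) with the architecture acting
  on the log-scale residual; DGC is realised through initial/final weights
  and holding days so the growth formula inverts it exactly. Default trait
  scales (return-day SD ~3 weeks, spawn-day SD ~1 week, fork length 74 ± 6
  cm) follow typical spring Chinook broodstock. Causal effect sizes default
  to Gaussian; an equal-effects option exists because power studies of
  "k causal loci" are only meaningful when each locus is individually
  detectable.
- **Read depths** per genotype: total depth negative binomial (default
  mean 40, dispersion 10 — overdispersed as RAD libraries are, while deep
  enough that a heterozygote passes the two-reads-each/total>10 rule more
  than 99% of the time, matching the closed-form tail computation),
  binomial allele split for heterozygotes, off-allele reads at the allelic
  error rate (default 0.001) for homozygotes.
- **Alignments** to two proxy genomes at 1 Mb/cM with planted, clearance-
  checked donor geometry, so the anchoring rules can be verified exactly,
  including deliberate violations of the distance and quality thresholds.

Effective sizes are deliberate inputs, not defaults drawn from any real
program: the package ships `ne_integrated = 150`, `ne_segregated = 60`,
`ne_wild = 1000` as a plausible supportive-breeding regime in which the
closed line drifts markedly faster. Selection strengths in scenarios are
likewise user-set hypotheses.

What the simulator does *not* emulate: linkage disequilibrium within
chromosomes (loci drift independently, so window power studies plant
*blocks* of selected loci to mimic a swept region), sequence-level reads,
genotyping batch effects, pedigree structure, or age-structured overlapping
generations. Passing tests on simulated data therefore demonstrate the
statistical machinery under the stated model, not robustness to every
feature of real RAD data.

## Numerical and design choices

- All randomness flows from one integer seed per config or function call;
  sub-streams are derived with a fixed multiplicative hash, and forest
  fitting pins `seed` and `num.threads = 1`. Reruns are bit-identical.
- The exact HWE p-value uses log-factorial enumeration with a `1 + 1e-9`
  relative guard when summing probabilities "at most" the observed one, so
  ties in probability are included rather than lost to rounding.
- Monomorphic loci: theta undefined (NA), HWE p = 1, F_IS undefined.
- Wright–Fisher updates round `2 * Ne` to an integer gamete count; loci may
  fix and stay fixed, which is legitimate behaviour, not an error.
- The purge trajectory always runs to two loci; the reported set is chosen
  over the whole trajectory. A candidate set smaller than three loci is
  returned unpurged with a warning.
- Desk-scale problem sizes used in tests and the acceptance script (e.g.
  2000 loci x 400 analysed individuals for the association power study;
  500–1000 loci for scan calibration; 300–500 trees per forest at the
  screening stage) were chosen as the smallest sizes at which the studied
  properties are stable; all are configurable upward.

## Known limitations

- The out-of-bag metric bias from importance-based pre-selection, described
  above: a cross-sample (held-out) evaluation would remove it but would
  depart from the procedure this package sets out to reproduce.
- Frequency-based imputation does not use linkage information; with very
  high missingness it shrinks genotypes toward population frequencies.
- The temporal test assumes the configured Ne and discrete generations; the
  integrated line's null ignores its gene flow, which makes its calls
  conservative (migration from the shared wild pool reduces net divergence
  from the founders).
- Window nulls resample loci as exchangeable, so genomewide backgrounds
  that differ systematically between chromosomes are not modelled.
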