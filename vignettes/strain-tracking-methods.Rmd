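---
title: "Tracking strain populations with rare marker SNVs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking strain populations with rare marker SNVs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainseed)
```

## The problem

Shotgun metagenomes of the gut cannot resolve individual bacterial strains,
but within one person the single-nucleotide-variant (SNV) profile of a
species is a stable fingerprint of its resident *strain population* —
possibly several coexisting conspecific strains. Comparing fingerprints
between family members and across time answers three questions this package
is built around: where do an infant's first colonizers come from, how long
do they persist, and who transmits strains to whom inside a family.

The difficulty is that most SNVs are common in the population: observing
the same common allele in two people is no evidence of transmission. The
package therefore works with **rare marker SNVs (rmSNVs)**: for every
compared pair of samples (A, B), a *pair-specific reference population* is
formed from all samples of all individuals unrelated to either donor —
including a large unrelated background cohort — and the markers of A are
the alleles present in A but in **no** reference sample. Both donors'
families are excluded from the reference even when the two donors are
unrelated, so that family-shared alleles can still serve as markers. Two
refinements exist: FmSNVs (identical marker rule; the name stresses that
family members may share them) and EmSNVs, which additionally exclude
alleles seen in any *other* member of the two families, isolating sharing
exclusive to the pair.

## The sharing statistic and its calibration

Directional similarity A→B is

\[
s_{A \to B} \;=\;
\frac{\#\{\text{markers of } A \text{ whose allele is present in } B\}}
     {\#\{\text{marker positions of } A \text{ covered in } B\}},
\]

assessed only when more than 100 marker positions are available (strict
inequality), and set to 0 — defined, not missing — when the species has
zero genome coverage in either sample. An allele is *present* when its
position is covered and the observed frequency is at least `min_freq`
(default 0.05); coverage matters because an uncovered position carries no
information and must not be confused with reference-only (frequency 0).
Marker identification is inherently asymmetric, so the pair-level value is
the marker-count-weighted mean of the defined directional similarities,
with both directions retained for audit (`sharing_table()`).

*Strain sharing* is called when similarity is strictly above 0.2. The
cutoff is deliberately conservative and is calibrated empirically: on
simulated null cohorts (no transmission between families),
`calibrate_cutoff()` measures how often unrelated pairs exceed each
candidate cutoff; at 0.2 the exceedance — the empirical false-discovery
rate of the call — stays below 0.5% (see `null_calibration_experiment()`
and the acceptance suite). Similarity below 1 does not imply distinct
strains: SNV frequency spectra are typically bimodal (one dominant strain),
but mixtures are common in infants, and a shared strain can coexist with a
non-shared one; the 0.2 cutoff is chosen to call sharing robustly in that
regime. `snv_frequency_modality()` reports the spectrum diagnostic.

Two QC layers guard the statistic. `select_tracked_species()` keeps species
with vertical coverage above 10x and horizontal coverage above 0.4 in at
least two members of some family — the regime where markers are plentiful
enough to compare. `bias_diagnostics()` checks, per taxonomic class, that
similarity is not associated with marker richness or species abundance;
classes where it is (insufficient sampling depresses similarity) are
flagged for exclusion.

## Transmission inference

**Maternal classification.** Per species, a child's strain population is
labeled *maternal* when the symmetric rmSNV similarity between the child's
first available sample and the mother's nearest-in-time sample exceeds the
strain-sharing cutoff, *nonmaternal* when defined and at or below it, and
*untracked* when undefined. The label is frozen: later samples never
revise it, so a nonmaternal species that later converges toward the mother
(postnatal acquisition) keeps its original label. We use the mother's
nearest-in-time sample because family cohorts typically sample mothers
once, near delivery; when no common timeline (`collection_day`) exists,
her earliest sample is used.

**Persistence and drift.** `persistence_curve()` reduces within-individual
comparisons to per-individual medians within groupings (age group, class,
maternal label) — reduction-first avoids pseudo-replication and matches
how group summaries are built throughout (`group_summary()`).
`annual_change()` estimates the average annual strain turnover as the
slope of a through-origin linear fit of \(1 - s\) against the time gap in
years, with a bootstrap confidence interval over individuals. We feed it
consecutive-timepoint records only: non-overlapping intervals are
independent replacement opportunities, whereas long spans compound several
intervals and double-count the same events. Note a structural property:
under whole-strain replacement with annual probability \(\delta\), the
expected fraction replaced over \(\Delta t\) years is
\(1 - (1-\delta)^{\Delta t}\), which is sub-linear; a linear fit over
multi-year gaps therefore sits slightly below \(100\,\delta\) %/yr (about
12 when \(\delta = 0.13\) over 0.5–3-year gaps). The estimator is kept
linear because it is the transparent, assumption-light summary of the
decline; the vignette states the property so it is not mistaken for a bug.

**Directionality.** Novel SNVs of an individual are alleles present now at
positions that were covered in at least one earlier sample of that
individual and absent from every earlier covered observation — positions
never covered before are excluded, because non-observation is not absence.
All SNVs are used here (not only markers) to maximize the number of
events. `attribute_transmission()` credits a family member as donor when a
strict majority of the event's novel alleles appear in that member's
strictly earlier samples; several members can be credited, and per-member
support counts are always emitted for audit. Role-level donor→recipient
proportions (events / comparisons) summarize directionality
(`detect_family_transmissions()`).

**Birth mode.** `birthmode_contrast()` cross-tabulates children (any
maternal species vs none) by delivery mode and reports the chi-squared
test both without and with continuity correction; the uncorrected
statistic is the headline because the expected counts derive from dozens
of children.

## Composition

Species abundance is vertical genome coverage normalized within sample
(`relative_abundance()`); compositional similarity is the Pearson
correlation of log abundances over the union of species in either profile
(`composition_similarity()`). Zeros are shifted by a pseudocount before
the log; the default `1e-6` is of the order of the smallest detectable
abundance, and the value is a free parameter precisely because no
principled zero-replacement exists for compositions. A zero-variance log
vector yields `NA` — an undefined correlation is not a correlation of 0.

## Statistics

Similarity is a proportion, so group differences are tested with beta
regression: beta-distributed response, logit mean link, single precision
parameter with log link, fitted by maximum likelihood with analytic
gradients and Wald tests from the observed information
(`beta_regression()`). Responses touching 0 or 1 are first compressed by
the standard \(y' = (y(n-1) + 0.5)/n\) transform. The implementation is
validated three ways in the test suite: the score equations vanish at the
optimum, coefficients agree with an independent ML implementation
(`mgcv::gam` with its beta family) to four decimals, and the type-I error
over 1000 null simulations lies in [0.03, 0.07] at nominal 0.05. One
caution: the ML mean of an intercept-only beta model is *not* exactly the
arithmetic sample mean (the likelihood matches log-moments), so the tests
check score equations rather than a mean identity. Compositional
similarity is approximately normal and is handled with ordinary linear
models (`linear_trend()`). Clustering by individual is handled by the
reduction-first rule rather than random effects, keeping the model classes
simple and matching how the medians are defined.

## The synthetic cohort generator

`simulate_cohort()` exists so that every stage can be exercised against a
known truth; it emulates the statistical structure the analysis relies on,
not gut ecology. Per species:

1. common sites receive population alternative-allele frequencies from
   Beta(0.5, 5) — a skewed spectrum that makes common SNVs common;
2. every founding strain draws each common site at its population
   frequency and receives a block of *private alleles* from a monomorphic
   site pool partitioned disjointly across strains — exclusivity is
   structural, so the ground-truth private ledger is exact by
   construction;
3. vaginally born children copy the mother's strain haplotypes at birth
   per class (`p_vertical`: 1 for Actinobacteria and Bacteroidia, 0 for
   Clostridia by default); Caesarean-born children start environmental and
   can acquire the maternal strain postnatally as a two-strain mixture
   with a Beta(2, 2) weight;
4. between samples \(\Delta t\) apart a strain population is wholly
   replaced with probability \(1-(1-\delta)^{\Delta t}\) (default
   \(\delta = 0.13\)/yr), by an environmental strain or, optionally, a
   family member's current one (father-biased donor weights let the
   directionality machinery be tested against truth);
5. observation: vertical coverage is Gamma-distributed around the
   abundance-scaled mean depth (default 20x; class abundance profiles
   differ between infants and adults), horizontal coverage follows
   \(1 - e^{-vc}\), each site is covered with that probability, covered
   sites report the carried-strain mixture fraction under binomial
   sampling at a Poisson site depth, frequencies below 0.05 are floored
   to 0, and uncovered sites are MISSING. `noise_free = TRUE` switches to
   exact reporting for analytic checks.

Key sizing choice: defaults use 800 common sites and 150 private alleles
per strain. Real species carry tens of thousands of SNV sites of which a
small fraction is private; the simulator uses fewer sites with a
proportionally larger private fraction so that marker counts land in the
same regime as real data relative to the >100 marker-position filter
(~120–150 usable markers after coverage loss at 20x) while matrices stay
small. Drift is modeled as whole-strain replacement rather than per-site
mutation because the observed near-binary pattern of longitudinal
similarity (either high or near zero) is the signature of replacement;
within-host mutation accumulation is out of scope.

What the simulator does **not** emulate: sequencing error (absence calls
are only miscalled through coverage, never through error reads),
recombination and selection, within-host evolution beyond replacement,
batch effects between cohorts, and compositional covariation between
species. Passing tests therefore demonstrate the correctness and
calibration of the marker algebra under the stated generative assumptions
— not that real cohorts satisfy those assumptions.

## Numerical and edge-case choices

- Age groups partition \([0, \infty)\) with left-closed, right-open
  day boundaries: 7 (one week), 183 (six months), 730, 3652, 9131 days;
  the day-level constants are conventions chosen for determinism.
- Both filters are strict: similarity must exceed 0.2 and marker
  positions must exceed 100.
- The zero-coverage rule (similarity := 0) takes precedence over the
  undefined rule.
- The presence floor `min_freq = 0.05` is configurable; it guards
  against read noise and matches the observation layer's detection
  threshold.
- Reference populations are recomputed for every pair; the shared
  presence index in `sharing_table()` is an algebraic rewrite (per-family
  presence counts), proven equal to the pair-by-pair definition in the
  test suite, not a cache that could leak family samples.
- Degenerate inputs reject loudly: all-zero coverage compositions,
  constant predictors, empty reference populations, fewer than two
  groups; beta-regression non-convergence warns with diagnostics.

## Problem sizes used in validation

The packaged experiments run at desk scale: null calibration uses 100
background individuals plus 20 families (~1250 unrelated pair-species
comparisons); seeding detection uses 50 vaginal families over 5 species;
drift recovery pools four replicate cohorts of 125 adults sampled three
times (about 5000 interval records). These sizes put Monte-Carlo noise
well below the margins being tested while keeping each simulated SNV
matrix modest.
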