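---
title: "Outline morphometrics and QTL mapping of posterior lobe shape: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outline morphometrics and QTL mapping of posterior lobe shape: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lobeqtl)
```

This vignette is the package's own account of its science: the models
it implements, the assumptions behind them, the parameters that matter,
and the design decisions taken where the design was genuinely open.

## The trait and its measurement

The posterior lobe of the *D. melanogaster* male genital arch varies
strikingly between strains but offers no repeatable landmarks, so shape
is measured from the traced outline.  An open trace is closed through an
*artificial baseline* (the segment joining its two endpoints, where the
lateral plate meets the lobe), rotated so the baseline is horizontal,
mirrored if necessary so all outlines share clockwise handedness, and
translated so the *area centroid* of the closed polygon sits at the
origin.  The area centroid (rather than the vertex mean) makes the
origin robust to the uneven vertex spacing of manual-style traces.
Standardization is idempotent and invariant to rotation, translation
and mirroring of the input, which the test suite asserts at 1e-9 on
unit-scale fixtures.

### Elliptic Fourier analysis

The x- and y-projections of the standardized outline are treated as
independent periodic functions of contour length and expanded in a
Fourier series (Kuhl–Giardina).  The package treats the polygon as
exactly piecewise linear in chord length, for which the Fourier
integrals have a closed form; `n` harmonics yield `4n` descriptors
(`a_i, b_i, c_i, d_i`), and the default `n = 25` gives the
100-coefficient representation used for all shape analyses.  Two
deliberate choices:

* the constant (DC) terms are computed but excluded from the
  descriptor, because outlines are centroid-centered beforehand;
* no size, rotation or phase normalization is applied — outlines are
  already in a standard configuration, and normalization would discard
  genuine shape signal.

One numerical subtlety is worth recording.  Under the contour-length
parameterization, an eccentric ellipse is *not* a pure first harmonic:
arc length accumulates non-uniformly around the curve, so `x(s)`
carries genuine odd harmonics.  For the 2:1 ellipse the arc-length
quadrature oracle used by the tests gives first-harmonic coefficients
(1.8284, 0, 0, 1.0730) and a third harmonic of (0.1289, 0, 0, 0.0893);
the implementation is required to match that oracle to 1e-3, and its
round-trip reconstruction error (L2, against the chord-parameterized
curve) must be nonincreasing in the harmonic count — the Fourier
partial-sum property.  A circle, whose arc length is uniform, does come
out as the pure unit first harmonic.

### Shape space and size metrics

The descriptor matrix enters an ordinary centered, unscaled PCA.  Signs
of principal components are arbitrary, so each component is flipped, if
needed, to give a designated reference outline a nonnegative score; the
pipeline uses a rendered Sam-parent outline as the reference, which
makes higher `mPC1` mean a more Sam-like (squatter) lobe and fixes the
negative `mPC1`–H:W correlation the analysis expects.  Height and width
are total chord lengths of the vertical and horizontal lines through
the centroid (summed over crossings for non-convex outlines), area is
the shoelace area of the closed polygon — the region bounded by the
baseline is included, a convention the file formats document.

## The synthetic data generator

The generator is first-class, tested code: it defines the conditions
under which every downstream claim is checked.

**Crosses.**  Individuals carry run-length-encoded founder haplotypes.
Female meiosis places a Poisson(`L`/100) number of crossovers uniformly
on each chromosome (Haldane model, no interference — matching the map
function used by the estimators, so oracle equivalences are exact in
expectation); male meiosis transmits intact chromosomes; sons receive
their X from their mother.  Map positions are therefore female-meiosis
cM.  The F1 pool mixes reciprocal crosses (a son's X is either founder
allele with probability 1/2); no parent-of-origin effects are modeled,
consistent with the reciprocal F1 males' similar phenotypes.  The AIL
runs at a constant census (default 500, halved by sex) with random
union of gametes for 15 generations after the F2; the study reports
only "high census size", and 500 keeps drift modest at desk scale.
Viability selection is rejection sampling at zygote formation; the
default pipeline emulates the observed F17 X-chromosome and 3R-telomere
allele-frequency skew with relative fitness 0.7 against Sam genotypes
at one X and one 3R locus — mildly deleterious Sam alleles being the
standing hypothesis for that skew; the true loci and strengths are
unknown and configurable.

**Phenotypes.**  The latent shape score of an individual is
`sum(a x + d z)` over QTL (`x` = −1/0/+1, `z` = 0/1/0) plus 2×2
cross-product epistasis, plus noise.  The default architecture places
Q1 at 2L (28 cM), Q2 at 3L (30 cM) and Q3 over the chromosome-3
centromere (47.5 cM) with the reported additive/dominance effects
(4.51/6.76, 6.02/1.07, 9.61/1.27) and an additive-by-additive Q1:Q2
coefficient of 9.0, chosen so the interaction's share of genetic
variance matches the reported drop-one decomposition (5.5 of 29 parts).
The residual SD is set from the unlinked Hardy–Weinberg identities
(`Var(x) = 1/2`, `Var(z) = 1/4`, `Var(x_i x_j) = 1/4`) so the genetic
variance fraction is 26.5%.  Two per-lobe scores share the genetic
value and an individual-level noise component; the split between shared
and lobe-specific noise is solved from the *realized* genetic variance
so the phenotypic left–right correlation hits its target (default
0.85).  One side per individual is drawn at random as the mapped score.

**Outlines.**  A template (an ellipse with a diagonal bulge that leaves
the axis intercepts exact) is stretched by `(1+s)` in height and
`1/(1+s)` in width, with `s` affine in the latent score and calibrated
so the two parents measure at H:W 1.08 and 0.70; the reciprocal scaling
preserves area to O(s²).  Coordinate jitter emulates tracing noise.
What the generator does *not* emulate: vial/replicate environmental
structure, image segmentation artifacts, asymmetric lobe deformation,
or genotyping error beyond the HMM's ε.  Passing tests therefore
validate the estimators under the stated genetic model, not the
robustness of the morphometrics to real imaging noise.

## QTL machinery

**Map estimation.**  Adjacent-pair recombination fractions by EM for an
intercross (missing genotypes drop out of the pairwise likelihood,
which is exact because the single-marker margin does not depend on
`r`), hemizygous male X pairs by direct counting, conversion by the
inverse Haldane function.  Marker order is never re-estimated.  Because
only females recombine but the estimator is the standard symmetric
intercross one, the estimated F2 autosomal map is about half the female
map — exactly what happens when such data are run through standard
mapping software, and immaterial for the F17/F2 expansion *ratio*,
where the convention cancels.  Adjacent fractions at or above 0.5 are
capped at 0.49 (with a warning); in a deep AIL, distant marker pairs
reach this cap, which makes the expansion ratio conservative at the cap
rather than divergent.  The F17 is deliberately analyzed as an
intercross on its own re-estimated, expanded map — mirroring standard
practice — rather than with generation-specific AIL transition
probabilities, which are out of scope; the approximation affects cM
scale, not marker order or peak identity.

**HMM and imputation.**  Genotype classes follow a Markov chain along
each chromosome (autosomes: two independent haploid chains, three
classes; male X: one chain, two classes) with Haldane transitions,
emission `1 − ε` for the observed class (`ε` split over the others,
default `ε` = 1e-4), and uniform emission at missing genotypes.
Imputations are whole-chromosome posterior path draws (forward
filtering, backward sampling) — never independent per-position draws.

**Scans.**  At each grid position (default step 1 cM; markers always on
the grid) each imputation contributes the likelihood ratio of the
single-locus regression (additive + dominance on autosomes, additive
only on the male X), and `LOD = log10(mean LR)`, computed stably in
logs: averaging on the likelihood scale is the correct way to combine
imputations, and at a fully typed marker with `ε = 0` the combined LOD
equals the closed-form regression LOD `(n/2) log10(RSS0/RSS1)` to 1e-6
(an acceptance oracle).  CIM selects marker covariates by forward
selection on RSS (the covariate-selection rule is not specified by the
source analysis; forward selection is the natural greedy choice) and
drops covariates within half a window (default 10 cM) of the test
position from both null and full models.  Permutation thresholds use
the `ceiling((1−α)P)`-th order statistic of the permuted genome maxima
(ties resolve toward the larger, conservative value), with separate X
and autosome scopes; under selective genotyping the permutations are
stratified within the genotyped and ungenotyped subsets.

**Selective genotyping.**  The analysis keeps *all* phenotyped
individuals, with non-tail genotypes recorded as missing: their
imputations are prior draws, which preserves test validity (type-I
error is calibrated — an acceptance check at 400 null replicates) while
sacrificing efficiency.  A consequence documented here because it
shapes one acceptance outcome: per-imputation OLS on prior-draw
genotypes *attenuates* effect and variance-explained estimates, and
likelihood reweighting across imputations cannot repair this (with 250
ungenotyped individuals the weights degenerate).  At the study design
(26.5% generative variance, 47 + 47 of 344 genotyped) the median fitted
total variance explained is ~21–22% rather than 26.5%, while the same
estimator under full genotyping recovers the realized generative
fraction.  The realized F17 fraction itself sits near 31% rather than
26.5%, because the two linked chromosome-3 QTL (17.5 cM apart) retain
residual F2 linkage disequilibrium after 15 generations — the unlinked
calibration identity cannot hold exactly in the linked design.  The
classic upward bias the study cautions about (overestimation at low
sample size) appears when the fit conditions on the genotyped tails
only, and the test suite demonstrates exactly that contrast.

**Model fitting.**  The joint model regresses the phenotype on all
locus codings plus, per epistatic pair, the four cross-products of the
additive/dominance codings; estimates are averaged over imputations
weighted by each imputation's profile likelihood.  Variance attribution
is drop-one and hierarchical (dropping a QTL drops its interactions),
so per-term percentages can exceed or undershoot their sum relative to
the total under linkage; no renormalization is applied.  2-LOD support
intervals are the maximal contiguous grid run containing the peak with
LOD ≥ peak − 2; endpoints are the last grid positions still above the
threshold, not expanded to the flanking below-threshold positions (on a
triangular profile with unit slopes the 2-LOD interval is exactly the
apex ± 2 cM).  A profile that never drops below the threshold flags the
whole chromosome.

**Candidate test.**  The observed sum of scan LODs at `k` candidate
positions (snapped to the autosomal grid; the X is excluded) is
compared with `N` null sums over sets of `k` distinct positions drawn
uniformly over grid points (default) or uniformly in cM (a flag —
whether the original procedure sampled markers, grid points or
uniform locations is unstated), with
`p = (1 + #{null ≥ obs}) / (N + 1)`.  The shipped candidate table
carries the 22 real gene names at *synthetic* standard-map positions,
because the source analysis does not print its coordinates.

## Parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `harmonics` | 25 | EFA harmonics; 4 × 25 = 100 descriptors |
| `M` | 256 | imputations per scan |
| `P` | 1000 | permutations per threshold |
| `alpha` | 0.05 | significance level |
| `step` | 1 cM | scan grid step |
| `window`, `n_covariates` | 10 cM, 4 | CIM settings |
| `tails` | 47 | per-side selective-genotyping count |
| `N_resample` | 1e6 | candidate-test null sets |
| `census` | 500 | AIL census per generation |
| `error_prob` | 1e-4 | HMM genotyping error rate |

## Problem sizes used by the test suite

Stochastic checks run at sizes chosen to give stable Monte-Carlo
verdicts in a desk-scale run: segregation ratios at n = 10,000;
effect-recovery identities as means over five n = 5,000 F2 replicates;
permutation calibration over 400 null replicates at P = 200 (the
threshold machinery is identical at P = 1000 — only the quantile's
Monte-Carlo error changes); the full study-design recovery at 20
replicates of n = 344 with M = 128 imputations (M = 256 gives the same
medians); and the map-expansion check at the study's full sizes over
five seeds.  The demonstration pipeline (`demo_config()`) shrinks
population sizes and resampling counts so the complete chain runs in
seconds; `run_config()` holds the full-scale defaults.

## Known limitations

* AIL transition probabilities are approximated by intercross ones on
  the re-estimated expanded map; absolute cM on that scale should be
  read comparatively, not literally.
* The selective-genotyping fit attenuates absolute effect sizes (see
  above); detection, thresholds and intervals remain valid.
* The morphometrics assume simple (non-self-intersecting) traced
  outlines; self-intersection is detected and flagged, not repaired.
* No environmental (vial/replicate) variance structure is simulated,
  and the X-skew emulation is a one-parameter stand-in for an unknown
  selective history.
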