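---
title: "Models and methods behind heterochiasma"
author: "heterochiasma authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind heterochiasma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterochiasma)
```

## The experimental design the package models

A backcross of an F1 hybrid to one of its parents exposes, in every
progeny plant, exactly one gamete of the F1: at each marker the plant is
either homozygous for the recurrent parent (`A`) or heterozygous (`H`),
and every `A`/`H` switch along a chromosome marks one crossover (CO) in
the F1 meiosis that produced the gamete.  Scoring ~1,500 plants at ~380
SNPs, with the F1 used once as male and once as female parent, gives
sex-specific genome-wide CO landscapes for a species such as
*Arabidopsis thaliana*.  The package implements the full analysis chain
for such data, and a generative simulator so every estimator can be
validated without any external data set.

## Crossover placement: the stationary gamma renewal model

Genetic length is defined so that a gamete carries 1 CO per Morgan on
average; a bivalent (the four-chromatid pairing of two homologs) carries
2 per Morgan.  The gamma model states that inter-CO distances on the
bivalent, in genetic coordinates, are i.i.d. Gamma with shape $\nu$ and
rate $2\nu$, hence mean spacing $1/2$ Morgan.  $\nu = 1$ is the
memoryless (Poisson) case of no interference; $\nu > 1$ makes close
double COs rare, which is what crossover interference means
operationally.  For integer $\nu$ the model is the counting model with
$m = \nu - 1$ intermediate events.

The simulator starts each bivalent in the *stationary* (equilibrium)
state: the distance to the first CO follows the forward-recurrence
density $S(x)/\mu$ of the gap distribution.  With a stationary start the
expected CO count on *any* sub-segment of length $\ell$ is exactly
$2\ell$, so simulated genetic length equals nominal genetic length —
the same convention under which the likelihood below is derived.  A
fixed-origin start would bias the count near the left telomere.

Each bivalent CO involves two of the four chromatids, so a given gamete
inherits it with probability $1/2$, independently ("thinning").  No
chromatid interference and no gene-conversion tracts are modelled.

```{r simulate, eval = FALSE}
sp <- chromosome_spec("chr1", genetic_length = 1.4236,
                      physical_length = 30.4e6,
                      marker_positions = round(seq(1, 30.4e6, length.out = 97)))
pop <- simulate_backcross(sp, n_plants = 1505, model = gamma_model(nu = 2.6),
                          missing_rate = 0.02, error_rate = 0.001, seed = 1)
```

The genetic-to-physical map is linear (uniform cM/Mb) by default, but a
piecewise-linear profile can be supplied to emulate the end-loaded male
maps seen in real data; the analysis stages never assume uniformity, so
the simulator must be able to break it.  Chromosomes are simulated
independently (the model is fitted per chromosome, so cross-chromosome
structure would never be exploited).  All randomness flows from one
master seed, with per-chromosome substreams derived deterministically.

## Map estimation

For adjacent markers the recombination fraction is $r = N_r/N$ over the
$N$ plants with data at both markers, with standard error
$\sqrt{r(1-r)/N}$ and normal 95% bounds; Haldane's map function
$d = -\tfrac12\log(1-2r)$ converts to distance.  Two chromosome-length
estimators are provided:

* **interval sum** — add the Haldane lengths of all adjacent-marker
  intervals;
* **crossover counting** — count each plant's genotype switches along
  its non-missing call sequence and average.  Missing calls are
  transparent: a CO bracketing a missing marker is still seen.  A double
  CO hidden entirely inside a missing run is necessarily uncounted; this
  is documented behaviour, not corrected.

On complete data the two agree to within the Haldane correction (the
interval sum is larger by $\approx \sum_i r_i^2$, the parity-loss
adjustment).  The estimator variance of the counting method is the
per-plant CO-count sample variance over the number of plants, and
male/female length ratios get Gaussian intervals by summing relative
variances.  Truncation analyses (removing 30% or 50% of the physical
length, half per end, dropping every interval overlapping the removed
regions) and the per-class CO-loss bookkeeping reproduce the standard
end-effect diagnostics; under interference the multi-CO gametes lose
proportionally more of their COs to truncation because their COs sit
closer to the chromosome ends.

## Segregation distortion and its correction

Under the 1:1 backcross null, the frequency of the recurrent allele at a
marker lies in $0.5 \pm 2.33\,s$ with $s^2 = 1/(4(N_C+N_L))$; markers
outside the band are flagged.  (The cut 2.33 is the one-sided 1% normal
point, so the two-sided null exceedance of the band is close to 2%; the
calibration test asserts the exact binomial rate.)

Gametic selection at a single locus rescales recombinant and
non-recombinant classes equally, so single-locus distortion leaves
recombination fractions unbiased.  Two selected loci $L_1 < L_2$ with
retention probabilities $s_1, s_2$ (product $s_1 s_2$ when both
unfavored alleles are carried — no epistasis) do distort intervening
intervals.  For each interval $(M_i, M_{i+1})$ between the loci, the 16
four-locus genotype classes have Haldane-model frequencies determined by
the three spanning recombination rates, reweighted by the selection
coefficients and re-normalized.  The inner fit recovers the three rates
by Pearson chi-squared minimization (box-constrained, started from the
naive pairwise fractions); the outer fit minimizes the summed chi-squared
over $(s_1, s_2)$ on a coarse grid refined by Nelder–Mead (the inner
optimizer is L-BFGS-B, which is not reentrant, so the outer search must
not use it).  When a marker coincides with a selected locus the class
set collapses from 16 to 8 (or 4) and the machinery handles the smaller
simplex directly.  Corrected rates replace naive ones only between the
loci; outside, the single-locus argument applies and naive estimates are
kept byte-identical.  For opposite-parent selection the induced bias on
the inter-locus length is a small *inflation* (about +2.4% for the
geometry in the tests), which the correction removes.

## Interference estimation from gamete data

Thinning a stationary renewal process with retention $p = 1/2$ yields
another stationary renewal process whose gap density is the geometric
mixture

$$g(x) = \sum_{j \ge 1} p\,(1-p)^{j-1}\,\Gamma(x;\, j\nu,\, 2\nu),$$

with mean 1 Morgan.  For a gamete with ordered COs $x_1 < \dots < x_k$
on $[0, L]$ the likelihood is
$h(x_1)\,\prod_i g(x_{i+1}-x_i)\, S_g(L - x_k)$, where
$h(x) = S_g(x)$ is the stationary first-event density and $S_g$ the gap
survival; a zero-CO gamete contributes the equilibrium survival
$1 - \int_0^L S_g$.  All terms close in regularized incomplete gamma
functions (the survival integral of a Gamma is itself a pgamma
expression), so no quadrature is involved; the mixture is truncated when
the geometric tail drops below $10^{-12}$ (40 terms), and doubling the
truncation changes no log-likelihood by more than $10^{-8}$.

$\hat\nu$ maximizes the log-likelihood over $[0.05, 50]$ on the log
scale; the 95% interval is the profile-likelihood set
$\{\nu : \ell(\nu) \ge \ell_{max} - 1.92\}$.

### Marker data: placement and hidden-pair censoring

Marker data localize each CO only to its bracketing informative
interval, and — more importantly — hide any CO *pair* falling inside a
single interval (genotype parity is unchanged).  Two choices address
this:

* **placement** — each switch is placed uniformly at random within its
  bracketing interval (the exact conditional law of one CO under the
  Poisson null), rather than at the midpoint; midpoints impose an
  artificial floor on observable gaps.
* **censoring correction** — the likelihood multiplies each gamete's
  contribution by $1 + \bar F(\Delta)\, R$, the first-order probability
  of one unobserved tight pair anywhere along the chromosome:
  $\bar F(\Delta)$ is the mean probability that a CO's partner lands in
  the same marker interval of width $\Delta$, and $R$ integrates the
  pair's location in closed form (interior gaps via the two-gap
  convolution $g \ast g$, the flanking and zero-CO segments via the
  matching survival integrals).

The correction vanishes as markers densify or interference strengthens.
Measured at $\nu = 1$ with 50 markers on 1.4 Morgans and 2000 gametes,
the mean fitted shape is 1.20 uncorrected at midpoints but 1.01 with
uniform placement and the correction; at the study's marker density the
calibration run in the test suite covers $\nu = 1$ with the profile
interval in 25/25 replicates.  Poisson-null goodness of fit of CO-count
classes (0, 1, 2, 3+) uses Pearson chi-squared with the mean estimated
from the data (classes − 2 degrees of freedom) and tail classes pooled
to expected counts of at least 5; the exact statistic behind such
reported p-values is rarely stated, so the pooled chi-squared is this
package's documented choice.

## Features, hot/cold intervals, and scaling

Heterochromatin is inferred from euchromatic histone-mark presence
(H3K4me3/H3K27me3-like) averaged in 2 kb windows: an interval is
heterochromatic when its overlap-weighted mean presence is strictly
below 0.2.  Arm mean CO rates weight each euchromatic interval by its bp
span; an interval is *hot* (*cold*) when its 95% rate interval lies
entirely above (below) its arm mean — under homogeneity about 5% of
intervals are flagged, by construction.  Male/female interval
comparisons use the two-proportion normal test by default (Fisher's
exact optionally) with Benjamini–Hochberg control at $q = 0.05$ applied
genome-wide.  Rate–feature association is ordinary least squares on
euchromatic intervals; feature tracks are consumed as supplied tables
(no sequence or annotation parsing), and the synthetic generator builds
them with centromere-to-telomere gradients (GC and gene density up, TE
density down, CpG flat) so the positional-confounding analysis has the
structure it probes.

Chromosome-size scaling fits the obligate-CO threshold model
$L_G = 0.5 + a\,(L_{Mb} - L_{thr})$ by weighted least squares, with
per-chromosome weights the inverse variances of the length estimates;
the zero-threshold special case is the Li–Freudenberg model, tested by
the weighted chi-squared at its one-parameter fit.  Synaptonemal-complex
lengths enter as a plain numeric size column reusing the same fits.

## Numerical and design choices

* Equilibrium first-gap sampling inverts the closed-form CDF
  $2xS(x;\nu) + F(x;\nu+1)$ on a cached 8193-point grid (CDF error
  $\sim 10^{-7}$).
* Chi-squared class weights are Pearson (expected counts); an expected
  zero with a positive observation rejects the parameter point.
* The genotype QC flags singletons (calls disagreeing with two
  concordant informative neighbors); flags are reported, not silently
  removed — genotyping errors masquerade as tight CO pairs and would
  bias interference estimates downwards if left in.
* Problem sizes in the test suite are chosen to keep each property
  informative at desk scale: populations of 150–2,000 plants, 25–200
  replicate seeds per calibration, $10^4$–$10^5$ draws for Monte-Carlo
  oracles.

## What the simulator does and does not establish

The generator reproduces the statistical structure the estimators
assume: stationary gamma placement, binomial thinning, two-locus gametic
selection, i.i.d. call dropout and flips, and smooth feature gradients.
Real data add marker-order errors, locally varying error rates,
segmental duplications confusing clusters, NOR regions without markers,
and interference that need not follow a gamma law.  Green tests
therefore certify the estimators *under the model*, plus the documented
robustness checks (missing-data transparency, truncation behaviour);
they cannot certify the gamma model itself on any real population.

## Limitations

* At most two selected loci per chromosome; no epistatic selection.
* No two-pathway (interfering + non-interfering) CO mixture; the single
  gamma pathway only.
* Marker order is taken as given; no multipoint map ordering.
* The hidden-pair correction is first order: configurations with two or
  more censored pairs in one gamete are ignored (negligible at the
  marker densities the design targets).
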