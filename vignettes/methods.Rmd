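---
title: "Calibrating the per-generation mutation rate against the recombination map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating the per-generation mutation rate against the recombination map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetrelax)
```

## The idea

At every site of a diploid genome the two chromosome copies have a time to
most recent common ancestor (TMRCA) $T$, and the genome decomposes into
blocks of constant $T$ separated by ancestral recombination events.  A block
of age $T$ and length $L$ carries $2T L \mu$ heterozygous sites in
expectation, and its expected length is $(2 T r)^{-1}$, so the expected
number of heterozygous sites per block is $\mu / r$ regardless of age.
Because fine-scale recombination maps of the human genome are far more
precisely known than the mutation rate, this ratio can be inverted: observe
how much heterozygosity accumulates per unit of *genetic* distance, and read
off $\mu$.

Block boundaries cannot be observed directly, so the package uses an
indirect statistic.  Tile the genome with 100-kb windows, and ascertain as
*starting points* the midpoints of windows whose heterozygosity lies in a
narrow low range $S$ (by default 5--10 heterozygous sites per 100 kb of
unmasked sequence, with at least one site in each half-window).  Such
windows descend from recently coalesced blocks.  The statistic $H_S(d)$ is
the average heterozygosity of unmasked sites at genetic distance $d$ (in cM,
both directions pooled) from the starting points, computed in 60 half-open
bins over $(0, 0.1]$ cM; the anchor $H_S(0)$ is the pooled heterozygosity of
the ascertained windows themselves.  As $d$ grows, the probability of having
crossed an ancestral recombination rises and $H_S(d)$ relaxes from $H_S(0)$
toward the genome average $\bar H$.  The *rate* of that relaxation is set by
the typical starting TMRCA --- that is, by $H_S(0)/2\mu$ --- so at fixed
$H_S(0)$ a larger $\mu$ means younger blocks, fewer recombinations per cM,
and a lower, slower curve.

$H_S(d)$ has no useful closed form: successive block TMRCAs are not
independent, not even Markovian, because distant lineages interact inside
the ancestral recombination graph (ARG).  Inference is therefore fully
simulation-based: calibration data are simulated under the sample's
demography at known rates $\mu_c$ (by default $\{1, 2, 4\}\times 10^{-8}$),
pushed through the *same* ascertainment and curve computation, and the
observed curve is interpolated within the calibration family by a natural
cubic spline across $\mu$ at each bin, with a variance-weighted
least-squares fit over $\mu$ (dense grid plus golden-section refinement,
absolute tolerance $10^{-11}$).

## The coalescent engine

No suitable non-Markovian coalescent simulator is available to R, so the
package implements one (in C++): Hudson's back-in-time algorithm for the two
lineages of a diploid sample, realising the full ARG --- trapped
non-ancestral material recombines, and lineages far apart on the sequence
can coalesce --- under a piecewise-constant demography and an arbitrary
piecewise-linear genetic map.  Rates per generation are: crossover
recombination at the genetic length spanned by a lineage's ancestral
material; optional non-crossover gene conversion initiating at
$c/\ell$ per base ($c$ = probability a base is covered by a tract per
generation, $\ell$ = mean tract length, tracts exponential); coalescence at
$1/2N(t)$ per within-population pair.  A two-population variant (lineages
assigned to demes with an admixture fraction, demes merging at a split
time) supports the admixture scenario.  The engine emits the TMRCA block
partition; heterozygous sites are then placed as a Poisson process at
$2T\mu$ per base.  Tests validate the single-site TMRCA distribution under
bottleneck histories, the $\theta$ expectation, the $\mu/r$ block law, and
embedded-versus-isolated (projectivity) consistency.

Demographies are stored in coalescent scaling, exactly as PSMC reports them
(`theta` $= 4 N_0 \mu$, epoch times in units of $2 N_0$ generations,
relative sizes $\lambda$); a PSMC output parser is provided.  Realizing a
scaled history at a calibration rate $\mu_c$ sets $N_0 = \theta / 4\mu_c$,
which automatically enforces $\rho = \theta r / \mu_c$: diversity and the
mutation/recombination ratio, the two quantities the curve shape encodes,
are both preserved.

## Genetic-map error

$H_S(d)$ is measured on a published base map, which carries error.  Rather
than correcting distances, the calibration *matches* the error: each
interval of the base map with observed genetic length $g$ and physical
length $p$ is replaced by a gamma draw
$Z \sim \Gamma(\alpha\,\gamma(g + \pi p),\ \alpha)$, so $E[Z] = \gamma(g +
\pi p)$ and $\mathrm{var}(Z) = E[Z]/\alpha$.  The accuracy parameter
$\alpha$ (default 3100 M$^{-1}$, SE 300; simulation studies use 3000) has a
direct reading: $1/\alpha \approx 0.03$ cM is the interval length at which
the map's coefficient of variation reaches 1.  The pseudo-count prior
$\pi = 0.09$ cM/Mb spreads a small uniform rate over the grid because very
short map intervals are systematically underestimated (an interval with no
observed crossovers need not truly have zero length), and
$\gamma = G/(G + \pi P) < 1$ (computed genome-wide) preserves the total map
length in expectation.

Two design choices here deviate from the most literal reading of the
procedure and deserve their own justification:

* **Per-replicate perturbation.**  Map error enters through *ascertainment*
  as well as distance: a window whose local map rate drew low is both more
  likely to land in a narrow low-heterozygosity band and slower to relax
  around in base-map coordinates.  Real data realize this selection across
  many regions of one unknown true map.  A single shared perturbed map per
  calibration reproduces it only in the limit of many regions; at the
  reduced scales this package targets, the calibration instead draws a
  fresh gamma realization of each region's intervals for every simulated
  replicate, which integrates the error model into the conditional
  ensemble exactly at any region count.  Averaging repeated calibrations
  (25 for real data) retains its role of damping residual randomisation
  noise.
* **Region-equal pooling.**  The observed curve counts every ascertained
  region exactly once, so the calibration averages its accepted replicates
  *within* each region before pooling.  Pooling raw accepted replicates
  would weight regions by their conditional acceptance probability, which
  varies several-fold across a heterogeneous map and correlates with local
  curve shape; on synthetic data this distorted the calibration curves by
  up to ~10% at small $d$.

## Calibration, fitting and uncertainty

For each starting point a *super-region* is laid out: the minimal physical
span whose genetic flank on the base map is at least 0.1 cM on both sides of
the midpoint (full ARG simulation of whole chromosomes is impractical, and
0.1 cM is all the statistic needs).  Each super-region is simulated
independently at each grid rate, batched adaptively until a target number of
replicates (default 4) pass the ascertainment rule applied to the central
window, within a per-rate cap --- lower rates get wider caps because their
conditional acceptance is lower (stronger recombination averages window
heterozygosity toward the mean, thinning the extreme band).

Because demographic reconstruction is never perfect, each calibration
curve's relaxation portion is rescaled by the ratio of real to simulated
super-region heterozygosity, $H'(d) = H_S(0) + (H(d) - H_S(0))\,
\bar H_{\mathrm{real}}/\bar H_{\mathrm{sim}}$, leaving the intercept
untouched; the correction is expected small and a ratio outside $[0.5, 2]$
warns.  Calibration curves (never the observed one) are smoothed along $d$
with a site-count-weighted spline (df = 10): the underlying curve is smooth,
and unsmoothed simulation noise --- whose size varies systematically across
the $\mu$ grid --- both inflates fit variance and tilts weighted least
squares toward the least-noisy curve.

Fit weights are reciprocal per-bin variances of the observed curve.  The
variances come from a leave-one-chromosome jackknife, stabilized through a
one-parameter model $\mathrm{var}_d = \phi\, H_d / n_d$ (binomial sampling
variance times a common overdispersion factor, $\phi$ estimated as the
median ratio): with tens of chromosomes raw and stabilized weights agree,
but with the handful of chromosomes of a reduced run the raw reciprocal
variances would concentrate the fit on whichever bins drew small variances
by chance.  The $d=0$ anchor is excluded from the sum (ascertainment fixes
it in both data sets).  An extrapolation guard rejects fits where the
observed curve leaves the calibration envelope (with two per-bin standard
deviations of slack --- a matched curve still leaves the raw min/max
envelope of a few noisy curves in about half the bins by exchangeability).

Uncertainty is a weighted delete-one-chromosome jackknife (blocks weighted
by starting-point counts): each replicate recomputes the observed curve and
the asymptote adjustment and refits against the same calibration
simulations, with the same demographic history throughout.  Map-accuracy
uncertainty is propagated by rerunning the inference over an $\alpha$ grid
(2500--4500 by default) and multiplying the regression slope of
$\hat\mu$ on $\alpha$ by the SE of $\alpha$; smaller $\alpha$ smooths the
calibration curves' relaxation (a concavity effect), so $\hat\mu$ increases
with $\alpha$.  All error components --- jackknife, $\alpha$, and the three
corrections below --- combine as a root sum of squares under an
independent-normal assumption.

## Corrections

Three post-fit corrections are applied in a fixed order:

1. **Genotype error (multiply).**  False heterozygotes inflate $H_S(0)$
   without changing the relaxation rate, so the raw fit overstates $\mu$ by
   the observed-to-true starting-heterozygosity ratio; multiply by
   $(H_S(0)-\epsilon)/H_S(0)$.  On real data $\epsilon$ is estimated from
   CpG dilution: CpG transitions are roughly an order of magnitude more
   mutable than other sites, hence over-represented among genuine
   heterozygotes but not among errors, and the mixture deconvolution
   $\epsilon = H_S(0)(f_{\mathrm{true}} - f_{\mathrm{obs}})/
   (f_{\mathrm{true}} - f_{\mathrm{err}})$ recovers the error rate from the
   depressed CpG fraction near the starting points.  Simulated data carry
   no nucleotides, so simulation studies count the injected errors in the
   ascertained windows directly.
2. **Non-crossover gene conversion (subtract).**  Conversion copies ~100-bp
   tracts between homologues and introduces heterozygosity into young
   regions at rate $c \cdot r_{\mathrm{local}}/r_{\mathrm{genome}} \cdot
   (\bar H - H_S(0))/2$ per base per generation ($c = 5.9\times10^{-6}$,
   95% CI $4.6$--$7.4\times10^{-6}$): the probability of being covered by a
   tract, adjusted for the test regions' local crossover rate, times the
   probability the copied-in base differs --- the excess of genome-average
   over test-region heterozygosity, halved because the tract copies one of
   the two donor haplotypes.  At realistic inputs this is
   $0.13$--$0.17\times10^{-8}$.
3. **Base content (multiply).**  Ascertained regions may differ from the
   filtered genome in composition; a relative-mutability score
   $M = 1 + \beta_{\mathrm{CpG}} f_{\mathrm{CpG}} + \beta_{\mathrm{GC}}
   f_{\mathrm{GC}} + \beta_{\mathrm{int}} f_{\mathrm{CpG}} f_{\mathrm{GC}}$
   converts the regional rate to a genome-wide equivalent via
   $M(\mathrm{genome})/M(\mathrm{regions})$.  The default coefficients give
   CpG sites roughly tenfold mutability and a mild GC effect; they are
   configuration, not inference.

A class mode splits heterozygous sites into CpG transitions (reference
context CG) versus the rest, with its own ascertainment ranges
($S = 0.1$--$2$, i.e. a single site per window, half rule off, and
$S = 4.375$--$8.75$), a lowered calibration grid
($\{0.2, 0.4, 0.8\}\times10^{-8}$ for CpG), class-scaled error rates and a
0.09/0.91 split of the gene-conversion correction.

## The synthetic-data generator

`scenario_genomes()` is first-class, tested code that defines the study
conditions: 20 diploid genomes at full scale (4 at desk scale) with true
$\mu = 2.5\times10^{-8}$, an ancestral diploid size of 10,000 outside a
10$\times$ bottleneck 1000--2000 generations ago (the age structure that
makes low-heterozygosity windows abundant in non-African genomes), a
hotspot-punctuated synthetic base map (gamma background plus sparse
exponential hotspots, rescaled to 1.25 cM/Mb), and map error realized at
$\alpha = 3000$ M$^{-1}$, $\pi = 0.09$ cM/Mb.  The low-rate scenarios use
$\mu = 1.5\times10^{-8}$ with $N_0 = 16{,}666$, preserving
$\theta = 10^{-3}$.  Scenario extras: gene conversion at
$c = 5.9\times10^{-6}$ (tracts exponential, mean 100 bp), injected false
heterozygotes at 1 per 100 kb (1 per 150 kb in the combined scenario), a
log-normal window-level mutation-rate field (mean 1, CV 0.3 --- a stand-in
chosen in the absence of a published parameterisation), and a
two-population admixture history (split 3000 generations, fraction 0.5).

Two generator choices matter for interpretation:

* Chromosomes are simulated in genealogically independent chunks (2 Mb at
  desk scale; 1.25 Mb when gene conversion is on, whose short tracts
  inflate the ARG lineage count superlinearly with segment length);
  super-regions never span a chunk edge.  Correlations beyond these scales
  are irrelevant to a statistic confined to 0.1 cM.
* Each genome receives an **independent** map-error realization.  Real
  genomes share one true map; but with a shared realization and few
  genomes, a window ascertained in several genomes at once carries extra
  information about its local map draw that a per-region calibration
  cannot condition on --- measurably slowing the observed relaxation at
  small $d$ at desk scale.  Independent draws keep every per-genome
  marginal identical while making the test ensemble exactly the one the
  calibration integrates over.  This is a known limitation of what the
  desk-scale recovery demonstrates about real data, where the shared-map
  conditioning effect shrinks with the (much larger) number of regions and
  is partly absorbed by the error corrections.

What passing recovery tests does *not* show about real data: the generator
has no nucleotide composition (base-content and CpG machinery are tested on
labelled synthetic profiles), no sequencing-depth structure, no correlation
between map quality and base composition, and its demography is handed to
the calibration directly --- isolating the method's own accuracy from
PSMC's, whose output is consumed, never reimplemented.

## Scales, budgets and numerical choices

The `"paper"` profile mirrors the full study conditions (20 genomes, 25
trials, 30 simulated genomes' worth per calibration curve) and takes hours.
The `"desk"` profile --- 4 genomes, 12 chromosomes of 4 Mb, 5 trials,
adaptive calibration targeting 4 accepted replicates per region and rate
--- yields 200+ super-regions per trial and runs each scenario in one to a
few minutes on one CPU; the low-rate scenarios double the chromosome count
because the ascertainment band no longer coincides with the bottleneck
TMRCA mass and eligible windows thin out.  At desk scale the realized
trial-to-trial SD is roughly $0.5$--$1\times10^{-8}$ and the recovery
criterion is correspondingly coarse (two realized standard errors); the
argmin of a noisy objective over a family that flattens toward large $\mu$
is slightly right-skewed, which is visible as a small positive bias well
inside that tolerance.

Degenerate inputs are handled explicitly: regions of zero genetic length
are an error; zero-length map intervals receive $Z = 0$ unless the
pseudo-count applies; starting points whose flank would leave the map or
cross a chunk boundary are dropped with a warning and counted; trials that
ascertain nothing are recorded as failures, never silently dropped;
multi-allelic sites are masked (the method models biallelic
heterozygosity); ties in the coverage percentiles are kept on the
conservative (masking) side.
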