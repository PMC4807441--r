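---
title: "Characterizing hybrid zones: clines, disequilibria, hybrid indices and bimodality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing hybrid zones: clines, disequilibria, hybrid indices and bimodality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridzone)
```

## The scientific problem

When two differentiated taxa meet and interbreed, the transition zone
between them carries a characteristic genetic signature.  Two families of
questions recur in hybrid-zone studies:

1. **Cline shape.**  How does the frequency of a diagnostic allele change
   with position along the contact transect?  A cline maintained only by
   diffusion after secondary contact keeps widening; a cline held *narrower*
   than that neutral expectation implies selection.  Whether clines at
   different loci share a centre (coincidence) and width (concordance)
   distinguishes a genome-wide barrier from locus-specific forces.
2. **Genotypic structure at the centre.**  If hybrids reproduce freely, the
   distribution of per-individual ancestry (the hybrid index) at central
   sites is unimodal - a hybrid swarm.  If reproductive isolation removes
   F1s and backcrosses, the distribution is bimodal, with modes near the
   parental extremes.

The motivating system is the Atlantic killifish (*Fundulus heteroclitus*),
whose northern and southern subspecies meet along the New Jersey coast.
The package models that study design: 13 sites along a 1631-km coastal
transect (`killifish_transect()`), nine codominant microsatellite loci and
one diagnostic mitochondrial marker per individual, with all stages -
within-site disequilibrium statistics, cline fitting, admixture, hybrid
indices and the dip test - implemented over one `genotype_table`.

## Cline model and fitting

The cline in the composite northern-allele frequency is

$$p(x) = p_{min} + (p_{max}-p_{min})\,\frac{1+\tanh\!\big(2(x-c)/w\big)}{2},$$

with centre $c$ (km), width $w$ (km; the inverse of the maximal slope of
the scaled sigmoid) and end frequencies $p_{min} \le p_{max}$.  Four
variants are fitted: a flat null (1 parameter), variant I with the ends
fixed to supplied constants (2), variant II with free ends (4), and
variant III adding exponential introgression tails (8).  A tail replaces
the sigmoid beyond $c \pm \delta$ by an exponential whose slope at the
splice is $\tau$ times the sigmoid's, continuous there; $\tau \in [0,1]$
so tails only flatten, never steepen.

`fit_cline()` maximizes the binomial log-likelihood
$\sum_s [k_s \log p(x_s) + (n_s-k_s)\log(1-p(x_s))]$ ($p$ clamped to
$[10^{-9}, 1-10^{-9}]$; the binomial coefficient is a constant and is
omitted) by bounded multi-start L-BFGS-B rather than MCMC: at this problem
size (a dozen sites, up to eight parameters) a deterministic, seeded
optimizer is faster and exactly reproducible.  Internally the ends are
parameterized as $p_{min}=m$, $p_{max}=m+(1-m)s$ with $m,s\in[0,1]$, which
enforces the ordering without constrained optimization.  Width is
optimized on the log scale.  Default box: centre within the data range
widened by 200 km, width in $[1, 3000]$ km.

*Support limits.*  Uncertainty is reported as 2-unit support intervals:
the widest interval over which the profile log-likelihood (re-maximized
over the other free parameters, warm-started from the MLE) stays within 2
units of its maximum - roughly a 95% confidence interval.  Endpoints are
found by an expanding walk plus root bisection; intervals that hit a
parameter bound are flagged `clipped`.

*Model selection.*  Variants are compared by AIC ($2k - 2\log L$ with $k$
the number of free parameters); exact ties go to the simpler variant.

*Neutral width.*  `neutral_cline_width()` implements
$w = \sigma\sqrt{2\pi T}$, the width a purely diffusive cline attains $T$
generations after contact with dispersal $\sigma$ per generation.  For
post-glacial contact ($T = 15000$ generations, $\sigma = 2$ km) this gives
614 km; observed widths of tens of km are therefore strong evidence of
selection:

```{r neutral}
neutral_cline_width(T = 15000, sigma = 2)
```

*Concordance test.*  `concordance_test()` uses the scaled-logit shape
$p(x) = p_{min} + (p_{max}-p_{min})/(1+e^{-4(x-c)/w})$ (same
width-as-inverse-maximal-slope convention; kept distinct from the tanh
form because the two shapes are associated with different fitting
traditions) and compares a free model (per-locus $c, w$ and ends) with a
constrained one (shared $c, w$): $\chi^2 = 2\Delta\log L$ with $2(L-1)$
degrees of freedom.  The free fits include the constrained solution among
their starts, so the free likelihood can never fall below the constrained
one numerically.

## Within-site disequilibrium statistics

* **Exact HWE test** (`hwe_exact_test()`): conditional on allele counts,
  either by full enumeration of genotype tables (small samples; also the
  oracle for the test-suite) or by a Guo-Thompson-style Markov chain over
  individual allele pairings.  The proposal swaps one allele copy between
  two random individuals; because a value may occur in several copies, the
  acceptance includes the exact Hastings correction from copy
  multiplicities - without it the chain is visibly biased (the
  configuration distribution is $\propto 2^{H}$ with $H$ the heterozygote
  count).  Defaults: 1000 dememorization steps, 100 batches of 1000
  iterations, with a between-batch Monte Carlo standard error.  One-sided
  deficit/excess p-values order tables by $H$; the global p-value orders
  them by conditional probability.
* **$F_{IS}$** (`inbreeding_coefficient()`): $1 - H_{obs}/H_{exp}$ with
  the small-sample-corrected $H_{exp}$; positive = heterozygote deficit.
  Reported per site and locus (`hwe_fis_scan()`), matching the usual
  marsh-by-locus grid.
* **$F_{ST}$** (`fst_theta()`): the Weir-Cockerham variance-components
  estimator summed over alleles and loci, with significance from
  permutations of individuals between the two samples.
* **Composite LD** (`composite_ld_test()`): the Burrows/Weir composite
  disequilibrium, which needs no phase information, aggregated into a
  chi-square with $(k_1-1)(k_2-1)$ df.  The headline p-value is the
  permutation one (the asymptotic p is also reported); alleles with zero
  dosage variance carry no information and are dropped from the
  aggregation.
* **Cytonuclear disequilibrium** (`cytonuclear_disequilibrium()`): the
  nuclear locus is reduced to a diallelic composite and the allelic and
  genotypic disequilibria between it and the mitotype are tested by
  permuting mitotype labels (a deliberate substitution for asymptotic
  variance formulas: permutation needs no large-sample assumptions at
  marsh-sized samples).  $D_1+D_2+D_3 = 0$ holds identically.
* **FDR** (`fdr_adjust()`): classical one-stage step-up control, the flags
  equal to Benjamini-Hochberg-adjusted p-values at the same rate (asserted
  in the tests); whether the original study's "classical one-stage method"
  is exactly this rule is not certain from its description, but the step-up
  rule is the standard reading.

All permutation p-values carry the add-one correction
$p = (1+\#\{T^* \ge T\})/(n_{perm}+1) \ge 1/(n_{perm}+1)$.

## Multiallelic loci and the composite allele

Cline fitting needs one frequency per locus, but microsatellites are
multiallelic and the pooling rule is rarely stated.  The package's
explicit rule (`diallelic_reduction()`): compute per-allele differentials
$\delta = p_N - p_S$ between designated parental pools and pool alleles by
the *sign* of $\delta$ into a composite northern class versus the rest.
Alleles with $\delta = 0$ carry no ancestry information and are excluded
from both numerator and denominator; loci with all $\delta = 0$ are
flagged non-informative.  When no ties occur, the between-pool difference
of the reduced frequency equals the per-locus summary differential
$\frac12\sum|\delta|$, so the reduction preserves exactly the
informativeness it is meant to capture.

## Admixture and parental-site choice

`admixture_em()` fits the no-linkage admixture model (each allele copy
drawn from cluster $z$ with probability $q_{iz}$, then from that cluster's
frequencies) by EM - a deliberate point-estimation replacement for MCMC
posterior machinery; the log-likelihood trace is monotone and exposed.
Replicated runs over a range of $k$ (`admixture_replicates()`) feed the
Evanno second-difference statistic (`evanno_delta_k()`).  One consequence
of point estimation is that replicates can converge to identical optima,
making the replicate standard deviation zero; $\Delta K$ is then flagged
undefined rather than fabricated.  Clusters are anchored geographically
(cluster 1 = southernmost by membership-weighted mean distance), so for
$k=2$ the second column is northern ancestry.

`select_parental_sites()` encodes the edge-of-zone rule: walking inward
from each end, a site is parental while more than half of its individuals
have $q > 0.9$ (north) or $q < 0.1$ (south); the innermost such site
before the first majority-admixed site bounds the zone.  The >50%
majority threshold is this package's concrete reading of "predominating";
the qualitative rule does not fix a number.

## Hybrid index and bimodality

`hybrid_index()` maximizes, over $h \in [0,1]$, the likelihood that treats
the individual's two allele copies per locus as independent draws from the
mixture $h\,p_N(a) + (1-h)\,p_S(a)$ - the standard codominant hybrid-index
model.  Optimization is a 0.001 grid refined by golden-section search;
the 2-unit support interval is read from the same profile.  Alleles
absent from exactly one parental sample are floored at $1/(2n_{pool}+1)$
(transparent, no smoothing parameters); alleles absent from both make the
locus uninformative for that individual and it is skipped.  Swapping the
parental pools maps $\hat h \to 1-\hat h$ exactly.

`dip_test()` assesses unimodality of the binned-or-raw hybrid indices with
Hartigan's dip: the sup-norm distance from the empirical CDF to the
nearest unimodal CDF (convex left of the mode, concave right, an atom
allowed at the mode).  The implementation minimizes, over candidate modes
at the data values, the smallest feasible band half-width, computed from
greatest-convex-minorant / least-concave-majorant hulls on each flank plus
a junction condition that the convex piece's minimal attainable end value
not exceed the concave piece's maximal attainable start value.  The
junction condition matters: omitting it underestimates the dip whenever
the candidate mode sits after a data gap.  p-values are Monte Carlo
against Hartigan's conservative uniform null
($p = (1+\#\{D^* \ge D\})/(n_{null}+1)$), seedable, rather than
interpolated from precomputed tables - small discrepancies from
table-based implementations are expected at extreme p-values.

A practical caveat established while calibrating the simulator: with a
panel of *fully diagnostic* loci the hybrid index lives on a lattice
(19 values for 9 diploid loci), and the dip test against a continuous
null reads those atoms as modes whatever the ancestry regime.  Real
microsatellite panels mix strong and weak differentials and give
quasi-continuous indices; conclusions from the diagnostic-panel regime
transfer to the *bimodal* question only because there the atoms genuinely
concentrate at the parental extremes.

## The synthetic hybrid zone

`simulate_hybrid_zone()` generates genotype tables with known truth under
two regimes (see `hz_sim_config()`):

* **clinal** - every allele copy independently northern with probability
  $p(x)$ from an ancestry cline; the hybrid-swarm regime, unimodal at any
  site;
* **classes** - each individual drawn from per-site weights over
  $\{P_S, P_N, F_1, F_2, BC_S, BC_N\}$ with gametes composed accordingly
  ($F_1$: one gamete per pool; $F_2$: two $F_1$ gametes; backcrosses: one
  $F_1$ and one pure gamete); the reproductive-isolation regime.
  Mitotypes follow the maternal side (configurable per class; parentals
  and backcross recurrent parents are fixed by definition, $F_1$/$F_2$
  default to an even chance).

Defaults define the study conditions: the 13-site transect with its
published per-site sample sizes; a nine-locus panel whose per-locus
differentials (1.00-0.15) mirror a real microsatellite panel spanning near
diagnostic to weakly informative (`default_locus_panel()`); the central
marsh at $n = 89$ with class weights $0.4/0.4$ parentals, $0.1$ F1 and
$0.1$ backcrosses for the bimodal regime (`preset_bimodal_config()`).
What the generator does **not** emulate: genotyping artefacts (null
alleles, allele dropout), within-site spatial structure, linkage between
loci, drift-mutation history of allele frequencies.  Passing tests
therefore demonstrate estimator correctness under the stated generative
model, not robustness to those artefacts.

## Numerical choices

* Likelihood clamps at $10^{-9}$; EM mass floors at $10^{-300}$ (guards
  against log-of-zero only).
* The dip is computed by per-mode bisection to $10^{-14}$, with a cheap
  hull-deviation lower bound per mode so the bisection runs only where the
  junction condition binds; agreement with an independent band-feasibility
  oracle is asserted to $10^{-9}$ in the tests.
* Profile-likelihood roots are located to about $10^{-5}$ of the parameter
  range (tighter for the closed-form interface).
* Ties in the dip input are handled by the ECDF directly; no jitter.
* Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state; derived child seeds stay below $2^{31}$.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which the calibration bands are
informative: 100 seeded replicates for cline parameter recovery (13
sites, 100 allele copies each), 200 replicates for the concordance-test
size, 500 individuals for hybrid-index class recovery, 500 uniform
samples (each with its own 999-replicate null) for dip calibration, and
several hundred replicates for the permutation-test sizes.  The
end-to-end pipeline example runs on a reduced panel with shortened chains
purely to keep the example brisk; scientific use should keep the
defaults (e.g. the full 1000/100x1000 HWE chain).

## A worked run

```{r worked, eval = FALSE}
sim <- simulate_hybrid_zone(hz_sim_config(seed = 1))
out <- hz_pipeline(sim$table, out_dir = tempfile("hz"), seed = 1)
out$cline$table          # per-locus fits, AICs, support limits
out$dip                  # per-site dip tests of the hybrid indices
```

## Known limitations

* The admixture model ignores linkage and correlated allele frequencies;
  it is a two-or-few-pool ancestry estimator, not a replacement for full
  posterior structure inference.
* Variant-III tails use a slope-ratio exponential splice that is
  continuous but not differentiable at the splice; profile intervals for
  tail parameters are not reported.
* The dip test's uniform null is conservative for peaked unimodal
  alternatives and, as noted, unsuitable for heavily latticed inputs.
* Genepop files carry no site metadata, sex or collection year; the CSV
  dialect is the lossless format.
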