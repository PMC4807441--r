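# hybridzone

Tools for characterizing hybrid zones from codominant multilocus genotypes
(e.g. microsatellites) plus a diagnostic haploid mitochondrial marker.  The
package covers the full analysis chain of a classic contact-zone study -
the Atlantic killifish (*Fundulus heteroclitus*) subspecies transition along
the New Jersey coast is the motivating system - from raw genotype tables to
the verdict on whether the zone is a hybrid swarm or reproductively
isolated:

* **Geographic cline fitting** by maximum likelihood,
  `p(x) = p_min + (p_max - p_min) * (1 + tanh(2(x - c)/w))/2`,
  in four variants (flat null; fixed ends; free ends; free ends with
  exponential introgression tails), with AIC model selection, 2-unit
  support limits by profile likelihood, a constrained-vs-free
  likelihood-ratio test of cline concordance/coincidence in the
  scaled-logit shape, and the neutral-width prediction
  `w = sigma * sqrt(2 * pi * T)`.
* **Within-site disequilibrium statistics**: exact Hardy-Weinberg tests
  (full enumeration or a Guo-Thompson-style Markov chain), F_IS,
  Weir-Cockerham F_ST with permutation p-values, Burrows/Weir composite
  linkage disequilibrium, cytonuclear disequilibrium, and classical
  one-stage FDR control.
* **Admixture** proportions by EM on the no-linkage admixture model, the
  Evanno delta-K heuristic, and the rule for picking parental reference
  sites at the zone edges.
* **Hybrid indices**: per-individual maximum-likelihood ancestry
  h in [0, 1] from parental allele-frequency differentials, 0.10-binned
  distributions, and **Hartigan's dip test** of unimodality (exact
  statistic, Monte Carlo p-values) to diagnose bimodal hybrid zones.
* **A seeded hybrid-zone simulator** (clinal hybrid-swarm and
  genotype-class-mixture regimes, maternal mitochondrial inheritance) with
  known truth, so every stage is testable without field data.
* Genepop and CSV genotype I/O, and an end-to-end `hz_pipeline()` writing
  TSV reports plus a JSON manifest.

## A worked example

```r
library(hybridzone)

# a synthetic killifish-like transect: 13 sites, 9 microsatellites + mtDNA
sim <- simulate_hybrid_zone(hz_sim_config(seed = 1))
sim$table
#> Genotype table: 471 individuals, 9 codominant loci, 13 sites, mito typed

# mitochondrial cline: fit all four variants, pick by AIC
d <- cline_data(sim$table, "mtDNA")
fits <- lapply(c(null = "null", I = "I", II = "II", III = "III"),
               function(v) fit_cline(d, v, seed = 1))
select_cline_model(fits)
#> [1] "I"
#> attr(,"aic")
#>     null        I       II      III
#> 630.4233 247.9992 251.9992 259.9992
fit <- fits$I
coef(fit)
#>     centre      width      p_min      p_max
#> 1220.75228   55.90393    0.00000    1.00000
confint(fit)
#>             lower      upper
#> centre 1215.95187 1225.24167
#> width    45.34966   69.79888
```

Variant I (end frequencies fixed at the transect-end observations, here
exactly 0 and 1) wins on AIC because the free-ends variant buys no extra
fit for its two extra parameters.  The fitted centre (~1221 km from the
southern end of the transect, i.e. central New Jersey; 2-unit support
1216-1225 km) and width (~56 km, support 45-70 km) recover the generating
cline (centre 1217 km, width 58 km); a width this far below the neutral
expectation (`neutral_cline_width(15000, 2)` = 614 km for post-glacial
contact with 2 km/generation dispersal) is the signature of selection
maintaining the zone.

```r
# bimodality at the central marsh (reproductive-isolation regime, n = 89)
simb <- simulate_hybrid_zone(preset_bimodal_config(n = 89, seed = 1))
h <- hybrid_index(simb$table,
                  parental_frequencies_from_panel(fixed_difference_panel(9)))
dip_test(h$h, n_null = 999, seed = 1)
#> Hartigan dip test: D = 0.1966, n = 89, Monte Carlo p = 0.001 (999 null reps)
```

A dip this large rejects unimodality decisively: the simulated marsh,
built with 80% parental genotypes and few F1/backcrosses, shows the
bimodal hybrid-index distribution that indicates reproductive isolation.

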