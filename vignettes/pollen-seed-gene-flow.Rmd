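---
title: "Contrasting pollen and seed gene flow with nuclear and organelle markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrasting pollen and seed gene flow with nuclear and organelle markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenseed)
```

## The problem

In seed plants the two genomes travel differently.  Nuclear genes move
through both pollen and seeds; a maternally inherited organelle genome
(chloroplast DNA in most angiosperms) moves only with seeds.  Comparing the
population structure of the two marker classes therefore separates the two
dispersal channels: if pollen moves much more than seed, the maternal marker
should be far more structured than the nuclear one; if the two move equally,
the maternal structure is predictable from the nuclear structure and the
mating system alone.  This contrast is particularly interesting in coastal
and estuarine trees (e.g. mangroves), where water-borne seed dispersal can
rival or exceed pollen dispersal — the reverse of the usual situation in
trees.

`pollenseed` implements the complete inferential chain for one nuclear
microsatellite panel plus one organelle haplotype locus:

1. **Nuclear structure** — Weir & Cockerham (1984) variance-component
   estimators of $F_{ST}$ ($\theta$) and $F_{IS}$ ($f$), multilocus values
   as ratios of summed components, SEs by delete-one-locus jackknife,
   pairwise $\theta$ with permutation tests.
2. **Mating system** — at inbreeding equilibrium under mixed mating,
   $F_{IS} = s/(2-s)$, so the outcrossing rate is
   $t = (1 - F_{IS})/(1 + F_{IS})$.
3. **Organelle structure and diversity** — Nei's
   $G_{ST} = (H_T - H_S)/H_T$ on haplotype frequencies with unbiased
   diversities, delete-one-population jackknife SE, and per-population
   haplotype diversity $H_d = \frac{n}{n-1}(1 - \sum p_i^2)$.
4. **AMOVA** — one-level (among/within populations) analysis of molecular
   variance, allele-identity distances for the nuclear data and squared
   mutational-step distances for haplotypes, permutation significance.
5. **Spatial genetic structure (SGS)** — Loiselle kinship $F_{ij}$ against
   $\ln$(distance): slope $b_{ld}$, locus-jackknife SE, one-sided
   permutation test, first-class mean kinship $F_A$, and
   $Sp = -b_{ld}/(1 - F_A)$.
6. **Pollen versus seed inference** — the expected maternal $F_{ST}$ under
   equal migration,
   $F_{ST}^{mat} = a_b F_{ST}^{bipar} / \{a_m + (a_b - a_m) F_{ST}^{bipar}\}$
   with $a_m = 2$ and $a_b = 4 + 2t$, a $\pm 2\,SE$ interval-overlap test
   against the observed $G_{ST}$, and the Ennos migration-rate ratio
   $$ r = \frac{m_p}{m_s}
      = \frac{(1/F_{ST}^{bipar} - 1)(1 + F_{IS}) - 2(1/G_{ST}^{mat} - 1)}
             {1/G_{ST}^{mat} - 1}. $$
7. **A forward simulator** that generates data with all of the above as
   known truth.

## Estimator conventions and their consequences

**Weir–Cockerham, not Nei, for the nuclear side.**  Multilocus $\theta$ and
$f$ are ratios of summed variance components, never averages of per-locus
ratios.  With all populations fixed for different alleles $\theta = 1$; for
a duplicated population $\theta$ is slightly *negative* (the estimator is
unbiased around zero, with noise of order $1/n$) — code that expects exact
zeros there misreads the estimator.

**The $a_b = 4 + 2t$ coefficient.**  The equal-migration conversion from
biparental to maternal $F_{ST}$ needs the effective number of gene copies a
dispersal event moves.  A seed carries two nuclear copies plus the
organelle; pollen carries one outcrossed nuclear copy.  Selfing discounts
the pollen channel, giving $a_b = 4 + 2t$ between the fully selfing
($a_b = 4$) and fully outcrossing ($a_b = 6$) limits, while $a_m = 2$.
An algebraic consequence worth knowing: if the observed $G_{ST}$ equals the
equal-migration expectation exactly, the Ennos formula returns
$r = 1 + F_{IS}$, not 1 — the two published methods disagree slightly about
what "equal migration" looks like, and this package reproduces that
arithmetic as published rather than reconciling it.  Note also that $r$ is
strictly *increasing* in $G_{ST}^{mat}$: more maternal structure means less
seed flow, hence a larger pollen-to-seed ratio.

**Interval-overlap testing.**  The expected maternal $F_{ST}$ inherits the
nuclear $F_{ST}$ jackknife SE untransformed, and both intervals are
point $\pm 2\,SE$ closed intervals; the null of equal migration is rejected
only when they fail to overlap (touching endpoints overlap).  With only two
populations a delete-one-population jackknife for $G_{ST}$ has no contrast,
so the SE — and then the verdict — is reported as `NA` rather than
invented.

**Loiselle kinship.**  Per locus and allele the pair term is
$(p_{ia}-\bar p_a)(p_{ja}-\bar p_a) + \bar p_a(1-\bar p_a)/(n_l-1)$ with
$n_l$ the typed gene copies, and the multilocus value is the ratio of
summed numerators to summed weights $\sum_a \bar p_a(1-\bar p_a)$ over
co-typed loci.  The small-sample term centers the estimator *approximately*:
the all-pairs mean is $O(1/n^2)$ in expectation plus a sampling term, not an
exact zero, and structure in the sample shifts it by about $-\bar F/(2n)$.
Tests therefore bound the mean rather than asserting machine zero, and the
pairwise values themselves are verified against a brute-force oracle.

**Distance classes.**  Uneven lags with a constant pair count are built as
equal-count quantile bins over pair distances up to 10 km, after which the
first edge is widened until at least 90% of nearest-neighbor pairs fall in
class 1 — this makes $F_A$ a genuine near-neighbor kinship.  Pairs at
distance zero (trees sharing one GPS point) cannot enter a
$\ln$(distance) regression; they are dropped and counted in the result.
The regression runs over individual pairs, not class means; the class curve
is reported for plotting.  The permutation test shuffles spatial locations
among individuals and is one-sided for negative slopes, because restricted
dispersal predicts kinship decline.

**Brookfield null alleles.**  The method-1 estimator
$q = (H_e - H_o)/(1 + H_e)$ has a structural negative bias under the very
model it targets: with $H_e$ and $H_o$ computed from amplified individuals
its expectation is about $2qH/\{(1+q)(1+H)\}$, which cannot exceed
$q/(1+q)$ even as $H \to 1$ and falls with diversity.  At $q = 0.2$ and
$H \approx 0.9$ it returns $\approx 0.17$.  The estimator-recovery check
therefore uses a high-diversity panel, the regime the method was designed
for; at low diversity the estimator should be read as a screen, not a
measurement.

**AMOVA.**  "F_ST-based" means allele-identity distances at the gene-copy
level (0/1 per locus), not repeat-size differences; haplotype AMOVA squares
the mutational-step distance.  Components use the standard unequal-$n$
coefficient, are summed over loci, and permutations move whole individuals
(a diploid genotype migrates as one unit) among populations.  A negative
among-population component is reported raw, with the percentage display
floored at zero.  For haploid data with identity distances this machinery
is algebraically identical to the Weir–Cockerham haploid $\theta$
(`wc_theta_haploid()`), which the tests exploit as a cross-check.

**Permutation p-values** always include the observed statistic:
$p = (1 + \#\{\text{permuted} \ge \text{observed}\})/(n_{perm} + 1)$, so
$p \in (0, 1]$ and the null distribution is discrete-uniform.  The default
permutation count everywhere is 10,000.

## The simulator: what it emulates and what it does not

`simulate_metapopulation()` runs non-overlapping generations of a
hermaphroditic plant metapopulation with constant deme sizes:

* each offspring draws a **mother** (seed migration with probability `m_s`
  moves the zygote — two nuclear copies and the organelle — to another
  deme, uniformly);
* with probability `s` it is **selfed**, otherwise an outcross **pollen
  donor** (never the mother) is drawn, from another deme with probability
  `m_p` — pollen moves exactly one nuclear gamete;
* microsatellites mutate stepwise ($\pm 1$ repeat, rate `mu_nuc`), the
  organelle mutates to a brand-new haplotype (infinite alleles, rate
  `mu_org`);
* in `linear` mode the deme draws become Gaussian kernels (`sigma_s`,
  `sigma_p`) along a 1-D habitat with reflecting boundaries, which
  produces isolation by distance.

Defaults are desk-scale study conditions chosen once: 4 demes of 100
diploids, 200 generations, 10 loci with 8 founder alleles per locus,
full outcrossing, `m_p = m_s = 0.01`, `mu_nuc = 1e-3`, `mu_org = 3e-4`
with 6 founder haplotypes (enough standing organelle variation that
$G_{ST}$ stays defined through 200 generations of drift at these sizes),
and a 10 km linear habitat with `sigma_s = 250` m and `sigma_p = 500` m —
the spatial scale on which within-estuary SGS is usually summarized.  One
run takes well under a second.

Null alleles are injected after the fact: per locus a randomly ordered
allele set is accumulated to total frequency `q_null` (the boundary allele
enters fractionally so the expectation is exact); one masked allele in a
heterozygote shows as a visible homozygote, two masked alleles show as a
missing genotype.

What the simulator does **not** emulate: overlapping generations and
perennial demography, selection, realistic estuary geometry and water-borne
dispersal kernels, genotyping error other than null alleles, and
hybridization/introgression.  Passing the recovery suite therefore shows
the estimators are correct under the stated statistical model, not that
field data meet that model.

## Validation design

The test suite follows three layers, at sizes chosen for a single CPU:

* **Oracle equivalence** — Weir–Cockerham from the indicator-variable
  nested ANOVA, AMOVA from explicit pair loops, Loiselle from literal
  sums over alleles; randomized tiny instances (2–3 populations, 2–6
  individuals, 1–3 loci) agree to $10^{-9}$.
* **Replay** — the derived-quantity chain ($t$, expected maternal
  $F_{ST}$ with CIs, Ennos $r$, $Sp$) reproduces a published mangrove
  comparison exactly from its printed summary statistics.
* **Recovery from simulation** — equilibrium $F_{IS}$ matches $s/(2-s)$
  within 3 Monte-Carlo SEs at $s \in \{0, 0.33, 0.8\}$ (12 replicates
  each); organelle $G_{ST}$ exceeds nuclear $F_{ST}$ under equal migration
  (20 replicates); replicate-mean Ennos $r$ ranks the true
  $m_p/m_s \in \{0.25, 1, 4\}$ (12 replicates each); linear-habitat runs
  give significantly negative $b_{ld}$ in at least 90% of 30 replicates;
  and the Brookfield estimator recovers $q_{null} = 0.2$ within $\pm 0.05$
  over 50 replicates on the high-diversity panel.  Permutation machinery
  is checked for p-value uniformity (Kolmogorov–Smirnov over 200 null
  replicates at 99 permutations).

## A worked example

```{r example}
cf <- sim_config(n_demes = 3, N = 60, generations = 100,
                 m_p = 0.04, m_s = 0.01, rng_seed = 42)
sim <- simulate_metapopulation(cf)
gene_flow_analysis(sim$genotypes, sim$haplotypes)
```

With pollen migrating four times faster than seed, the maternal marker is
much more structured than the nuclear one and the Ennos ratio lands well
above 1.

The same chain runs directly from published numbers, without genotypes:

```{r replay}
replay_gene_flow(f_st = 0.3181, se_f_st = 0.0396, f_is = 0.1950,
                 g_st = 0.3469, se_g_st = 0.1031)
```

## Known limitations

* The equal-migration conversion and the Ennos ratio assume island-model
  equilibrium; neither is meaningful under strong non-equilibrium
  (recent colonization, range shifts).
* $G_{ST}$ SEs come from a population jackknife; with few populations they
  are coarse, and with two they do not exist.
* The Hamilton–Miller test is a conservative interval-overlap rule, not a
  likelihood-based test; near-touching intervals carry no graded evidence.
* Unbiased diversity corrections make small-sample $G_{ST}$ slightly
  negative for identical populations sampled evenly; this is a property of
  the estimator, not a bug.
* The Brookfield estimator's diversity-dependent bias (above) means its
  output on low-diversity loci should not be taken at face value.
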