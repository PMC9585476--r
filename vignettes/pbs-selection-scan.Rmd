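---
title: "PBS selection scans with pbscan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PBS selection scans with pbscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbscan)
```

## The statistic

pbscan scans a genome for allele-frequency change specific to one population
branch.  For a target population A scored against an ingroup B and an
outgroup C, each bi-allelic site contributes a population branch statistic

$$\mathrm{PBS}_A = \frac{T_{AB} + T_{AC} - T_{BC}}{2},
\qquad T_{XY} = -\log\!\left(1 - F_{ST}^{XY}\right),$$

with natural logarithms.  $T$ is an additive divergence on the three-taxon
tree, so $\mathrm{PBS}_A$ estimates the length of the branch private to A:
drift or selection on the A branch raises $T_{AB}$ and $T_{AC}$ together
while leaving $T_{BC}$ untouched.  An immediate consequence, used throughout
the test suite, is the swap identity
$\mathrm{PBS}_A + \mathrm{PBS}_B = T_{AB}$ at every site.

Per-site $F_{ST}$ is the two-population Weir–Cockerham moment estimator
computed from derived-allele counts, treating each called chromosome as one
haploid observation.  Writing $n_i$ for called chromosomes, $p_i$ for sample
frequencies, $\mathrm{MSP}$ and $\mathrm{MSG}$ for the between- and
within-population mean squares and $n_c$ for the sample-size correction, the
estimate is $(\mathrm{MSP}-\mathrm{MSG})/(\mathrm{MSP}+(n_c-1)\mathrm{MSG})$.
The package stores the `a` and `b_plus_c` variance components per site so
multi-site $F_{ST}$ aggregates as a ratio of sums (`fst_region()`), the
standard "ratio of averages".

Numerical conventions, fixed and tested:

* Negative per-site estimates (expected whenever sample frequencies are
  nearly equal) are clamped to 0 before the log transform; $F_{ST}=1$ is
  clamped to $1-10^{-8}$ so branch lengths stay finite.  The raw unclamped
  values are retained in the scan table for audit.  PBS itself is never
  truncated: ranking operates on signed values.
* A site is *undefined* exactly when both populations are monomorphic for
  the same allele (zero denominator); undefined values propagate as `NA`
  instead of being silently dropped.
* Every percentile in the package (`percentile()`) is the linear-interpolation
  ("type 7") definition, so threshold behaviour is reproducible across
  platforms.

## The scan

`run_pbs_scan()` (VCF + population map) or `compute_pbs()` (a `site_counts`
table) applies, in order: a depth rule (site mean DP of at least 10 reads;
sites lacking DP fail unless the rule is disabled), a missingness rule
(missing-call fraction strictly below 5%), a polymorphism rule (derived
frequency strictly inside (0,1) in at least one trio population) and a
low-call guard (at least 2 called chromosomes per population).  Each removed
site is attributed to the first rule it fails, so the filter report is
conserved: removals plus survivors equal the input.  Two interpretations the
input formats leave open are resolved as follows and exposed as
configuration: depth is a *site-level mean* across the selected samples (a
per-sample rule would interact with the separate missingness filter), and
the inequality is non-strict (`>= 10`).

Thresholds (90th, 99.995th, 99.999th percentiles) are computed on the
post-filter PBS distribution of the analysed trio itself — the only
self-consistent choice when different trios retain different sites.  Hits
above the 99.995th percentile are annotated with every gene whose body
extended by 20 kb contains them (boundary-inclusive, BED half-open
conventions respected at the edges); `local_zoom()` adds composite
genotype-dosage $r^2$ against the top-PBS index variant of a gene window,
with ties broken towards the smaller position — data in this pipeline are
unphased, so a haplotype-based LD measure is out of reach by design.

`trio_contrast()` compares the bulk of two PBS distributions after windowing
each to the open interval between the 90th and 99.995th percentiles,
discarding the noise floor and the extreme sweep tail, and applies a
one-sided Mann–Whitney U test of "first lower than second".  Windowing by
each side's *own* percentiles (the default) makes the comparison invariant
to a pure location shift and sensitive to shape differences in the upper
bulk; a pooled-percentile mode is available when a common absolute window is
wanted.  Both modes are provided because either reading of a shared
90th/99.995th window is defensible; the choice is reported in the result.

## The polygenic-selection test

`prepare_gene_sets()` mirrors the standard curation of pathway collections:
genes without a mapped interval and genes on non-autosomes are dropped per
set, then sets with fewer than 10 surviving genes are discarded.
`run_polygenic_scan()` assigns every scanned variant to each curated gene
whose body ± 20 kb contains it (the same flank the scan uses for hit
annotation; configurable, 0 = gene body only), pools a set's variants with
deduplication, and tests the pool against the background with a one-sided
Mann–Whitney U ("set larger").  The background for each test is every
scanned variant *not* assigned to that set — the complement reading of
"the rest of the genome"; a genic-only background is available behind a
flag.  Bonferroni control multiplies by the number of curated sets, capped
at 1.

The U statistic uses average ranks, so ties contribute one half to each
side and the complement identity $U_1 + U_2 = n_1 n_2$ holds exactly.  The
p-value is computed by exact enumeration over all group assignments when
the combined sample has fewer than 20 observations (which makes the
documented toy example — set {3,4,5} vs background {1,2}, $U = 6$,
$p = 0.1$ — reproducible bit for bit) and otherwise by the normal
approximation with tie correction and continuity correction, which the
suite checks against both `wilcox.test()` and the exact tie-free Wilcoxon
distribution.

## Uniparental summaries and ROH

Haplogroup diversity per population is
$\mathrm{HD} = n\,(1 - \sum_h x_h^2)/(n-1)$ with $n$ the population's sample
size (row sum of the count table) and $x_h$ the haplogroup frequencies — an
unbiased heterozygosity analogue; it is 0 exactly when a single haplogroup
is present.  The frequency PCA centres the frequency vectors without
variance scaling (the columns already share a scale) and fixes each axis'
sign by making its largest-magnitude loading positive, so coordinates are
deterministic; scaling is available as an argument for users who want it.

ROH segments are classed as short ($\le$ 0.5 Mb), medium (0.5–1 Mb) or long
(> 1 Mb).  The interior boundaries are left-open/right-closed — 0.5 Mb
exactly is short, 1.0 Mb exactly is medium — so the three printed classes
partition the length axis; per-class average length is total length divided
by count, and totals are conserved exactly.

## The synthetic trio generator

All calibration runs on synthetic panels from `sim_config()` +
`simulate_trio_frequencies()` + `sample_genotypes()`.  The generator
emulates the statistical structure the scan assumes, not sequence-level
realism:

* **Drift.** Balding–Nichols: each site's ancestral derived-allele
  frequency $p$ is uniform within `ancestral_freq_bounds` (default
  0.05–0.95), and each population draws an independent
  $\mathrm{Beta}$ frequency with mean $p$ and variance $p(1-p)c$.  The
  drift parameter $c$ is therefore the expected $F_{ST}$ of that population
  against the ancestral pool, giving direct control of the quantity the
  estimator measures: the suite verifies that two populations at $c = 0.05$
  yield a realized ratio-of-averages $F_{ST}$ within $\pm 0.01$ of 0.05.
* **Sweeps.** A `sweep_locus()` pins one population's frequency at one site
  to an exact value, emulating the end state of a branch-specific sweep;
  all other draws are untouched, so a swept and a sweep-free run with the
  same seed agree everywhere else.
* **Genotypes.** Hardy–Weinberg binomial dosages, per-call missingness at a
  flat rate, and a site-level mean depth from a negative-binomial model
  (mean 30×, matching a high-coverage panel; overdispersion 0 gives
  Poisson).  Depth is generated and stored at the site level because the
  scan's depth filter is site-level.
* **Polarity.** Each site's ancestral allele is emitted as REF or ALT by a
  fair coin and recorded in the `AA` INFO tag, so the polarization code is
  exercised in both directions on every panel.
* **Reproducibility.** Every component (frequencies, genotypes, depth,
  polarity, genes, haplogroups, ROH) draws from its own sub-stream derived
  deterministically from the master seed, so enlarging one component never
  perturbs another, and an identical `sim_config` reproduces byte-identical
  artifacts.

Default sample sizes are 48 diploids per population — the size of an
unrelated high-coverage panel of an isolated target population — with a
2% missing-call rate.

What the generator does *not* model: linkage (sites are independent, so LD
in `local_zoom()` is only non-trivial at engineered or chance-correlated
sites), recombination and haplotype structure, mutation spectra, and
population-size history beyond the single drift parameter per branch.
Passing calibrations therefore demonstrate that the estimators and
thresholds behave as designed under the assumed frequency model; they do
not certify behaviour under background LD, which in real data widens sweep
signals and correlates neighbouring tests.  One useful consequence of the
model worth stating explicitly: with equal drift $c$ on all three branches
the *expectation* of PBS is the target branch length, about $c$, not 0 —
only the *median* of the noisy per-site distribution sits near zero at the
drift levels used here ($c \le 0.02$), which is what the null-centred check
in the suite asserts.

## Problem sizes and calibrations

The calibrations in the test suite and the acceptance script use the
following fixed designs, chosen to keep every stage at desk scale while
leaving the Monte-Carlo error well inside each asserted band: drift
calibration at 50,000 sites × 50 diploids × 5 seeds; sweep recovery at
200,000 sites with 50 sweep loci boosted to 0.85 derived frequency from
ancestral frequency $\le 0.2$ ($c = 0.02$ target/ingroup, 0.05 outgroup),
scored against the scan's own 99.9th percentile; polygenic null calibration
with 500 random 15-gene sets over an 8-chromosome, 80,000-site genome; and
an enrichment recovery with one 50-gene set engineered over 50 sweep loci
among 49 null sets.  The 80%-power floor for sweep recovery was calibrated
once on this design and frozen with its seeds; observed power is 100% with
zero designated-site exceedances in matched sweep-free runs.

## Known limitations

* Only bi-allelic SNVs are scanned; multi-allelic records are skipped with
  a count, not decomposed.
* Unpolarizable sites (missing or off-allele `AA`) stay in the F_ST/PBS
  path, which needs no polarity, but are refused by `derived_allele_frequency()`.
* The Mann–Whitney exact path enumerates group assignments and is reserved
  for small samples; large tied samples rely on the corrected normal
  approximation.
* The null-calibration band for 500 dependent set tests is the binomial
  95% band; because the tests share one genome draw, occasional excursions
  beyond it are expected across seeds.
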