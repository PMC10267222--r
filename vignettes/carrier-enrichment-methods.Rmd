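---
title: "Methods: strain-resolved carrier enrichment and gene association"
author: "carrierscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-resolved carrier enrichment and gene association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carrierscan)
```

# The scientific problem

Gut bacteria are not uniformly mixed: different taxa prefer the mucosal
layer or the lumen, and this spatial organization matters for community
function and host interaction. In vitro, mucin-hydrogel carriers suspended
in a liquid culture of a defined strain community reproduce this dichotomy —
the carrier emulates mucosa, the supernatant emulates lumen — and paired
metagenomic sampling of both compartments at each passage yields
strain-resolved measurements of spatial preference. `carrierscan` implements
the downstream analysis: calling strain detection from abundance and
coverage, scoring per-strain compartment enrichment, scanning KEGG Orthology
(KO) gene-family genotypes for association with that enrichment under a
phylogenetic regression, testing gene-neighborhood co-occurrence around an
anchor gene family, and grouping biosynthetic gene clusters (BGCs) by KO
co-occurrence for group-level association.

Because the package is validated end to end on synthetic data, the
synthetic-data generator is itself a first-class, tested module: it produces
every input the pipeline consumes with the statistical structure the
analysis assumes, so planted truths can be recovered and null behavior can
be calibrated without any sequencing data.

# Detection, richness and prevalence

A strain is *detected* in a library when its relative abundance strictly
exceeds 1e-6 (0.0001%) **and** its horizontal genome coverage strictly
exceeds 0.01 (1%). Both inequalities are strict: the rule is "exceeds", so
boundary values are absent. Richness is the per-library count of detected
strains; group medians (e.g. carrier vs no-carrier over stabilized passages)
are taken over libraries, before technical-replicate collapsing, since the
counting unit is the sequenced library. Both per-library and collapsed views
are available, as the choice is not forced by the statistic.

*Top prevalent strains* are those exceeding 1e-4 (0.01%) relative abundance
in at least `ceil(0.10 * n_samples)` passaged libraries — with the study
design of 270 passaged libraries this is 27 or more. `ceil` rather than
`round` keeps the count threshold monotone in the sample count. Percent
strings ("0.01%") are accepted anywhere a fraction is expected and converted
by `as_fraction()`, specifically to avoid the 0.01%-vs-0.01 trap.

Technical replicates (same culture tube) are collapsed to their per-strain
*median* abundance and coverage; biological replicates (different tubes)
stay separate. Medians of renormalized fractions need not sum to exactly 1
and are deliberately not renormalized again.

# The carrier-enrichment score

For strain $s$ and pair $p$ (one carrier and one supernatant sample from the
same tube and passage),

$$ e_{s,p} = \ln \frac{a^{\mathrm{carrier}}_{s,p}}{a^{\mathrm{sup}}_{s,p}} $$

with zeros replaced, *per sample*, by half that sample's minimum nonzero
relative abundance before the log transform. The per-sample scope treats the
replacement as a sample-specific detection limit; per-strain or global
alternatives would mix detection limits across sequencing depths. If a
strain is zero in **both** compartments of a pair the score is missing
rather than 0 — a ratio of two pseudo-counts carries no signal.

The aggregate score is mean over standard deviation (sample SD, $n-1$) of
the non-missing pair scores in the late passages (P3–P6, so up to
4 passages × 3 biological replicates = 12 scores). Strains with fewer than
two usable scores, or zero SD, get a missing aggregate with a flag — never
±infinity. The natural log is used and labeled; the aggregate is invariant
to the log base since the constant cancels in mean/SD (asserted to 1e-12 in
the tests). Positive scores mean carrier (mucosa-like) preference. The same
statistic with pairing over (individual, site) serves mucosa/lumen designs:
13 individuals × 3 sites gives 39 scores per species.

# Phylogenetic regression

Closely related strains have correlated genotypes *and* correlated
phenotypes, so ordinary least squares overstates the evidence for
genotype–phenotype association. The scan therefore fits, per KO $k$,

$$ y = \alpha + \beta z_k + \varepsilon, \qquad
   \varepsilon \sim N(0, \sigma^2 C), $$

where $y$ is the per-strain enrichment score, $z_k$ the standard-scaled
maximum-bitscore column, and $C$ the Brownian-motion covariance of the
community tree: $C_{ij}$ is the root-to-MRCA shared path length,
$C_{ii}$ the root-to-leaf depth. The fit whitens both sides with the inverse
lower Cholesky factor of $C$ and solves OLS on the whitened data;
$\hat\sigma^2$ uses the unbiased divisor $n-2$ and the two-sided p-value a
Student t on $n-2$ degrees of freedom. The Brownian rate is profiled out, so
results are invariant to rescaling $C$; with $C = I$ (a unit-depth star
phylogeny) the fit reduces to OLS exactly. An exact bit-match to any
particular reference implementation is not claimed; correctness is anchored
to an explicit-inverse GLS oracle and to null calibration.

Numerical choices: a near-singular $C$ receives one shot of diagonal jitter
`1e-10 * trace(C)/n`, then errors if still singular; zero-variance genotype
columns are excluded from the test and from the Benjamini–Hochberg family
(they carry no test); strains with missing phenotype are dropped per scan,
not imputed; BH uses the standard step-up with stable ordering. Hits are
called at BH FDR < 0.01. Clade scans repeat the procedure within phyla on
the pruned tree, merging Firmicutes, Firmicutes_A and Firmicutes_C into one
clade; clades with fewer than three phenotyped strains are skipped. Overlap
between two hit lists over a common universe is assessed by the two-sided
Fisher exact test, reporting the log conditional-MLE odds ratio with its 95%
CI (the Haldane-corrected sample log odds is also emitted, and used as the
cap when a degenerate margin makes the MLE infinite).

# Gene-neighborhood permutation test

A gene is KO-labeled when its profile-HMM hit covers strictly more than half
the KO model and its bitscore strictly exceeds half the KO's adaptive
threshold. For an anchor KO (K00441 in the motivating analysis), the
observed statistic per KO is the number of genes carrying it whose interval
intersects the union of windows `[start - 10 kb, end + 10 kb]` around
anchor-labeled genes, same contig, summed over genomes. The union rule
counts a gene once per genome even when anchor windows overlap — the
counting unit is a declared choice, since midpoint or start-to-start
distances and per-window counting are equally unstated alternatives and less
inclusive. Anchor genes' other labels are counted; the anchor KO itself is
not.

The null reassigns gene label *sets* (moved as units, so multi-label genes
stay internally consistent, and anchor labels move too) uniformly within
each genome, keeping gene positions fixed, 1000 times. The raw empirical
p-value is `#(null >= observed)/1000` — deliberately without add-one
smoothing, to mirror the "990 or more out of 1000" hit rule: a KO is a hit
when its observed count strictly exceeds the permuted count in at least
`ceil(0.99 * n_perm)` permutations. A smoothed p-value `(k+1)/(n+1)` is also
emitted for downstream use. KOs never observed in a window are skipped, and
no multiple-testing correction is applied across KOs, matching the raw
P < 0.01 convention of the motivating analysis. Because counts are small
integers, the test is conservative at atoms of the null distribution; the
calibration test therefore checks the hit fraction over *tested* KOs against
the 99% binomial band around 0.01.

# BGC grouping

Each BGC's KO presence set is the union of qualifying labels over its genes
(same labeling rule as above). BGCs with fewer than three present KOs are
dropped; the rest are clustered on binary KO profiles with Jaccard distance
($1 - |A \cap B| / |A \cup B|$, via `dist(method = "binary")`) and
average-linkage hierarchical clustering, cut into `min(k_groups, n)` flat
groups. Average linkage is the conventional default for Jaccard profiles;
the linkage and cut count are exposed as configuration, with 256 groups as
the default cut. Processing order is fixed by BGC id, making the grouping
deterministic. A strain carries a group when its genome contains at least
one member BGC; the binary strain-by-group matrix feeds the same
phylogenetic regression, unstandardized (t and p are scale-invariant for a
single regressor).

# The synthetic-data generator

The generator emulates the study conditions end to end:

* **Tree** — a pure-birth (Yule) tree on `n_strains` leaves, rescaled to
  unit root-to-tip depth. 64 strains is the default working size: large
  enough for the scan's asymptotics to be representative, small enough that
  the full suite runs in seconds.
* **Genotypes** — per KO, a latent Brownian trait on the tree thresholded at
  the `presence_rate` quantile (default 0.5), so presence patterns carry
  realistic phylogenetic signal (clade-like blocks). Present strains draw
  bitscores at `threshold * (1 + |N(0.5, 0.1)|)`, absent strains uniformly
  below half the threshold, so the adaptive-threshold labeling rule
  separates them cleanly.
* **Phenotype** — Brownian motion (rate `bm_sigma2 = 1`) plus
  `beta * z_k` for each causal KO (`z_k` the standardized presence
  indicator, default `beta = 2`) plus i.i.d. noise (`noise_sd = 0.1`). This
  is exactly the generative model the PGLS assumes, apart from the i.i.d.
  noise term (see limitations).
* **Abundances** — log-normal baselines (sdlog 3, so the community spans the
  ~5 decades real defined communities do), with the carrier sample
  multiplied by `exp(+trait/2 + eps)` and the paired supernatant by
  `exp(-trait/2 + eps')`. The symmetric ±trait/2 construction makes the
  per-pair log ratio equal the trait in expectation, so recovery is exact in
  the noiseless limit. Samples are renormalized to 1, floored at the
  detection limit, and horizontal coverage follows a logistic in log10
  abundance (midpoint 1e-5, scale 0.15 decades), placing the 1%-coverage
  failure mode above the abundance cutoff so both arms of the detection rule
  are exercised.
* **Annotations** — one contig per genome, fixed 1 kb genes with 200 bp gaps
  (hand-checkable window arithmetic), uniform background labels, exactly one
  anchor gene per genome, and with probability `colocal_prob` each partner
  KO relabels one gene inside the anchor's window.
* **BGCs** — disjoint KO signatures per group; each member BGC keeps at
  least 80% of its signature plus a little label noise; carriage per strain
  is Bernoulli.

Every simulator is bit-reproducible under its seed (seeds are restored via
`withr`, so the caller's RNG state is untouched). What the generator does
*not* emulate: read-level sampling noise, compositional coupling between
strains beyond renormalization, genome rearrangement, horizontal transfer
decoupling genotype from phylogeny, or any BGC–phenotype linkage (the BGC
scan in the demo run is a deliberate negative control). Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated model, not robustness to every feature of real sequencing data.

# Problem sizes used in tests and the acceptance script

The test suite and `scripts/acceptance.R` run at: 64-strain trees; 1000 null
KOs (calibration) and 500 nulls + 1 causal (recovery), each over 10–20
seeds; the full paired design of 108 libraries (2 conditions × 6 passages ×
3 biological × 3 technical replicates); 50 genomes × 200 genes with a
2000-KO pool and 1000 permutations for the neighborhood test; 8 planted BGC
groups across 64 strains. These sizes were chosen so each statistical
property is measured with useful precision while the whole suite stays
interactive.

# Known limitations

* **Measurement noise vs short branches.** The PGLS t-test is exact when
  the phenotype is Brownian on the tree. The enrichment aggregate, however,
  carries i.i.d. measurement noise, and Yule (and real) trees contain
  near-zero terminal branches — e.g. strain pairs at ANI > 99%. Whitening
  divides tip contrasts by the square root of tiny branch lengths, so even
  noise_sd = 0.1 can dominate those contrasts and inflate type-I error well
  above nominal (we measure per-seed rates up to ~0.4 at study-like noise,
  against a calibrated ~0.05 for a pure Brownian phenotype). This is a
  property of the method, not of this implementation; it equally affects any
  BM-covariance regression of a noisy score over closely related strains.
  Hits between near-identical strains deserve particular caution.
  Measurement-error and Pagel's-λ style covariance adjustments are out of
  scope here.
* **Discrete permutation nulls.** Neighborhood counts are small integers;
  the ≥990/1000 rule is conservative at atoms, so the realized null hit rate
  sits at or below 1%.
* **Aggregate degeneracy.** The mean-over-SD aggregate is undefined for
  strains observed in fewer than two late-passage pairs or with zero score
  variance; such strains are dropped from scans, not imputed.
* **Grouping granularity.** The number of BGC groups is a configuration
  choice, not an estimate; the default reproduces the scale of the
  motivating analysis, and results at other cuts should be compared before
  interpretation.
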