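---
title: "stratpg: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stratpg: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stratpg` implements the full computational arc of a two-marker
phylogeographic study of island and mainland bird populations: classical
population-genetic summary statistics for mitochondrial sequence alignments
and nuclear microsatellite genotypes, coalescent-simulation-based scenario
choice by approximate Bayesian computation (ABC), and likelihood comparison
of time-stratified dispersal models on a dated lineage tree. This vignette
records the models, their assumptions, and every place where the design was
genuinely open and a choice had to be made.

## Sequence statistics

**Haplotype collapsing.** Identical sequences are grouped into haplotypes.
Samples missing data (gaps, `N`, IUPAC ambiguity codes) at more than 10% of
sites are excluded (threshold configurable); a partially missing sample
joins the first haplotype with which it conflicts at no jointly observed
site. First-fit assignment in sample order makes the grouping deterministic;
"identity over shared sites" is not transitive, so some rule of this kind is
unavoidable. Ambiguity codes are treated as missing because the original
analysis software's handling is not documented; treating them as missing is
the conservative choice.

**Diversity.** Haplotype diversity is Nei's unbiased estimator
$h = \frac{n}{n-1}(1 - \sum_i p_i^2)$ with Nei's sampling variance.
Nucleotide diversity $\pi$ is the mean proportion of differing sites over
all sequence pairs, with pairwise deletion of missing sites; its standard
deviation is Tajima's (1983) variance. On complete data the pairwise form
equals the per-site heterozygosity sum exactly, which the test suite checks
to 1e-12.

**Neutrality tests.** Tajima's D uses the standard constants from $S$,
sample size $n$, and mean pairwise differences. Fu's $F_s$ is computed from
the Ewens sampling formula: $S' = \Pr(K \ge k_{obs} \mid \hat\theta_\pi, n)$
with the signless-Stirling recurrence, and $F_s = \ln(S'/(1-S'))$. P-values
come from neutral coalescent simulation conditioned on $n$ and
$\hat\theta_\pi$ (default 1000 replicates, seed required); both are
lower-tail probabilities, so small values flag the star-like genealogies of
expansions. Monomorphic samples are reported as $D = F_s = 0$ with $p = 1$
rather than undefined, matching how such rows are conventionally printed.

**Distances.** The Tamura (1992) three-parameter distance corrects for
transition/transversion bias and GC content; the gamma variant replaces
$-\ln w$ by $a(w^{-1/a} - 1)$. The gamma shape is a user parameter because
the original study used locus-specific values (0.015 for COI, 0.306 for the
control region). Saturated pairs (non-positive logarithm argument) are
returned as `NA` with a warning rather than clamped.

**AMOVA.** $\Phi_{ST}$ comes from a one-level analysis of molecular
variance on squared inter-individual distances. The entries of the supplied
distance matrix are used directly as squared distances; the conventional
input is the matrix of pairwise difference counts, which is the squared
Euclidean distance in site space. The haplotype-frequency $F_{ST}$ uses the
same machinery with inter-haplotype distance fixed at 1. P-values permute
individuals among populations; the overall test and every pairwise test use
independent seeded streams, so single tests are reproducible in isolation.
Negative estimates are reported as computed, not clamped.

**FDR.** Pairwise tests are corrected with the Benjamini–Yekutieli step-up
procedure (valid under arbitrary dependence). The reported critical value
is the step-up threshold of the largest passing rank; for 15 simultaneous
tests at $\alpha = 0.05$ it is 0.0151, and for 15 microsatellite pairs at
the study's scale it reproduces the familiar "critical value ~0.012–0.015"
magnitudes.

## Microsatellite statistics

**Diversity.** Observed heterozygosity, Nei's unbiased expected
heterozygosity over $2n$ gene copies, and rarefied allelic richness by
hypergeometric subsampling of $g$ gene copies. The default $g = 2$ is
chosen because printed richness tables in compact study summaries are on
the $1 + H_e$ scale, and $AR(2) = 1 + H_e$ is an exact identity (used as a
cross-check between the two operations). Any other $g$ is available.

**Differentiation.** $F_{ST}$ is the bias-corrected $G_{ST}$ built from
Nei & Chesser (1983) small-sample estimators $\tilde H_S$, $\tilde H_T$
(harmonic-mean sample size, observed-heterozygosity correction). Hedrick's
$F'_{ST} = G_{ST}(k-1+H_S)/((k-1)(1-H_S))$ and Jost's
$D = \frac{k}{k-1}\,\frac{H_T-H_S}{1-H_S}$ correct the downward bias of
$G_{ST}$ when within-population heterozygosity is high — the reason the
study reports them alongside $F_{ST}$. Multilocus values combine loci as
ratios of locus-averaged $H_S$/$H_T$ (ratio of averages), not means of
per-locus ratios; the $G_{ST}$ family was chosen over Weir–Cockerham
$\theta$ because the standardized measures printed in the study are defined
on that family. Monomorphic loci contribute zero and are flagged.

**Bottleneck test.** For each polymorphic locus the equilibrium
heterozygosity distribution $H_{eq}$ conditional on the observed allele
count $k$ is simulated: $\theta$ is tuned by bisection so the expected
allele count matches $k$ (exactly via the Ewens formula for IAM, by pilot
simulation for SMM/TPM), then coalescent samples are retained when they
yield exactly $k$ alleles. The TPM default is 90% single-step mutations
with a geometric multi-step tail (parameter 0.5); the study does not state
its settings, so these are package defaults, configurable. Significance is
a one-tailed Wilcoxon signed-rank test across loci on the
probability-integral transform $P_\ell = \Pr(H_{eq} \le H_e)$ minus 1/2:
$P_\ell$ is uniform at mutation-drift equilibrium, whereas the raw
difference $H_e - \overline{H_{eq}}$ is anticonservative because the
conditional $H_{eq}$ distribution is left-skewed. The acceptance suite
verifies the calibration directly (empirical type-I rate at equilibrium
inside [0.01, 0.12]). Fewer than four usable loci flags the test as
low-power. A calibration fact worth knowing, also exercised by the
acceptance suite: under strict stepwise mutation the excess signal after
even a severe crash is structurally weak, while under the infinite-alleles
model the same crash is detected with useful power; real analyses
therefore run several mutation models and report significance under at
least one, as the study did.

**PCoA.** Classical scaling (double centering + eigendecomposition).
Negative eigenvalues are reported, axes are built from positive ones only.

## The synthetic world

The generator emulates the study design exactly: six populations with
mtDNA sample sizes 21/25/9/16/8/11 and microsatellite sample sizes
24/26/10/33/12/24; one maternally inherited non-recombining mtDNA locus of
652 + 377 = 1029 sites evolving under HKY+gamma; twelve unlinked diploid
microsatellite loci under a generalized stepwise model with reflecting
allele-size bounds (40 states). The mtDNA locus uses an inheritance scaler
of 0.25 relative to the diploid deme size; autosomal loci use 2.

The three demographic scenarios are event-based reconstructions (the
original appendix diagram is not reproduced in the available text, so the
topology below is this package's explicit reconstruction, labelled as
such):

* **H0** — all six demes split from one ancestor at a single recent time
  (U[0.01, 0.4] mya): no lasting structure.
* **H1** — three old regional lineages: the Insular deme splits at
  U[1.2, 2.5] mya and the Southeastern ancestor (Eastern Coastal +
  Southern) at U[1.7, 6.7] mya, both ranges taken from the study's dated
  phylogeny; splits within regions are recent (U[0.01, 0.4] mya); event
  ordering is enforced by rejection.
* **H2** — H1 plus an older Southern/Eastern-Coastal split (U[0.7, 1.5]
  mya) and recent admixture pulses from the Mainland into the Southern
  (proportion U[0.05, 0.5]) and, more weakly, Eastern Coastal
  (U[0.05, 0.25]) demes. Pulse times are U[0.002, 0.02] mya — the
  "recent erosion" the study describes is a late-glacial/Holocene signal,
  so pulse times older than ~20 kyr would contradict the stated history.

Times convert to generations at 2 years/generation (configurable). Deme
sizes have U[1e2, 1e5] priors; the mtDNA rate U[1e-8, 1e-6]/site/gen; the
microsatellite rate U[1e-4, 1e-3] with single-step probability U[0.8, 1].
HKY settings are fixed defaults (kappa 8, avian-like base frequencies,
gamma shape 0.25) since the summary statistics used downstream are nearly
insensitive to them. Ancestral segments keep the carrier deme's size.

What the generator does **not** emulate: recombination, selection,
sequencing error, null alleles and allele-dropout, uneven locus mutation
rates, and spatially continuous structure. A green simulation-based test
therefore establishes internal consistency of the pipeline under the
stated model, not robustness to those real-data complications.

The simulator is exact in the following senses, and tested as such:
uniformization makes the HKY jump process exact (one jump round per site
per Poisson event, using a state snapshot so later rounds never re-mutate a
site within the same round); the structured coalescent reduces to the
analytic two-lineage law ($E[T_2] = N$ under scaler 1); and a divergence at
time 0 or an admixture pulse with proportion 1 is distributionally
identical to the corresponding degenerate history.

## ABC scenario choice

The summary-statistic vector is fixed and ordered: per population, mtDNA
Tajima's D, mtDNA mean pairwise differences, and mean microsatellite genic
diversity; per population pair, mtDNA $\Phi_{ST}$, microsatellite $F_{ST}$
and Goldstein's $(\delta\mu)^2$. Undefined components (monomorphic data)
are imputed as 0, their zero-divergence limit, so vectors remain
comparable. Distances are Euclidean after dividing each statistic by its
median absolute deviation over the reference table (fallback SD, then 1);
the posterior probability of a scenario is its frequency among the $k$
nearest simulations (the direct estimator; the logistic-regression variant
is deliberately out of scope). Ties at the k-th distance break by stable
row order. Confidence is evaluated either by leave-one-out reuse of table
rows (cheap, default) or by fresh pseudo-observed simulations; the
misclassification matrix and overall error are reported. The reference
implementation's table size of 1e7 is replaced by a configurable desk-scale
size with an identical code path.

## Time-stratified dispersal models

Geographic range evolution on the dated tree uses the DEC family. States
are all non-empty subsets of the six areas (optionally capped in size; the
null range is included for extirpation paths but excluded from tips and the
root prior). Anagenetic rates: dispersal into area $a$ at
$d \sum_{b \in range} m_{ba}$ (per-epoch multiplier matrices $m$; the
multipliers scale dispersal only, never extirpation) and extirpation at
$e$. Cladogenesis: DEC allows single-area sympatry, subset sympatry and
narrow vicariance; DIVALIKE replaces subset sympatry with unrestricted
vicariance; BAYAREALIKE copies the parent range. Every distinct ordered
daughter pair enters once with weight 1; `+J` adds founder jumps to single
areas outside the parent range with weight $j$ (normalized per parent
state). Branches are segmented at epoch boundaries (6–3, 3–0.2, 0.2–0 mya
by default) and each segment uses its epoch's rate matrix via an
eigendecomposition-cached matrix exponential with a scaling-and-squaring
fallback. Root states are weighted uniformly over non-null states (the
study is silent on root treatment; this is the common default).

The three dispersal hypotheses are multiplier structures: H0 all-open; H1
open during colonization then a 0.01 multiplier between the three regions
until the present; H2 as H1 until 0.2 mya, then the Mainland/Southeastern
barrier dissolves while a new barrier separates the two southeastern areas.
Fits maximize over $d, e \in [10^{-12}, 5]$ (log scale) and $j \in [0, 3]$
with multi-start L-BFGS-B; models are compared by AIC and AICc (sample
size = number of tips) and Akaike weights across all 18 fits, summed per
hypothesis. AICc drives the default weights; with 14 tips AIC and AICc
order the models identically in practice.

The study's actual 14-haplogroup tree and tip ranges are not published in
machine-readable form, so the dispersal comparison is validated by
simulation: trees and range histories simulated under an H2-style
restricted-then-open process must hand H2 the largest summed weight in a
clear majority of replicates. The study's 86.6% weight is therefore a
qualitative, not numeric, target.

## Numerical choices and degenerate inputs

* Ultrametricity tolerance: max tip-age deviation 1e-6 x root age.
* AMOVA with zero total variance returns 0 (not NaN); populations of size
  one are dropped from pairwise tests.
* Permutation p-values use the add-one estimator $(1 + \#\{\ge obs\}) /
  (n_{perm} + 1)$.
* Saturated Tamura pairs are `NA` with a warning; they would otherwise
  poison downstream AMOVA silently.
* The GenePop dialect accepts 2- or 3-digit coding per file, never mixed
  within a locus; `000`/`00` alleles are missing.
* All randomness flows from integer seeds through small linear-congruential
  stream derivation, keeping every derived seed below 2^31.

## Known limitations

* Scenario choice between H1 and H2 is power-limited by prior overlap: an
  H2 dataset drawn with an admixture proportion near the lower prior bound
  (0.05) and a small recipient deme is observationally equivalent to H1
  under the fixed summary-statistic set, which caps H2 recovery rates at
  desk-scale reference tables (the acceptance suite measures the rate
  honestly rather than relaxing its bar). The same structural overlap
  appears in the dispersal-model comparison whenever no cross-region
  dispersal event happens to fall inside the short most recent epoch.
* The scenario topologies and priors are reconstructions of an appendix
  that is unavailable in the source text; they are the package's defaults,
  not verbatim study settings.
* Fu's $F_s$ p-values are simulation-based and slightly conservative for
  very small samples.
* The bottleneck test's conditioning-by-rejection can be slow for loci
  whose observed allele count is very unlikely at equilibrium; the
  implementation caps attempts and warns.
* DEC state spaces above ~8 areas are refused (exponential growth); the
  study design needs 6.
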