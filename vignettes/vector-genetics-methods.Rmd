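---
title: "Methods: vector-driven connectivity and microsatellite population genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vector-driven connectivity and microsatellite population genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vecgen)
```

# The question and the inference chain

Invasive coastal species spread between harbours largely on human vectors.
If vessel traffic drives that spread, the *directional* pattern of
port-to-port transits should predict the *directional* pattern of recent
gene flow among established populations. `vecgen` implements the complete
chain for testing this with diploid microsatellite panels:

1. descriptive diversity and differentiation statistics per population,
2. Bayesian clustering to delineate genetic groups,
3. assignment-based directional migration estimation (a non-equilibrium
   gene-flow measure — unlike F~ST~, it does not assume
   migration–drift equilibrium, which young invasive populations violate),
4. bottleneck screening, to exclude drift-dominated explanations of
   divergence,
5. rank-based Mantel correlation between (possibly asymmetric) matrices:
   genetic distance, geographic distance, migration, and vector intensity.

Because the real collections behind such studies are rarely deposited, the
package includes a first-class synthetic-data module: a forward-time
Wright–Fisher simulator whose migration exactly follows a supplied
directed network. All validation is ground-truth-based: simulate under a
known vector, then ask each stage to recover it.

# Statistical components

## Diversity statistics

For a group with $n$ gene copies at a locus carrying allele counts $n_j$:

* unbiased gene diversity $H_E = \frac{n}{n-1}\bigl(1 - \sum_j p_j^2\bigr)$,
  the probability that two copies drawn *without* replacement differ;
* rarefied allelic richness
  $A_R(g) = \sum_j \bigl[1 - \binom{n-n_j}{g}\big/\binom{n}{g}\bigr]$,
  the expected allele count in a standardized subsample of $g$ copies.
  The conventional depth is 18 individuals, i.e. $g = 36$; loci with fewer
  nonmissing copies are excluded from the group mean with a warning;
* Weir–Cockerham variance components give the within-population fixation
  index $f = 1 - \sum c / \sum(b + c)$ and pairwise
  $\theta = \sum a / \sum(a+b+c)$, combined over loci and alleles by
  ratio-of-sums. Negative estimates are kept by default: truncation would
  bias the rank-based matrix tests that consume the F~ST~ matrix
  (a `truncate` switch exists for display).

Missing genotypes are excluded locus-wise; no imputation. Whether
published tables of this kind use Nei's unbiased or plain gene diversity
is often unstated; the unbiased form is used throughout and documented
here as the package's choice.

## Bayesian clustering and ΔK

The sampler fits the no-admixture model: each individual belongs wholly
to one of $K$ clusters whose allele frequencies carry independent
Dirichlet(1) priors. A sweep draws frequencies from
$\mathrm{Dirichlet}(1 + \text{counts})$ and then each individual's label
from its full conditional under within-cluster Hardy–Weinberg
proportions. The admixture and correlated-frequency extensions used by
the well-known reference implementation are deliberately out of scope:
for discrete, well-separated clusters the no-admixture model suffices,
runs orders of magnitude faster, and no equivalence with that software's
output is claimed. Default chain lengths (burn-in $10^3$, $10^4$ sweeps)
are scaled down from the $10^5/10^6$ conventional for field data but are
configurable to those values.

Model choice uses the replicate-run summary
$L(K) = \overline{\ln L} - \mathrm{var}(\ln L)/2$ and Evanno's
$\Delta K = |L(K{+}1) - 2L(K) + L(K{-}1)| / \mathrm{sd}(L(K))$, maximised
over interior $K$. Two cautions, both visible in our experiments and both
well known for this statistic: it cannot evaluate the endpoints of the K
ladder, and under hierarchical or unequal divergence it tends to flag the
*top* level of structure. The clustering-recovery experiment therefore
uses equally divergent demes (see *Founder schemes* below); on such data
five replicate runs at moderate length select the true $K$ reliably.
Label switching across replicate runs is repaired by greedy matching of
membership columns against the first run.

## Assignment and the directional migration matrix

The source likelihood of a multilocus genotype in a candidate cluster is
the Rannala–Mountain posterior-predictive probability under a
$\mathrm{Dirichlet}(1/k)$ prior, with $k$ the dataset-wide allele count
at the locus: for cluster counts $n_j$ out of $n$ copies,

$$P(\text{het } j_1 j_2) = \frac{2(n_{j_1} + 1/k)(n_{j_2} + 1/k)}{(n+1)(n+2)},
\qquad
P(\text{hom } jj) = \frac{(n_j + 1/k)(n_j + 1 + 1/k)}{(n+1)(n+2)}.$$

Alleles unseen in a cluster keep prior mass, so no genotype has zero
likelihood anywhere. Leave-one-out removal of the focal individual from
its home-cluster counts is on by default (it removes self-inclusion bias
in small samples) and switchable off. Ties are broken by cluster label
order and flagged.

Directional gene flow from cluster $i$ to cluster $j$ is then estimated
as the proportion of individuals sampled in $j$ whose modal assignment is
$i$ — rows are sources, columns recipients, columns sum to one. Whether
self-assigned individuals belong in the denominator is ambiguous in the
field; both variants are computed (`excludeSelf`), the full matrix being
the default while the correlation engine simply ignores diagonals.

## Bottleneck tests

A recent demographic collapse leaves transient *heterozygosity excess*:
allele count drops faster than gene diversity, so observed $H_E$ exceeds
the equilibrium expectation for the surviving allele count. The package
simulates that conditional equilibrium distribution by standard
coalescent genealogies with two-phase mutation (TPM): steps are single
repeats with probability $1 - p$, otherwise $2 + \mathrm{Geom}(q)$
repeats with a symmetric sign, with $p = 0.10$ and step variance 12 by
convention (the variance convention is flagged as configurable because
published studies often leave it unstated). The mutation parameter
$\theta$ is calibrated by bisection so the mean simulated allele count
matches the observed $k$, then only replicates with exactly $k$ alleles
are retained. A pure-SMM oracle ($H = 1 - 1/\sqrt{1+2\theta}$) validates
the simulator.

Across loci, observed and equilibrium diversity are combined by a
Wilcoxon signed-rank test — exact by full $2^L$ enumeration (with
midrank handling) up to 20 loci, normal approximation with continuity
correction beyond. All three tails are reported, since studies rarely
state which tail they ran.

**A numerical choice that matters.** The conditional distribution of $H$
given $k$ is left-skewed, so $P(H_{\text{obs}} > \bar H_{\text{eq}})
\approx 0.56$–0.60 *at equilibrium*; pairing observations against the
conditional mean therefore inflates the one-tailed excess test to
roughly twice its nominal size — we measured 8–12% at nominal 5%, even
on null-by-construction panels. `bottleneckTest()` consequently pairs
against the conditional *median* by default (measured size ≈ 4% at
nominal 5%), while still reporting the mean, SD and standardized
difference DH per locus; `center = "mean"` restores the mean-paired
variant.

The qualitative companion check pools allele frequencies into ten classes
of width 0.1: at equilibrium the histogram is L-shaped with the rare
class `(0, 0.1]` as strict mode; a *mode shift* is the classic
founder-event signature.

## Rank-based Mantel tests for asymmetric matrices

Vector intensity and migration matrices are directional; classical Mantel
machinery assumes symmetry. The engine here mid-rank transforms all
$n(n-1)$ off-diagonal cells of each matrix (for symmetric matrices both
copies of a pair get equal ranks, so using the full off-diagonal set is
equivalent to using one triangle), computes $R$ as the Pearson
correlation of ranks (Spearman), and builds the null by applying a
uniformly random label permutation jointly to the rows and columns of the
second matrix: $P = (\#\{\text{permuted} \ge \text{observed}\} + 1) /
(n_{\text{perm}} + 1)$. Permuting either matrix is statistically
equivalent (property-tested). 9999 permutations is the default; an exact
mode enumerates all $n!$ permutations for small label sets and is the
oracle used in the tests. The default tail is `greater` — the published
use of such tables reports near-1 $P$ values for negative correlations,
implying a one-tailed test toward positive association. Matrices are not
converted between similarity and distance conventions; signs are
interpreted by the user. Cluster exclusion slices both matrices *before*
ranking, so excluding a label is identical to testing pre-sliced
matrices.

# The synthetic-data generator

## What it emulates

The generator reproduces the study design scale: 13 sampling sites
grouped into 8 port clusters (sites of one cluster are one deme, split at
sampling — consistent with finding no differentiation within clusters),
per-site sample sizes 18–58, 10 microsatellite loci, heterozygote
deficits from partial selfing, and a northern cluster (`PS`) optionally
founded as an independent introduction.

Each generation, every newborn in deme $j$ is a migrant from deme $i$
with probability $m \cdot w_{ij} / \sum_i w_{ij}$ — migration is
*exactly* proportional to the supplied directed network, which is the
point: the acceptance surface is recovery of a directed network, which a
coalescent simulator cannot express as directly. Mutation follows the
same TPM used by the bottleneck module (shared code, shared defaults),
with allele sizes reflected at a floor of one repeat.

## Founder schemes

Deme founder frequencies diverge from a shared ancestral pool (geometric
frequency profile, 5 allele states, mild cross-locus Dirichlet
variability) by one of two mechanisms:

* **swap** (default): each adjacent pair of frequency *ranks* is
  exchanged with probability `founderDivergence`. A permutation leaves
  $\sum p_j^2$ — hence founder gene diversity — exactly unchanged, so
  demes differentiate in *which* alleles are common without scattering
  their heterozygosity. This matters for calibration: Dirichlet-style
  founder draws at the divergence needed for realistic F~ST~ spread
  per-deme $H_E$ far outside the narrow envelope real surveys report.
  Biologically it mimics serial introductions drawn from one diverse
  source pool.
* **rotate**: deme $i$ receives the ancestral vector cyclically rotated
  by $i$ ranks — five demes become equally, strongly divergent
  (pairwise $\theta \gtrsim 0.3$), the star-like geometry on which ΔK
  behaves well. Used by `clusterScenario()`.

The outlier deme additionally receives `outlierNovelFraction` of founder
mass on novel allele states at a random ~30% of loci (an independent
introduction carries alleles absent from the regional pool; keeping them
rare and restricted to a locus subset yields a private-allele share near
8–12% of the dataset's distinct alleles, mostly at low frequency), uses
a higher rank-swap intensity, and — critically — exchanges migrants at a
rate damped by `outlierIsolation` regardless of its vector edges. That
deliberate mismatch between the *shipping* matrix (which retains strong
hub edges) and *realized* gene flow is the masking effect the exclusion
analysis is designed to detect; it is the package's model of an
independent introduction, not a claim about any particular harbour.

## Calibration

Defaults were calibrated once so that an 8-deme default run lands most
clusters inside the envelope typical of regional surveys of this kind —
rarefied richness ($g = 36$) ≈ 3.4–4.1, gene diversity ≈ 0.53–0.59,
$F_{IS}$ ≈ 0.18–0.36 via selfing rate 0.4 ($F_{IS} = s/(2-s) = 0.25$ at
equilibrium) — while keeping enough differentiation (mean pairwise
$\theta \approx 0.1$) for assignment tests to be informative:
`demeSize = 300`, `generations = 12`, `migrationScale = 0.01`,
`mutationRate = 5e-4`, `founderDivergence = 0.18`,
`ancestralDecay = 0.385`. Published sources for such systems give no
effective population sizes or divergence times; these are calibration
choices, documented as such, and not revisited per analysis. Sampling
noise alone (18–58 individuals, 10 loci) moves per-cluster $H_E$ by
±0.02–0.03, so a minority of clusters falling outside the envelope in
any one replicate is expected — the validation experiments therefore
assess envelope coverage over replicate panels.

Scenario presets deviate from the defaults only where the experiment
needs it: `recoveryScenario()` raises divergence (0.7) and migration
(0.06) so that sampled migrants are both present and assignable, and uses
`dominantEdgeNetwork()` — heavy-tailed background traffic with three
corridors boosted to 2.5× their recipient's remaining inbound weight, the
structure of real port systems where a few routes dominate;
`outlierScenario()` keeps a moderate signal (m = 0.05) so that one
discordant hub can tip the correlation below significance.

## What passing tests do and do not show

The generator omits, by design: isolation-by-distance in the founder
structure (geographic distance enters only as an analysis input),
overlapping generations and age structure, null alleles and genotyping
error beyond missingness, within-cluster site substructure, and any
oceanographic larval transport. Success of the validation experiments
shows the *inference chain* recovers vector-driven structure when the
generating model is vector-driven — it cannot show that any real dataset
was generated that way.

# Numerical and design notes

* Problem sizes in the shipped experiments: 484-individual panels for
  calibration and contrast runs; clustering over $K = 1..7$ with five
  replicate chains of 1,900 sweeps on 100 individuals; 500-replicate
  calibration studies for both permutation tests; 50-replicate recovery
  and exclusion experiments. These are the package's validation scale —
  all are plain function arguments.
* Bottleneck equilibrium distributions are cached per (n, k) within a
  run; with study-scale panels the distinct pairs number a few dozen.
* The Gibbs sampler and coalescent simulator use R's RNG (via Rcpp), so
  `set.seed()` governs every result; the pipeline derives per-stage
  substreams from its single master seed, and identical seeds reproduce
  reports byte for byte.
* Exact Wilcoxon enumeration doubles midranks to stay on an integer
  lattice; the cap of 20 informative loci keeps the $2^L$ distribution
  cheap; study-scale data have 10.
* Degenerate inputs: monomorphic loci are skipped by F-statistics and
  bottleneck tests (they carry no information); all-missing genotypes
  yield likelihood 1 in assignment (uninformative, never an error); an
  all-tied off-diagonal matrix is rejected by the Mantel engine rather
  than returning an undefined correlation.

# Known limitations

* The no-admixture sampler is not a replacement for admixture-model
  software when real populations mix continuously; memberships here are
  posterior label frequencies, not ancestry fractions.
* ΔK inherits its known biases (endpoint blindness, top-level-structure
  preference); the Evanno table is reported in full so users can inspect
  the L(K) curve rather than trust the argmax.
* The heterozygosity-excess test's median pairing is conservative
  (measured ≈ 4% at nominal 5%); users replicating mean-paired published
  software behaviour should set `center = "mean"` and expect inflation.
* Mantel tests on matrices derived from the same genotypes (F~ST~ and
  migration) are not independent of each other; the table is descriptive,
  as in the literature this package serves.
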