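---
title: "Multiallelic mixed-model QTL mapping in polyploid multiparental populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiallelic mixed-model QTL mapping in polyploid multiparental populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`polyqtl` tests genomic loci for association with a quantitative trait in
autopolyploid populations whose structure comes from a limited set of known
founders — the typical situation in outbreeding crop breeding programmes,
where several connected crosses share parents. Its distinguishing feature is
the side-by-side support for a *biallelic* marker parametrization (SNP
allele dosages) and two *multiallelic* parametrizations (true
identity-by-descent founder alleles, and haplotype blocks assembled from
phased SNPs), within one mixed-model genome-scan machinery. The package
also contains the full simulation stack needed to study when multiallelic
models pay off: tetraploid meiosis, ancestral-population drift, nested
association mapping (NAM) population construction, additive phenotypes and
a power-evaluation framework.

# The statistical model

Every locus is tested under the Q+K mixed model

$$ y = X\beta + Qv + Zu + \varepsilon, \qquad
   \mathrm{Var}(u) = K\sigma^2_G, \quad \mathrm{Var}(\varepsilon) = R\sigma^2_\varepsilon $$

where $y$ are phenotypes, $X\beta$ the tested marker effects, $Qv$ optional
fixed structure covariates (off by default — the kinship term carries the
structure correction), $u$ a polygenic random effect with
realized-relationship covariance $K$, and $R$ a diagonal matrix of
reciprocal observation counts ($I$ for the one-observation-per-genotype
designs simulated here; `weights` exposes the general case).

**Fixed term.** For a biallelic SNP the incidence matrix is an intercept
plus the dosage (0..ploidy) of one SNP allele — a purely additive
parametrization with a single effect parameter. For a multiallelic locus
with $k+1$ alleles, the incidence matrix carries the dosages of all alleles
*except one* reference allele, giving $k$ effect parameters expressed
relative to the reference. We take the most frequent allele as the
reference (ties broken by lexicographically smallest label): dropping the
most common allele keeps the retained columns maximally informative. A
monomorphic locus yields an intercept-only design and is flagged with
$p = 1$ rather than dropped, so scans stay positionally complete.

**Random term.** $K = DD^\top/\Delta$ with $\Delta$ the mean diagonal of
$DD^\top$, computed from column-centered dosages; by construction the mean
diagonal of $K$ is exactly 1 and $K$ is positive semidefinite. $D$ is
matched to the marker system under test: SNP dosages for the biallelic
scan, concatenated non-reference allele-dosage columns for the multiallelic
scans (the same columns the incidence matrices use). To mitigate
marker-density bias, $D$ uses loci thinned to one per cM: per chromosome,
the nearest locus to each integer-cM gridpoint. No leave-one-chromosome-out
correction is applied, so the tested locus contributes to $K$; this
*proximal contamination* conservatively shrinks peak heights, and matters
for interpreting absolute power levels (see *Parameter choices* below).

**Variance components and the scan.** $\sigma^2_G, \sigma^2_\varepsilon$
are estimated once by REML on the no-marker null model and recycled at
every locus (the EMMAX / P3D approximation). The restricted likelihood is
profiled in one dimension over the variance ratio
$\delta = \sigma^2_\varepsilon/\sigma^2_G$ via a spectral decomposition of
the null-projected kinship; we decompose $P(K+I)P$ rather than $PKP$ so the
informative eigenpairs stay separated from the null space of the projection
even for singular $K$ (e.g. clone or family-block covariances). The search
runs a 100-point coarse grid on $\log\delta \in [-10, 10]$ followed by
derivative-free refinement to tolerance $10^{-8}$; the unit test suite
checks the optimum against a 1000-point grid and against `lme4` on an
equivalent random-intercept model. Each locus is then tested with a
generalized least-squares F-test of the joint null that all its allele
effects are zero: numerator df = rank of the tested columns after
projection (rank-deficient columns dropped, singular-value tolerance
$10^{-10}$), denominator df = $n - $ rank of the full design. When
$\sigma^2_G = 0$ the test reduces exactly to the ordinary ANOVA F-test,
which the tests assert to $10^{-8}$.

**Significance.** Genome-wide thresholds come from phenotype permutation:
$y$ is permuted across individuals, variance components are re-estimated
under each permuted null (the conservative choice; recycling the observed
components is the cheaper alternative), the genome-wide maximum
$-\log_{10}p$ is recorded, and the empirical $1-\alpha$ quantile is the
threshold. Defaults: 100 permutations, $\alpha = 0.05$. On independent
loci this reproduces the Šidák closed form within Monte-Carlo error.

# Marker systems

* `snp` — integer dosage of the "B" SNP state per individual and marker.
* `ibd` — each marker becomes a multiallelic locus whose alleles are the
  founder (IBD) labels observed there; dosages sum to the ploidy. In
  simulations the labels are known truth; the package deliberately does
  *not* infer IBD from marker data.
* `hap` — haplotype blocks from a sliding window of 6 consecutive phased
  SNPs with overlap 4 (step 2; blocks start at SNP 1, 3, 5, ... per
  chromosome; trailing SNPs that cannot fill a window are dropped; windows
  never span chromosomes). A block's alleles are the distinct 6-state
  strings observed on homologues — at most $2^6 = 64$ — and its position is
  the mean of the member SNP positions. Window and overlap are tunable
  (`window`, `overlap`, in SNP counts). Rare haplotype alleles are *not*
  merged into the reference by default; merging is available but off, since
  the reference behaviour keeps every observed allele testable.

Phase is taken as known (simulation truth). Real-data haplotyping requires
statistical phasing whose uncertainty would erode the haplotype model's
performance; results obtained here are therefore an upper bound for
phased-SNP haplotypes on real data.

# From scans to QTLs, and scoring against truth

A QTL interval is a maximal chain of significant markers in which each pair
of *adjacent significant* markers lies strictly closer than the linking
distance $l$ (cM); non-significant markers in between do not break a chain,
chains never bridge chromosomes (cross-chromosome distances are treated as
unlinked, returned as `Inf`, which compares greater than any finite $l$),
and single-marker chains are discarded as isolated. The interval peak is
its most significant member, leftmost on ties. Because the choice of $l$ is
arbitrary, power sweeps run $l$ from 0 to 10 cM in 0.5 steps; with $l = 0$
the strict inequality chains nothing.

Against simulated truth (the three major QTLs only; polygenic loci are
deliberately *not* counted as true positions):

* an interval is a **true positive** iff its range contains a true QTL
  position (the realized position, i.e. the map marker the effect was
  snapped to);
* **detection power** = fraction of true QTLs covered by at least one
  true-positive interval (covered once counts once);
* **false-positive rate** = significant markers outside the ±5 cM bands
  around true positions, divided by all markers outside those bands (the
  marker-level window rule);
* **QTL / marker precision** = true-positive intervals (or their markers)
  over all detected intervals (or all interval markers) — the
  interval-level rule, so the two false-positive notions intentionally
  coexist;
* **peak accuracy** = mean distance from a true-positive interval's peak to
  the contained true position.

Undefined metrics (no intervals, no true positives, no outside-band
markers) are reported as absent (`NA`), never as zero, so replicate
averages stay honest.

# The simulator

**Meiosis.** Autopolyploid, bivalent-only: per meiosis and chromosome the
ploidy homologues are paired uniformly at random into ploidy/2 bivalents
(no preferential pairing, no quadrivalents, no double reduction), and each
bivalent yields one chromatid by a two-state Markov walk along the ordered
markers, switching between the paired homologues with the Haldane
probability $r = \tfrac12(1-e^{-2d/100})$ per interval — no crossover or
chromatid interference. Full four-chromatid bookkeeping is not modelled:
only the marginal gamete law matters downstream, and under no chromatid
interference the one-chromatid walk has exactly that law. The walk is
implemented in C++ (the inner loop of every simulation) but draws from R's
RNG, so `set.seed()` makes entire pipelines bit-reproducible.

**Ancestral groups.** 10 founders per group receive fair-coin SNP states
and 40 globally unique founder labels (one per homologue). Random mating
without selfing (uniform ordered pairs of distinct parents, redrawn per
offspring, no monogamy) at constant size 100 for 50 generations drifts the
40 labels down to a handful per locus; the acceptance suite checks the
average lands in the 12.5–13.5 alleles-per-locus band.

**NAM populations.** One central parent crossed to 9 peripheral parents,
50 offspring per cross, parents included: 460 individuals. The 10 parents
are sampled without replacement across `diversity_k` ancestral groups with
counts as equal as possible; the central parent always comes from the group
providing the most parents, ties broken by lowest group index (the design
is silent on ties). Replicate populations reuse one fixed pool of 10
ancestral groups — regenerating the pool per replicate would confound
diversity with pool sampling — and draw their seeds as base seed plus an
arithmetic offset.

**Phenotypes.** At each major QTL every contributing ancestral group draws
an allelic mean from $N(0, \sigma^2_{AG})$ and each founder label an effect
from $N(\text{mean}, \sigma^2_{within})$; 50 polygenic loci placed
uniformly on the map get per-label effects. Phenotype = sum of the 4
carried allele effects at every effect locus + Gaussian noise. Strictly
additive; invariant to permuting an individual's homologues. QTL positions
are snapped to the nearest map marker so arbitrary positions stay legal.

# Parameter choices and what they imply

The published effect-sampling constants for the motivating study are in a
supplement that is not reproduced here, so the package fixes explicit
stand-ins, chosen once: $\sigma_{AG} = 1$, $\sigma_{within} = 0.5$,
polygenic loci rescaled to contribute 30% of genetic variance, residual
noise set for broad-sense $h^2 \approx 0.6$. Two consequences deserve
emphasis when comparing desk-scale numbers with the full-scale study:

* With $\sigma_{AG} > \sigma_{within}$, most allelic variance at high
  diversity is *between* ancestral groups, hence between families — exactly
  the variance the kinship term absorbs. Together with the total-$h^2$
  calibration (which inflates $\sigma_\varepsilon$ as between-group
  variance grows), high-diversity populations carry markedly less usable
  within-family signal per QTL than low-diversity ones. The qualitative
  ordering (multiallelic ≥ biallelic, power falling with diversity) is
  robust to this; absolute detection-power levels at diversity 7–10 are
  sensitive to it and sit below the full-scale study's values under these
  stand-ins.
* Because the tested locus also contributes to the matched kinship (no
  leave-one-chromosome-out, mirroring the original procedure), peaks are
  conservatively shrunk; this is visible as the large gap between ordinary
  least-squares and mixed-model $-\log_{10}p$ at the simulated QTLs.

The synthetic map defaults to 3509 markers on five chromosomes of
115/96/88/106/80 cM (485 cM total — unequal lengths are required for a QTL
at 100.49 cM on chromosome 4). Major QTLs default to chromosome 1 at
67.88 cM, chromosome 2 at 61.2 cM, chromosome 4 at 100.49 cM.

**Desk scale.** `desk_config()` is the reduced design used by the test
suite and the reproduction script: the first 2 chromosomes (1404 markers,
211 cM), 5 replicate populations per diversity level (3 in the test
suite), 50-permutation thresholds, the 2 on-map major QTLs and 20 polygenic
loci (preserving genome-wide density). These sizes were chosen so a full
sweep runs on a single core in minutes while keeping per-population sample
size (460) and marker density at study levels; shrinking the genome rather
than the population preserves per-locus test behaviour at the cost of
noisier replicate averages and a kinship more dominated by QTL-bearing
chromosomes.

# Numerical and degenerate-input behaviour

* Variance weights in the GLS whitening are floored at $10^{-12}$;
  negative eigenvalues of $K$ (numerical noise) are clamped to zero.
* Rank decisions use QR with tolerance $10^{-10}$; a locus whose columns
  add no rank beyond the null design gets $p = 1$ and an `untestable`
  flag.
* An all-constant dosage matrix makes the kinship undefined
  ($\Delta = 0$) and errors; an all-monomorphic scan yields a degenerate
  permutation threshold of 0.
* Duplicate map positions are allowed (co-segregating markers); they chain
  at any $l > 0$ since their distance is 0.
* Phenotype files must cover every genotyped individual; dosages outside
  $[0, \text{ploidy}]$ and malformed phase tokens are rejected with row
  addresses.

# Known limitations

Quadrivalent pairing, double reduction and preferential pairing are out of
scope, as are dominance/epistasis, multi-trait phenotypes, statistical
phasing, IBD inference from markers, composite interval mapping and
LOD-drop support intervals. The haplotype results assume error-free phase.
Power estimates at desk scale carry Monte-Carlo noise from few replicates
and a 2-chromosome genome; the full-scale configuration
(`experiment_config()`) reproduces the study design exactly but needs
hours, not minutes.
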