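# polyqtl

Mixed-model QTL mapping for autopolyploid multiparental populations, with
**biallelic and multiallelic marker models side by side**, plus the
simulation and power-evaluation machinery needed to compare them.

## The problem

In a biparental diploid cross, two alleles segregate per locus and a
biallelic SNP regression describes a QTL well. In the populations breeders
actually have — connected crosses sharing founders (multi-parental / nested
association mapping designs), at higher ploidies — a locus can carry up to
`ploidy × founders` functional alleles. A single SNP then lumps several
allele effects into two dosage groups, diluting both detection power and
positional precision. `polyqtl` tests each locus under the Q+K mixed model

    y = Xβ + Qv + Zu + ε,   Var(u) = K σ²_G,   Var(ε) = R σ²_ε

with three interchangeable fixed-term parametrizations:

| model | incidence columns per locus | marker system |
|-------|-----------------------------|---------------|
| `snp` | 1 (dosage 0..ploidy of one SNP allele) | biallelic SNP dosages |
| `ibd` | n_alleles − 1 (founder-allele dosages, reference dropped) | true identity-by-descent labels |
| `hap` | n_alleles − 1 (haplotype dosages) | 6-SNP sliding-window haploblocks (overlap 4, ≤ 2⁶ = 64 alleles) |

`K` is the realized relationship `K = DD′/Δ` (Δ = mean diagonal of `DD′`),
built from loci thinned to one per cM and matched to the marker system
(concatenated allele-dosage columns for the multiallelic models). Variance
components are estimated once by spectral-decomposition REML and recycled
at every locus (EMMAX/P3D); each locus gets a GLS F-test of the joint null
that all its allele effects are zero. Genome-wide thresholds come from
phenotype permutation (Churchill–Doerge), QTL intervals from a
linking-distance chain rule (adjacent significant markers closer than `l`
cM; isolated markers ignored), and power/precision/accuracy are scored
against simulated truth.

The simulator covers the whole study design: bivalent-only autotetraploid
meiosis under the Haldane mapping function (C++ inner loop, R RNG),
ancestral groups of 10 founders drifted 50 generations at size 100, NAM
populations (1 central × 9 peripheral parents, 50 offspring per cross, 460
individuals) with 1–10 ancestral groups of parental diversity, and additive
phenotypes (per-group allelic means, per-allele effects, 50 polygenic loci,
h² ≈ 0.6).

## Worked example

```r
library(polyqtl)
set.seed(42)

map <- synthetic_map(1404, c(115, 96))          # 2 chromosomes, 211 cM
ags <- simulate_ag_pool(10, map)                 # 10 AGs, 50 generations drift
mean(founder_allele_counts(ags[[1]]))            # founder alleles surviving per locus

nam <- build_nam(ags, diversity_k = 1)           # 460 individuals, 1 AG
qt  <- qtl_spec(data.frame(chromosome = c("1", "2"),
                           position_cM = c(67.88, 61.2)),
                n_polygenic = 20, map = map)
eff <- assign_effects(nam, qt)
y   <- phenotype(nam, eff)

ma  <- ibd_loci(nam)                             # multiallelic true-IBD encoding
K   <- kinship_for(ma)
des <- scan_design(ma)
sc  <- scan_qtl(des, y, K)                       # EMMAX scan
th  <- permutation_threshold(des, y, K, n_perm = 50)
iv  <- call_intervals(sc, th$threshold, l = 3)
power_report(sc, th$threshold, qtl_positions(qt, map), l = 3)
```

This run prints:

```
> mean(founder_allele_counts(ags[[1]]))
[1] 14.34402
> iv
2 QTL interval(s) at l = 3 cM, threshold 3.202
  chromosome start_cM   end_cM n_markers peak_marker  peak_cM peak_neglog10p
1          1 66.27870 67.81300        10     c1_m473 67.81300       5.277642
2          2 56.51666 63.70602        32     c2_m416 61.24201      13.565512
> power_report(sc, th$threshold, qtl_positions(qt, map), l = 3)
  model l threshold detection_power false_positive_rate qtl_precision
1   ibd 3  3.202412               1                   0             1
  marker_precision peak_accuracy_cM n_intervals n_tp_intervals
1                1                0           2              2
```

Of the ~13–14 founder alleles surviving drift at a typical locus, the scan
recovers both simulated QTLs: a 10-marker interval on chromosome 1 and a
32-marker interval on chromosome 2 whose peaks coincide with the realized
(marker-snapped) QTL positions — detection power 1, no false positives,
peak accuracy 0 cM. `qtl_positions()` converts nominal QTL coordinates to
the map markers the effects were actually placed on.
`run_experiment(desk_config())` sweeps diversity levels × replicates ×
models × linking distances and aggregates the same metrics into a
Table-1-style summary (`summarize_experiment()`).

A thin command line mirrors the R surface
(`simulate | threshold | scan | call | power | plot`):

```sh
Rscript inst/scripts/polyqtl.R simulate --diversity 1 --replicates 1 --seed 7 --out sim/
Rscript inst/scripts/polyqtl.R scan --map sim/map.csv --genotypes sim/pop01_phased.csv \
    --phenotypes sim/pop01_phenotype.csv --model hap --out scan.csv
```

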