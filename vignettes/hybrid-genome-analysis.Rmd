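---
title: "Hybrid genome analysis with malus: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid genome analysis with malus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(malus)
```

The cultivated apple arose through hybridization of two wild species,
*Malus sieversii* and *M. sylvestris*, followed by clonal propagation. Its
diploid genome is therefore a mosaic: along each chromosome, the two
haplotype complements ("haplomes") switch between tracts inherited from one
or the other progenitor. This vignette explains the statistical models
behind each analysis in the package, the tunable parameters and their
defaults, what the synthetic-data generators do and do not emulate, and the
design decisions taken where several reasonable choices existed.

## Ancestry painting

### Model

For a fixed window (default 50 kb) on the target genome we observe, from
projected whole-genome alignments, the number of aligned columns and
mismatches against each progenitor reference. The mismatch proportion $p$
is corrected for multiple substitutions at a site with the one-parameter
Jukes–Cantor model,

$$ d = -\tfrac{3}{4}\,\ln\!\left(1 - \tfrac{4}{3}p\right), $$

which assumes equal base frequencies and exchange rates. The correction is
strictly increasing, dominates the identity ($d \ge p$) and saturates at
$p = 3/4$; windows at or beyond saturation are treated as having undefined
divergence.

A window is assigned to the progenitor with the smaller corrected
divergence when two conditions hold **strictly**:

* the smaller divergence is below `max_assignable_divergence` (default
  0.014, i.e. 1.4% — the genome-wide mean of the larger of the two window
  divergences in this system, so windows farther from *both* references
  than a typical interspecific distance stay unassigned);
* the absolute difference of the two divergences exceeds `min_difference`
  (default 0.002 = 0.2%, the lower bound of the mean divergence difference;
  windows where the references are indistinguishable stay unassigned).

Windows with less than `min_aligned` bp of alignment (default 100 bp) are
never classified. Boundary equalities yield "unclear": with bounds phrased
as "must be below/above", the conservative reading excludes ties. By
default only the smaller divergence must pass the assignability bound,
because the bound describes the winning divergence; `both_bounded = TRUE`
is available for the stricter reading.

Runs of identically classified windows merge into ancestry tracts. The
interval between the last window of one origin and the first window of a
different origin — including any unclear windows in between — is reported
as a candidate recombination site. Fractions are weighted by window bp
(terminal windows may be short), matching a "% of genome" interpretation;
both all-window and classifiable-only denominators are reported for the
diploid hybrid fraction, since the choice of denominator is a genuine
ambiguity.

Two further conventions: coordinates are 0-based half-open everywhere
except VCF/GFF I/O (interval arithmetic safety; BED on output), and when a
block spans a window boundary its counts are pro-rated by overlap length
with mismatches rounded half-up at the window level. Divergence-track
smoothing for plots uses a tricube-weighted local-linear (loess) fit with a
span of 2% of windows — display only, never used in classification.

### Sensitivity

`sensitivity_scan()` repeats the projection and painting over window sizes
of 5–70 kb and minimum-alignment cutoffs of 100–1,000 bp and reports the
largest spread of the origin fractions. On simulated mosaics the spread
stays within ~2 percentage points, so conclusions do not hinge on the 50-kb
default.

## Synthetic data

The generators produce inputs with the statistical structure the analyses
assume, plus the ground truth needed to score them.

* **Progenitor pair** (`simulate_progenitor_pair()`): a uniform random
  ancestral genome; the number of differing sites per chromosome is a
  binomial draw at the interspecific divergence (default 0.014, the
  progenitor-pair distance in this system), sites are drawn without
  replacement and each difference is assigned to a random lineage. The
  realized p-distance is therefore binomial around the target.
* **Hybrid diploid** (`simulate_hybrid_diploid()`,
  `simulate_mosaic_truth()`): each haplome switches ancestry at window
  boundaries with probability `window_size / tract_length_mean`
  (memoryless, hence geometric tract lengths). The default mean tract
  length is 5 Mb — several tracts per chromosome arm, the scale of the
  discrete ancestry blocks seen in hybrid cultivars. Independent
  intraspecific drift (default 0.006, ~0.8%, the within-species divergence
  scale; configurable because it is inferred rather than directly measured)
  is applied per haplome, so same-origin haplome pairs diverge at roughly
  twice that rate, mimicking the low-divergence regions of real
  comparisons.
* **Window observations** (`simulate_window_observations()`): a fast path
  that skips sequences entirely and draws per-window mismatch counts
  binomially: a window of true origin *sieversii* has expected mismatch
  proportion `intraspecific` against the *M. sieversii* reference and
  `intraspecific + interspecific` against the other (branch divergences
  add at these scales); boundary windows use the bp-weighted mixture.
* **Coverage** (`simulate_pav_coverage()`): covered fractions at depth ≥ 2
  are drawn directly (Beta around the Poisson-implied mean
  $1 - e^{-\lambda}(1+\lambda)$) rather than via read placement, since the
  PAV rule consumes only the fraction. Planted absences draw strictly below
  0.20, present genes above 0.20 plus a margin.
* **Allelic counts** (`simulate_ase_counts()`): negative-binomial counts
  (default dispersion 0.05, a typical RNA-seq value) with log-normal gene
  depths and a planted per-gene, per-stage log2 allelic ratio; the default
  stage axis is the 13 fruit stages at 11–127 days after full bloom with 3
  replicates.
* **Genotypes** (`simulate_genotype_matrix()`): a deterministic fixture
  mode reproducing exact genotype-class counts (used for locus case
  studies) and a stochastic Hardy–Weinberg mode.

All generators run off a single integer seed through fixed sub-streams
(`(seed mod 10^6)·2011 + stream·7919`), so adding one generator never
perturbs another and identical seeds give bit-identical outputs.

**What the generators do not emulate** — and hence what passing tests do
not establish about real data: indels and structural variation inside
alignments (divergence is substitution-only), alignment dropout correlated
with repeats, reference bias, tract-length heavy tails from recent
pedigree structure, linkage disequilibrium in the genotype matrices, and
read-level artifacts (mapping bias, PCR duplicates) upstream of the allelic
count tables. Because truth tracts switch at window granularity, simulated
windows are never split across ancestries except by explicit construction,
so boundary-window behavior is exercised by dedicated mixed-window tests
rather than by the default mosaics.

## Population genetics

Nucleotide diversity uses the unbiased per-site pairwise-difference
estimator $2\hat p\hat q\,n/(n-1)$ over the non-missing haplotypes of each
site, summed per window and divided by the full window length in bp
(VCFtools-style; `per_accessible = TRUE` divides by the number of sites
instead — the choice is documented because conventions differ). Tajima's
$D$ follows the 1989 definition with constants from the fixed haplotype
count; sites with missing genotypes are excluded from $D$ (not from π) so
the constants remain exact, and windows with fewer than 3 segregating
sites or 4 haplotypes are reported as `NA` rather than dropped. Windows
slide by 1 kb over a 20-kb width by default.

The p-distance between diploid samples is the mean over shared non-missing
sites of half the allele-dosage difference. Heterozygote–heterozygote
comparisons contribute 0 under this dosage metric; this is a declared
convention, not a claim of bit-compatibility with any particular distance
tool. Missing genotypes are excluded pairwise, maximizing data use.
Neighbor-joining follows Saitou–Nei with a deterministic lowest-index-pair
tie break; negative branch lengths are clamped to zero with the deficit
moved to the sibling branch, preserving path lengths through the join.
Reported percentages round half away from zero to one decimal, matching
conventional reporting of allele frequencies.

Site filters follow the common GATK/VCFtools practice: hard-filter
exclusion rules (`QD < 2`, `QUAL < 60`, `SOR > 3`, `FS > 60`, `MQ < 40`,
`MQRankSum < −12.5`, `ReadPosRankSum < −8`, and ≥ 5 reads supporting each
allele) with missing annotations never failing their condition, and
population filters of MAF ≥ 0.05, QUAL ≥ 30 and ≤ 10% missing genotypes
(all boundaries inclusive; the filter is idempotent).

## Pan-genome PAV

Presence calls use the strict `< 20%` covered-fraction rule; exactly 20% is
present. Orthogroups are present when any member gene is present. Pan/core
accumulation curves are summarized by the **median** over random accession
orderings (default 100; means are available from the quantile columns'
machinery if needed — medians are robust to the long tail produced by rare
accession-private genes). The curves are fitted with
$P(N) = A\,N^{\gamma} + C$, the standard saturating power law for
pan-genomes: the conditionally linear $A, C$ are solved exactly on a grid
of $\gamma$ values in $(0, 1.5]$ and the best start is polished by
Levenberg–Marquardt. A pan-genome is flagged *closed* when
$\gamma < 1$ and the fitted slope at the largest sampled $N$ is below 0.5
genes/accession — a pragmatic operational criterion, since "closed" is an
asymptotic statement.

Favored-orthogroup detection runs one Fisher's exact test per orthogroup
and species pair on presence counts, with Benjamini–Hochberg correction
applied within each species-pair family. Categories combine directions:
"favored in domestica and sylvestris versus sieversii" requires
domestica > sieversii **and** sylvestris > sieversii significance;
"domestica-only" requires significance against both wild species and
neither wild-pair pattern. Groups significant in only one pairwise test
fall into `none` — the category rules are declared rather than inferred,
and deliberately conservative. Segment deduplication
(`dedupe_segments()`) is a greedy longest-first containment clustering
(k-mer screen plus local alignment, 90% identity over 90% of the shorter
segment); it approximates the redundancy-removal step of dedicated
clustering tools without claiming identical output.

## Allele-specific expression

Read assignment accepts a haplome when its alignment score is no worse and
its mismatch count no higher, with at least one comparison strict (the
"one-strict" rule; `strict_both = TRUE` gives the harsher conjunction —
the two readings differ only for score/mismatch ties). Undecided reads are
rescued by majority vote over the phased SNPs they overlap; ties stay
ambiguous, and each read is counted exactly once or not at all. Phasing
uses the two haplome alleles directly when both are observed and distinct,
and imputes the missing side as the remaining allele of the biallelic call
otherwise.

The ASE test is a negative-binomial Wald test built from first principles
rather than delegated to a count-model package, keeping the calling rule
self-contained: per gene, dispersion $\phi$ is estimated by the method of
moments, $\hat\phi = (s^2 - \bar x)/\bar x^2$, pooled across stage ×
allele cells; per gene and stage the log ratio of replicate-mean counts
(0.5 pseudo-count, used for reporting and stabilization) is compared to
zero with the delta-method standard error
$\sqrt{((1/\mu_A + \phi) + (1/\mu_B + \phi))/n}$. P-values are BH-adjusted
**within each stage** (cross-stage multiplicity is not additionally
corrected: each stage is its own contrast family). A call requires both
adjusted $p < 0.05$ and an observed imbalance above twofold — applying the
fold criterion to the raw ratio as well as requiring Wald significance
avoids calling marginally-estimated large ratios at low counts. Gene ×
stage combinations where any replicate total is ≤ 10 are excluded; with a
single replicate (as at the earliest fruit stage, which had only two in
the motivating design) the test falls back to an exact binomial test with
a warning. The caller is exactly antisymmetric under allele swap.

Enrichment of hybrid-ancestry genes among ASE genes uses a two-sided
Fisher's exact test (sample odds ratio reported alongside the conditional
MLE); SV proximity uses the Mann–Whitney U test with tie correction,
exact enumeration for small tie-free groups, and p = 1 for degenerate
all-tied input.

## Numerical choices and degenerate inputs

* Jukes–Cantor: `log1p`/`expm1` forms for accuracy near zero; round trip
  $p \to d \to p$ accurate to $10^{-12}$; saturation ($p \ge 0.75$) is an
  error for the scalar API and `NA` (unclassifiable) inside window tables.
* Window projection resolves doubly-aligned target bp by first-block
  precedence with a warning; empty block sets require explicit chromosome
  lengths and yield all-unalignable grids.
* NJ ties are broken by the lowest index pair in scan order, making output
  independent of floating-point vagaries on symmetric inputs.
* Power-law fitting warns and returns $A = 0$ on flat curves rather than
  failing.
* All RNG-restoring wrappers leave the caller's random state untouched.

## Validation scale

The test suite validates π, Tajima's D, Fisher and Mann–Whitney p-values
against explicit enumeration oracles on small random inputs (up to 10
haplotypes × 50 sites, 2×2 margins ≤ 30, group sizes ≤ 6), neighbor
joining against 50 random 8-taxon additive trees, and the end-to-end
ancestry painting on ten simulated 10-Mb diploid mosaics (100 Mb in
total, 50-kb windows, default divergences) — sizes chosen so the whole
suite documents the pipeline's behavior at desk scale while remaining
quick to run. Dataset-level counts from real resequencing data (millions
of SNPs, tens of thousands of orthologues) are outside desk scale by
design: the acceptance checks target the *procedures*, not the published
dataset.

## Known limitations

* The Jukes–Cantor model ignores transition/transversion bias; at the
  1–2% divergences involved the correction is nearly linear and the
  ranking of the two divergences — all that classification uses — is
  unaffected.
* The dosage p-distance and the PAV-based tests treat sites and genes as
  independent; linkage and shared assembly errors are not modelled.
* The method-of-moments dispersion with 3 replicates is noisy; pooling
  across stages mitigates but does not remove this, and the Wald normal
  approximation is anticonservative in the extreme tails at very low
  counts (hence the additional fold-change requirement).
* The greedy segment deduplication is order-dependent by construction
  (longest first) and approximate relative to exhaustive clustering.
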