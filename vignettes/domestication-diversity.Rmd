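---
title: "Scanning domestication series for diversity loss and haplotype turnover"
author: "DomestiScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning domestication series for diversity loss and haplotype turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DomestiScan)
```

# The analysis in one paragraph

Domestication pushes a crop through a demographic bottleneck and
through episodes of strong artificial selection. Both leave measurable
traces in a panel of resequenced accessions ordered from wild
progenitor to modern cultivar: diversity (π) drops genome-wide in the
derived populations, and drops *locally much harder* where selection
acted, while differentiation (F~st~) between the wild and derived
groups rises in the same regions. DomestiScan computes these
statistics in genomic windows, calls candidate selective regions from
their joint upper tails, catalogues each gene's haplotypes to see
*which* variant was favoured, and cross-references QTL intervals,
tissue-specificity and orthology to rank candidate genes. A built-in
simulator generates panels with exactly this structure so that every
stage is testable end to end.

# The statistical core

## Nucleotide diversity

At a biallelic site with `nref` reference and `nalt` alternate
haplotypes, diversity is the mean pairwise difference
π~site~ = nref·nalt / C(n, 2), algebraically equal to the unbiased
heterozygosity (n/(n−1))·2p(1−p). Window values sum the per-site
diversities and divide by the window span in bp, so monomorphic and
uncalled positions contribute zero — the convention of the common
windowed-diversity tools, chosen so results are comparable with them.
The default window is 50 kb; the step defaults to the window (a
tiling), because a sliding-window analysis whose step is unstated is
most reproducible as non-overlapping tiles. Both are arguments
(`windowBp`, `stepBp`). The trailing window of a chromosome is
truncated and scaled by its actual span.

## F~st~

We use Weir & Cockerham's (1984) estimator from the per-site variance
components a (among populations), b (among individuals within
populations) and c (within individuals), computed from diploid
genotypes including the heterozygosity term, since panel samples are
diploid. The windowed ("weighted") estimate is Σa / Σ(a+b+c) over the
usable sites of the window; sites with zero total variance carry no
information and are skipped. Negative per-window estimates are
reported as computed rather than clamped: clamping would bias the
genome background upward and distort the quantile thresholds
downstream. `wcSiteComponents()` exposes the raw a/b/c per site so any
window can be audited; the test suite checks the components against an
independent ANOVA-route derivation (MSP/MSI/MSG mean squares) and
checks the fixed-difference limit (F~st~ = 1) and the permutation null
(mean near 0) exactly.

## Sweep calling

For each contrast (wild vs domesticated for domestication, earlier vs
later domesticate for improvement) the per-window π ratio and F~st~
are ranked and a type-7 (linear-interpolation) quantile threshold at
q = 0.95 defines the top 5% of each. The selection rule is
value ≥ threshold, so ties at the threshold are included. Two
top-tail criteria can be combined two ways and the convention is
genuinely open; we default to the **intersection** (a window must be
extreme in both statistics), the stricter reading and the one that
matches how joint π-ratio/F~st~ screens are usually practised, with
`rule = "union"` available. At q = 1 the top-0% tail is empty by
definition and nothing is called. Windows with too few segregating
sites (`minSites`, default 1) or zero denominator diversity are
flagged insufficient and excluded from ranking rather than given
arbitrary ratios. Adjacent selected windows merge into regions; genes
map into regions by any base-pair overlap.

## Haplotype catalogues

For each gene we take the panel SNPs in the gene body ±2 kb (matching
the promoter/downstream convention below, so upstream, downstream,
CDS and UTR variants are all captured) and build, per sample, a
*diplotype string*: the two phased allele letters at each site,
concatenated in genomic order — two letters per site, e.g. `CCAACCAA`
for four sites. Within a site the two letters are written
alphabetically, which makes the string independent of haplotype phase
ordering; published per-subgroup percentages are consistent with
counting samples (not haploid genomes), and that is what we count.
Frequencies are per subpopulation; the **major haplotype** is the
class carried by strictly more than 50% of the subpopulation's
samples — strictness matters (a 50/50 split has no major) and
guarantees uniqueness. `trackMajorShifts()` walks an ordered lineage
series and reports every consecutive pair whose major differs,
including transitions between "no major" and "some major"; genes with
no major anywhere count toward totals but produce no events.
Percentages are displayed rounded half-up to two decimals; all
comparisons use full precision.

## Molecular evolution

Ortholog pairs come from reciprocal best hits on a BLAST-like
similarity table (E ≤ 10⁻⁵; score ties broken by E-value then subject
id, so the best hit is unique). Rates are estimated with the
Nei–Gojobori (1986) counting method: per-codon synonymous site counts
(each position contributes the fraction of its three possible changes
that are synonymous; changes to stops count as non-synonymous)
averaged over the two sequences; observed within-codon differences
resolved by averaging over all shortest substitution pathways,
excluding pathways through stop codons (falling back to all pathways
in the degenerate case where every pathway is blocked); Jukes–Cantor
correction d = −(3/4)·ln(1 − 4p/3), undefined (flagged "saturated")
at p ≥ 3/4. A counting estimator was chosen deliberately over a
maximum-likelihood codon model: it is self-contained, exactly
testable against hand computation, and adequate in the dS < 0.3
regime to which the pair set is restricted anyway (`orthologDnDs()`
flags dS ≥ 0.3 pairs as excluded). dN/dS at dS = 0 is reported as
undefined, not infinity. Divergence time is T = dS/(2λ)·10⁻⁶ Mya
with λ = 6.5×10⁻⁹ synonymous substitutions per site per year, the
standard grass clock; the formula is linear in dS and 1/λ, and maps
dS of 0.01–0.02 to 0.77–1.54 Mya. Orthogroups are classified by
A:B:D subgenome member counts ("1:1:1" triads, singletons, and the
general a:b:c label).

## Expression

The tissue-specificity index is computed on x̂ⱼ = log₂(FPKM_j + 1):

τ = Σⱼ (1 − x̂ⱼ / x̂~max~) / (n − 1)

The +1 offset pins both boundary behaviours: a uniformly expressed
gene has every x̂ⱼ = x̂~max~ and τ = 0 exactly, and a gene expressed
in a single library has every other term equal to 1, so τ = 1. The
result is clamped to [0, 1] against floating noise. A gene counts as
expressed with FPKM > 0 in at least `minLibraries` libraries; the
two natural readings ("at least one" vs "more than one") both occur
in practice, so the threshold is an argument with default 1.

Profiles are clustered by Ward-linkage hierarchical clustering
(`ward.D2`, Euclidean) on per-gene z-scored log₂(FPKM+1), cut at
k = 7 by default; hierarchical clustering was chosen over k-means
because it is deterministic, which matters for reproducible reports.
Flat profiles get z = 0 rather than NaN. Family-in-cluster enrichment
is the one-sided hypergeometric tail P(X ≥ overlap) with the
expressed genes as universe, BH-corrected across all
(family, cluster) pairs, significant at FDR < 0.05; the test suite
verifies the p-values against exhaustive enumeration for universes up
to 12. Co-expression partners are ranked by Pearson correlation of
log profiles (ties by gene id, self excluded) — an intentionally
transparent stand-in for network intramodular-connectivity rankings,
and labelled as such.

## Integration

`colocateQtl()` applies the any-overlap rule — a gene is potentially
related to a trait if it overlaps a QTL for that trait; QTL intervals
are coarse, so boundary overlap counts. `prioritizeCandidates()` does
no weighting or scoring beyond counting evidence flags, because the
underlying logic is set intersection: the headline tier is the genes
carrying all four evidence classes (selective region ∩ QTL ∩ major
haplotype ∩ expressed), and the rest of the report orders genes by
how many flags they carry, then id, deterministically.

# Coordinates, formats and conventions

All internal interval work uses GenomicRanges, i.e. 1-based inclusive
coordinates — the native convention of both VCF and GFF3, so import
and export are lossless with no shifting. Region boundary semantics
follow from interval overlap: a gene starting one bp past a region's
end does not overlap it. The promoter is 2,000 bp upstream of the
TSS, strand-aware, and the downstream flank is symmetric at 2,000 bp;
no universal definition of a plant promoter exists and 2 kb is the
common convention, so both are flag-configurable and genic status
always beats a neighbouring gene's flank (nearest TSS, then
lexicographic gene id, breaks the remaining ties). GFF3 gene models
keep only the first (lowest-sorting) transcript variant per gene.
VCF input must be fully phased (`|` separators) and biallelic SNPs
only; multi-allelic and non-SNP records are skipped with a reported
count, and unphased or missing calls are a hard error because
imputation is out of scope.

# The simulator: what it emulates, and what it does not

The generator produces the statistical structure the pipeline
consumes, not a genealogical simulation:

* **Sites** are placed uniformly and derived-allele counts drawn from
  the neutral frequency spectrum (P(count = i) ∝ 1/i), assigned to
  haplotypes by permutation. Sites are therefore unlinked and
  exchangeable — there is no recombination map, no LD, no coalescent
  tree.
* **Bottlenecks** draw founder haplotypes without replacement and
  apply Wright–Fisher resampling for a set number of generations;
  diversity loss scales with founder count, as the tests verify.
* **Sweeps** overwrite a target fraction of haplotypes with a donor
  haplotype inside the region — the diversity/differentiation
  signature of a sweep without hitchhiking dynamics or partial
  linkage decay at the edges.
* **The default pedigree** mirrors a nine-subpopulation wheat panel
  (wild einkorn 31, domesticated einkorn 31, urartu 29, wild emmer
  28, domesticated emmer 29, durum 13, landrace 45, cultivar 25,
  Ae. tauschii 30), with founder counts and drift generations as
  fixture choices; subgenomes are modelled as labelled chromosomes,
  not as homoeologous copies.
* **Expression** has three ground-truth classes — uniform,
  single-library and graded (log-normal around a peaked profile) —
  chosen to pin τ's boundary behaviours and give clustering
  something real to find.

Passing tests on this generator therefore demonstrate correctness of
the statistics and the pipeline plumbing under a clean neutral model
with implanted signals. They do not demonstrate robustness to
missing data, unphased or error-prone calls, linkage, gene
conversion, admixture or reference bias, all of which real
resequencing panels contain.

## The reference validation scenario

`defaultSweepFixture()` fixes the package's reference conditions: two
populations of 20 diploid samples, five 1-Mb chromosomes, 2,000
segregating sites per chromosome (one per 500 bp, a plausible genic
SNP density for a diverse wild panel), a 12-founder bottleneck with
10 generations of drift, and one 50-kb sweep implanted at donor
frequency 0.95. Under these conditions the acceptance suite requires
the intersection rule at q = 0.95 to recover the implanted region in
at least 90% of 40 seeded replicates. The suite's other problem
sizes (toy panels up to 20 haplotypes × 200 sites for the brute-force
π oracle, universes ≤ 12 for enrichment enumeration, 50 random codon
pairs for the dN/dS oracle) are chosen so that exhaustive
re-computation is feasible and exact.

# Numerical and degenerate-input policy

* Quantile thresholds: type 7, selection by ≥, q = 1 selects nothing.
* π at fewer than two haplotypes: undefined, site skipped.
* F~st~ windows with no usable site: NA, flagged insufficient.
* π ratio with zero denominator: NA + insufficient, never Inf.
* τ of an all-zero profile: NA (the index is undefined without
  expression); τ clamped to [0, 1].
* JC correction at p ≥ 3/4: NA with a "saturated" flag.
* dN/dS at dS = 0: NA, not Inf.
* Haplotype display percentages: round half-up, 2 dp, display only.
* All generators and the clustering are deterministic given their
  seed/inputs; identical configurations produce byte-identical
  exported fixtures.

# Known limitations

* The sweep scan is window-based π-ratio/F~st~ only; no
  haplotype-length statistics (EHH/iHS), no composite-likelihood
  models, no XP-CLR.
* The simulator's unlinked-sites assumption means window statistics
  are less autocorrelated than in real genomes; merged multi-window
  regions are correspondingly rarer than in real scans.
* dN/dS is a pairwise counting estimate; no among-site rate
  variation, no branch or site models.
* Co-expression neighbours are plain correlation ranks, not a
  weighted-network analysis.
* Phasing is taken as given; there is no imputation, and multi-allelic
  sites are dropped rather than decomposed.
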