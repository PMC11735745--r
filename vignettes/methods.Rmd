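---
title: "Models and methods behind popgenpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popgenpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenpanel)
```

popgenpanel analyses multi-sample genotype panels from small, structured
populations. This vignette explains the models behind each stage, the
parameters that matter, the design choices made where several reasonable
conventions exist, and what the simulation-based tests do and do not show
about real data.

## The data model

A `gt_panel` stores a site-by-sample matrix of genotype codes (0 hom-ref,
1 het, 2 hom-alt, −1 missing), variant metadata, a sample-to-population
map, and a ploidy table. Haploid cells (males on the non-pseudoautosomal
X; the default non-PAR interval is chrX:2,364,962–151,635,290 in rheMac10
coordinates, overridable when reading a VCF) carry codes 0/2 only. Phase
is deliberately discarded: no statistic in the package is
haplotype-aware, so `0|1` and `0/1` are the same observation. Missing
genotypes are stored, never imputed; each estimator documents its own
exclusion rule.

## The simulator: drift on a tree

The generator is the package's reference experiment: it produces panels
whose true parameters are known, so every estimator can be tested for
parameter recovery rather than against opaque fixtures.

Ancestral alternate-allele frequencies are drawn from Beta(0.2, 0.2)
truncated to [0.05, 0.95]. The truncation keeps variants common, which is
what a polymorphism panel ascertained from a sequenced cohort looks like
after filtering, and keeps Hudson-type estimators well conditioned at
moderate site counts. Frequencies then evolve along a user-supplied
population tree (newick, branch lengths in generations) by hierarchical
Balding–Nichols draws: along a branch of length $t$ at effective size
$N$, the child frequency is

$$p_c \sim \mathrm{Beta}\!\left(p\frac{1-F}{F},\ (1-p)\frac{1-F}{F}\right),
\qquad F = 1 - e^{-t/2N}.$$

The draw is mean-preserving and has variance $F\,p(1-p)$; drift along
consecutive branches compounds as $F_{1:2} = 1-(1-F_1)(1-F_2)$. X-linked
sites use $N \cdot x_\mathrm{factor}$ (default 0.75, the neutral
expectation when both sexes have equal effective size and migration), so
the X drifts 4/3 as fast and the Q statistic below has expectation 0.75
by construction. Admixture events replace a target tip frequency with
$(1-\alpha)p_\mathrm{target} + \alpha p_\mathrm{source}$. Genotypes are
Hardy–Weinberg draws within populations; X-linked male genotypes are a
single allele draw.

Under this model the expectation of Hudson's ratio-of-averages estimator
for a pair of populations is the mean of the two compounded path drifts
from their most recent common ancestor,
$\mathrm{FST} = (F_a + F_b)/2$: the per-site numerator has expectation
$(F_a+F_b)\,p_0(1-p_0)$ and the denominator $2\,p_0(1-p_0)$, so the ratio
is free of the ancestral-frequency density. The simulation truth table
records this quantity per pair and per chromosome set, and the
parameter-recovery tests check the estimator against it at FST 0.05–0.4.

Sites are unlinked. None of the in-scope statistics requires linkage;
LD pruning is exercised through an optional "tag pair" flag that
duplicates sites at the adjacent position with identical genotypes
(r² = 1). Consequently the block jackknife's robustness to *real* local
linkage is exercised only structurally (unequal blocks, per-chromosome
boundaries), not against a recombining genome — a deliberate limit of the
generator, as are the absence of selection, of sequencing error in
genotypes, and of ascertainment bias. Pedigree relatives are added by
independent per-site Mendelian transmission; autozygous tracts are
planted by forcing a single population-frequency allele draw across an
interval; depth matrices are negative-binomial with optional
doubled/halved-mean outlier sites.

## Site filters

**Mappability.** The (k, e) score at a position is the reciprocal of the
number of positions whose k-mer lies within Hamming distance e; the
filter keeps score-1 (unique) positions, conventionally (30, 2). The
implementation is brute force over the forward strand by design — it is
the oracle the tests need on kilobase-scale synthetic genomes, not a
genome-scale FM-index tool; callers emulating strand-aware scoring can
append the reverse complement.

**Accessibility.** Total depth across samples is computed per site, the
mode of its distribution found (ties broken toward the smaller depth,
which is the conservative choice for inflated-coverage artefacts), and
sites within [mode/2, 2·mode], both ends inclusive, are retained. The
band always contains the mode.

**Hard filters.** Threshold rules are (class, key, comparator, threshold)
rows; a variant fails if *any* rule for its class fires on a *present*
annotation. Absent annotations never remove a site — the observable
behaviour of expression-based filtering engines on missing fields — but
are counted. The default rule set is the GATK-style one (SNVs:
QD < 2, QUAL < 30, SOR > 3, FS > 60, MQ < 40, MQRankSum < −12.5,
ReadPosRankSum < −8, ExcessHet > 30; indels: QD < 2, QUAL < 30, FS > 200,
ReadPosRankSum < −20, ExcessHet > 30). The three filters commute; masks
are combined by intersection.

## Kinship and pruning

KING-robust (between-family) kinship is used because its third-degree
threshold is the standard $2^{-7/2} \approx 0.0884$. Pruning is greedy:
while any pair sits at or above the threshold, the sample in the most
such pairs is removed, ties broken toward the later sample in panel
order. Greedy maximum-degree removal is deterministic and minimal in
practice; which member of a related pair is dropped is not specified by
the external tools this mirrors, so the package documents its own rule.
LD pruning works in windows of 50 variants sliding by 5 (counts, not kb),
removing the later variant of any pair with r² > 0.5; zero-variance
variants are kept. Removing the later rather than the lower-MAF variant
is again a determinism choice.

## Diversity and runs of homozygosity

Individual heterozygosity is het calls over the *accessible-site*
denominator (all filter-passing positions, not just variants), making it
a per-base-pair rate comparable across cohorts. Nucleotide diversity uses
the unbiased per-site form $2\hat p(1-\hat p)\,n/(n-1)$ with $n$ the
observed allele count.

The ROH caller is a two-state HMM over one sample's genotyped sites:
state HW emits heterozygotes at $2p(1-p)(1-\varepsilon)+\varepsilon'$
given the site's population alternate frequency $p$, state AZ at
$\varepsilon_{az}$; homozygous emissions are the complements. All three
error terms default to $10^{-3}$. Transition probabilities scale with
physical distance, $1-e^{-\rho d}$, with $\rho_{\mathrm{HW}\to\mathrm{AZ}}
= 6.6\times10^{-9}$ and $\rho_{\mathrm{AZ}\to\mathrm{HW}} =
5.0\times10^{-9}$ per bp — conventional values exposed in `params`, since
external ROH tools do not document a single canonical set. Segments are
the maximal runs of AZ in the Viterbi path, spanning first to last AZ
site (not midpoints to flanking sites; deterministic and conservative).
Segment quality is $-10\log_{10}(1-\bar\gamma)$ with $\bar\gamma$ the
mean forward–backward AZ posterior over the segment's sites, capped at
99. Because the mean includes the soft posterior shoulders at segment
edges, long segments rarely exceed quality ~25–30 unless their boundaries
are sharp; the downstream filter keeps segments with quality ≥ 30 *and*
length ≥ 100 kb (boundary values kept, so "below 30" and "shorter than
100 kb" are what is removed). Allele frequencies default to panel-wide
empirical values; a per-population frequency vector can be supplied.
Viterbi output is verified against exhaustive path enumeration on ≤ 12
site instances, and planted 500-kb tracts are recovered with ≥ 90%
overlap.

## Differentiation

Per-site Hudson components are
$N_i = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1}$
and $D_i = p_1(1-p_2)+p_2(1-p_1)$; the genome-wide estimate is
$\sum N_i / \sum D_i$ — always the ratio of averages, never the average
of per-site ratios, which is biased at low-information sites. Sites
where either population has fewer than two observed alleles are skipped
and counted. Standard errors come from a delete-one-block weighted
jackknife (Busing's formula) over contiguous blocks of 25,000 variants
by default; blocks never span chromosomes, and the short final block per
chromosome enters with proportional weight. The weighted form reduces to
the classic delete-one formula for equal blocks, which the tests verify
against brute-force leave-one-out recomputation.

Population-specific FST compares a target population against the pooled
remainder; the upper 1% tail of defined per-variant values is designated
"population-specific", with ties at the cut-off value all included (an
operational designation, so inclusivity was chosen for determinism).

The Q statistic is $Q = \ln(1-\mathrm{FST}_A)/\ln(1-\mathrm{FST}_X)$:
$-\ln(1-\mathrm{FST})$ is the accumulated drift on each chromosome set,
so Q is the autosome-to-X drift ratio, 0.75 under sex-symmetric
demography and smaller when female-mediated gene flow is rarer than
male-mediated flow. The result is flagged undefined when either FST lies
outside (0, 1) — near-fixed pairs make the log ratio unstable, which is
encoded rather than guessed at.

## f-statistics

f4(A,B;C,D) averages $(p_A-p_B)(p_C-p_D)$ over sites where all four
populations have at least one observed allele; outgroup f3(O;A,B)
averages $(p_O-p_A)(p_O-p_B)$. Sites are unweighted (weight 1 each) —
external implementations differ in their internal weighting and the
simplest convention is used and stated. The same weighted block jackknife
supplies SE and Z. Exact identities (antisymmetry; the cyclic identity
f4(A,B;C,D)+f4(A,C;D,B)+f4(A,D;B,C)=0) hold to numerical precision on
any panel and are tested that way. A single individual can stand as a
population, with frequencies in {0, 0.5, 1}. At desk scale, jackknife
blocks of 500 variants are used in tests (a 25,000-variant convention on
a 25,000-site simulation would leave a single block and no SE).

## Loss-of-function bookkeeping

A site is *species-specific derived* when every outgroup sample is
homozygous reference with no missingness — "unambiguously" is read as a
no-missingness requirement, the strictest defensible interpretation.
Because the simulator designates the ancestral allele as the reference
allele, this polarization is exact on simulated panels. LoF classes are
frameshift, stop_gained, splice_acceptor, splice_donor (splice_region is
deliberately excluded; the set is configurable). Variants fixed in the
focal cohort (every sample hom-alt, no missingness) are separated from
segregating ones; per-individual burden counts homozygous segregating
LoF variants split by SNV/indel, and the gene burden counts distinct
genes with at least one LoF allele (het or hom, fixed or segregating) —
multiple transcripts and multiple variants per gene collapse to the gene
level.

## Distances and trees

The genotype distance averages per-site allele-sharing distances over
sites genotyped in both samples: identical homozygotes 0, opposite
homozygotes 1, heterozygote against anything 0.5. The het–het value of
0.5 is the stated convention; the remaining cells follow allele-sharing
logic. A consequence worth noting: two identical genomes with
heterozygous sites are *not* at distance zero — their distance is half
their shared het fraction. Monomorphic shared sites contribute 0 and
dilute distances proportionally; `polymorphic_only = TRUE` restricts to
segregating sites. Pairwise deletion means per-pair site sets differ;
`n_sites_used` is exposed so imbalance is visible.

Neighbor joining delegates to the standard Saitou–Nei implementation in
ape, then deterministically clamps negative branch lengths to zero,
transferring the excess to the sibling branch so path lengths are
preserved. Distance matrices export to PHYLIP and to a nexus DISTANCES
block consumable by split-network software; trees export to newick.

## Pipeline and reproducibility

`run_pipeline()` chains simulate/read → hard-filter → kinship pruning →
LD pruning → diversity and ROH → FST/Q tables → population-specific
outliers with LoF intersection → f3/f4 → distances and NJ tree, writing
one TSV per stage and a JSON manifest (root seed, derived per-stage
seeds, stage counts, md5 of every output). All randomness flows from the
single root seed, so identical config + seed reproduce byte-identical
tables.

## Problem sizes and what the tests show

The test suite runs at desk scale: panels of 2,000–50,000 sites and
8–40 diploids, 2–50 seeds per property. At these sizes the analytic
expectations are sharp enough to test against: Q is recovered within 0.05
of 0.75 at 50,000 sites per chromosome set; FST within 3 jackknife SE of
truth at FST 0.05–0.4; jackknife SE within 20% of the across-seed SD;
planted ROH recovered at ≥ 90% overlap; parent–offspring kinship within
[0.20, 0.30]. Passing these shows the estimators are correct under the
generative model's assumptions (unlinked sites, Balding–Nichols drift,
Hardy–Weinberg genotypes, clean genotype calls). It does not demonstrate
robustness to linkage disequilibrium, genotyping error, ascertainment
bias or inbreeding within populations — on real panels those enter
through the block jackknife (linkage), the site filters (call quality)
and the user's choice of frequency sets for the ROH caller.
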