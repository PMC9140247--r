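---
title: "Candidate-gene SNP analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene SNP analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinesnp)
```

`pinesnp` is a pipeline for single-gene SNP studies in outcrossing tree
populations: one candidate gene is resequenced across a panel of trees, its
diversity and linkage structure are characterized, per-SNP associations
with a quantitative trait are tested, and the resulting TagSNPs drive a
genotype-combination marker-assisted selection (MAS) scheme. This vignette
explains the statistical machinery, every tunable that matters, the
synthetic-data generator, and the design decisions taken where the design
was genuinely open.

## Data model

Four inputs describe a study (`read_fasta_alignment()`,
`read_genotype_table()`, `read_gene_model()`, `read_trait_table()`):

* an **alignment** of the gene across haplotypes (rows are gametic-phase
  sequences; diploid consensus rows with IUPAC ambiguity codes are
  accepted for storage but refused by the sequence statistics — the
  treatment of heterozygous Sanger traces varies between tools, so this
  package makes phase an explicit contract rather than a silent guess);
* a **gene model**: exon intervals, which exons are coding, and the frame
  offset; all coordinates are 1-based and inclusive, and SNP positions
  always refer to the original (pre-indel-filter) reference coordinates;
* an **unphased diploid genotype table** at named SNP loci. Locus labels
  follow the minor-allele + major-allele + position convention
  (e.g. `CG615`: minor C, major G, position 615), with frequency ties
  broken alphabetically;
* a **trait table**, e.g. alpha-pinene content as a percentage of
  turpentine.

## Variant calling and classification

Columns containing an alignment gap in any row are removed wholesale
(`strip_indel_columns()`), merged into reported intervals, and later
positions keep their original coordinates. A column is a SNP if exactly
two nucleotides occur among called rows (`call_snps()`); columns with
three or more alleles are excluded from all pairwise analyses but counted
in reports, matching the biallelic semantics of genotype tables.

Two informativeness policies are shipped (`classify_informative()`)
because the field's "high information content" label has no single
definition: the default drops loci with MAF < 0.05 (`maf_threshold`), the
alternative drops singletons (`non_singleton`). Functional classification
(`classify_functional()`) translates the reference codon against the
codon carrying the alternate allele; "silent" means synonymous or
noncoding. A change that creates a stop codon is flagged, not rejected.

## Diversity and neutrality statistics

All diversities are reported **per site**; internal computations that need
totals (Tajima's D, Fu & Li's F*) use the mean pairwise difference count
$\hat{k}$.

* $\pi$ (`nucleotide_diversity()`): mean proportion of differing sites
  over all haplotype pairs, with pairwise deletion and per-pair length
  under missing data. The implementation uses per-column allele counts on
  complete data and exact pairwise comparison otherwise; tests hold it to
  a brute-force oracle at $10^{-12}$.
* $\theta_w$ (`watterson_theta()`): $S / (a_1 L)$,
  $a_1 = \sum_{i=1}^{n-1} 1/i$.
* Haplotype diversity (`haplotype_diversity()`):
  $\frac{n}{n-1}(1 - \sum p_i^2)$.
* Tajima's D (`tajimas_d()`): the 1989 constants recomputed from $n$;
  undefined at $S = 0$ and reported as `NA`, never as 0.
* Fu & Li's D* and F* (`fu_li_star()`): the no-outgroup forms, with the
  variance constants as corrected in the later literature (the original
  print contains typos); a singleton is a mutation carried by exactly one
  haplotype. When a study reports a single "Fu-Li" number without naming
  the statistic, both are available and reports label them explicitly.
* Fay & Wu's H (`fay_wu_h()`): $\theta_\pi - \theta_H$ from a polarized
  spectrum. Ancestral states require an explicit outgroup row; the
  optional major-allele-as-ancestral fallback emits a prominent warning
  because misassigning ancestral states biases H systematically.
* Ka/Ks (`nei_gojobori_ka_ks()`): Nei-Gojobori (1986) fractional site
  counting per sequence, difference counts averaged over all mutational
  pathways per codon (stop codons treated as a distinct residue), pairwise
  proportions averaged over all pairs, then Jukes-Cantor corrected
  ($d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, undefined for
  $p \ge 3/4$). The ratio is `NA` when $K_s = 0$ — a ratio against zero
  synonymous divergence is not evidence of selection.
* $R_m$ (`rm_four_gamete()`): Hudson-Kaplan minimum recombination. A
  site pair is incompatible when all four gametes are observed; the
  minimal number of breakpoints stabbing every incompatible open interval
  is found by the leftmost-right-endpoint greedy scan, which tests verify
  against exhaustive search on every instance up to 12 sites. The
  `rm_per_snp` denominator defaults to the number of sites analyzed but
  accepts the informative-SNP count, since published Rm-per-SNP figures
  typically use the post-filter locus count.

Per-site-class diversities (synonymous, nonsynonymous, silent) use NG86
fractional site counts of the reference row as denominators and the
noncoding length for silent sites. This is an explicit approximation of
the classical sliding treatment: only polymorphic columns contribute to
numerators, and the reference sequence fixes the site-count denominators.

## Linkage disequilibrium and haplotype blocks

Phase is never imputed per individual; only haplotype **frequencies** are
estimated. `em_haplotype_frequencies()` runs EM on unphased dosage
genotypes under random union of gametes, with a deterministic
initialization (product of single-locus allele frequencies, no random
restarts) so every run is reproducible; the log-likelihood trace is
returned and asserted non-decreasing in tests. For phase-unambiguous
inputs (at most one heterozygous locus per individual) EM reduces exactly
to gamete counting. Stopping: largest frequency change below `tol = 1e-8`
or 1000 iterations; the haplotype table is capped at $2^{14}$.

`pairwise_ld()` derives $D$, $D'$ and $r^2$ from the two-locus EM
frequencies with respect to the minor alleles;
$D_{max} = \min(p_A(1-p_B), (1-p_A)p_B)$ for $D > 0$ and
$\min(p_A p_B, (1-p_A)(1-p_B))$ otherwise. `ld_decay()` bins pairs by
distance (100-bp default), takes raw per-bin means (no monotone
smoothing) and interpolates the first crossing of each threshold;
decisions about LD extent should read the binned curve, not a smoothed
idealization.

Block partitioning (`partition_blocks()`) ships three methods because
published block definitions in single-gene studies are often
under-specified (feature-labeled blocks said to be "based on r²"):
`explicit` user boundaries for reproducing a published table, `feature`
(runs of loci sharing a gene-model region), and `r2_contiguous` (greedy
extension while mean $r^2$ with current members stays at or above 0.5).
No method is asserted to be "the" published rule. Within a block,
haplotypes at estimated frequency ≥ 0.01 are listed and those above 0.2
are called **dominant** — the conventional cutoff for a haplotype carried
by a substantial fraction of a panel.

## Association and marker-assisted selection

`hwe_test()` uses the Pearson statistic with df = 1 and **no continuity
correction** — the convention that reproduces published genotype-count
chi-squares exactly (verified to 4 decimals in the acceptance tests).
Expected heterozygosity is $2pq$ from observed allele frequencies; true
allele frequencies and carrier frequencies are reported as separate
columns because summary tables in the literature sometimes print carrier
frequencies under an "allele frequency" heading.

`anova_association()` is a fixed-effects one-way ANOVA across genotype
classes; the contribution rate is $R^2 = 100 \cdot SS_{between} /
SS_{total}$, with the small-sample adjusted value
$100 (1 - MS_{within}/MS_{total})$ reported alongside (the raw estimator
is inflated by roughly $(k-1)/(n-1)$ under the null). Classes with fewer
than 2 observations are dropped with a warning. No kinship or structure
correction is attempted (out of scope); the default applies no multiple-
testing correction, mirroring single-candidate-gene practice, with
Benjamini-Hochberg available via `multiple_testing = "bh"`.

TagSNPs are loci passing both $R^2 \ge 10\%$ and $p \le 0.05$
(`select_tag_snps()`), ordered by contribution. `combine_genotypes()`
assigns letters A, B, C… in genomic order with uppercase pairs for
homozygous-major (`AA`), mixed case for heterozygotes (`Aa`); three
biallelic loci span $3^3 = 27$ combinations. `mas_select()` reports the
selection ratio $100\,n_{sel}/N$, the selection differential
$\bar{y}_{sel} - \bar{y}$, and the realized gain
$100 \cdot \text{differential} / \bar{y}$ — selecting everyone gives 0
differential and 0 gain, and the gain is invariant under trait rescaling.

## The synthetic-data generator

No individual-level sequence panel accompanies the motivating class of
studies, so `generate_fixture_study()` builds one with the study's shape:
110 diploid individuals, a 4638-bp gene carrying ten coding exons
(1890 coding bp: 629 residues plus the stop), per-site $\theta = 0.003$,
six independently coalescing segments, and three causal SNPs with
single-locus $R^2$ targets 0.155 / 0.103 / 0.114 on a trait with
baseline 20.6 (an alpha-pinene-like percentage scale) and residual SD 8 —
chosen so that trait variability is realistic for a monoterpene fraction
and the planted signals sit clearly above the association threshold.

* **Haplotypes** (`simulate_haplotypes()`): per segment, a Kingman
  coalescent genealogy for $2n$ lineages; mutation counts are
  Poisson($\theta \cdot L_{seg} \cdot T_{total}/2$), placed on branches
  proportionally to length at distinct positions (infinite sites, so all
  variants are biallelic by construction; multiallelic test fixtures are
  built directly). Independent segment genealogies produce within-block
  LD and between-block decay, and nonzero $R_m$, without the cost and
  verification burden of a full ancestral-recombination graph. Tests hold
  the mean segregating-site count to the Watterson expectation
  $\theta L a_1(2n)$ within 3 standard errors over 200 replicates.
  The ancestral CDS is sanitized to be stop-free and derived alleles in
  coding sequence avoid nonsense changes, so every simulated haplotype
  encodes a full-length protein; this does not alter where or how many
  mutations occur.
* **Diploids** (`pair_into_diploids()`): a random perfect matching of
  haplotypes, so Hardy-Weinberg proportions hold by construction; the
  phase truth is retained so EM-based $r^2$ can be compared against
  phased $r^2$ in tests.
* **Trait** (`simulate_trait()`): baseline $+\sum_c a_c x_c + d_c h_c +
  \varepsilon$. When targets drive the effects, $a_c$ is solved against
  the **empirical** dosage variance of the supplied panel,
  $a_c^2 \mathrm{var}(x_c) = \frac{r^2_c}{1-\sum r^2} \sigma^2_\varepsilon$,
  and default causal loci are chosen near the preferred positions subject
  to pairwise dosage $r^2 < 0.2$. Both choices matter: calibrating
  against theoretical $2pq$ leaves the realized panel $R^2$ off target,
  and tightly linked causal loci can partially cancel, in which case no
  single-locus scan can recover the nominal effects.

What the generator does **not** emulate: population structure and
kinship, selection and demography, sequencing error, missing-data
patterns of real genotyping, and multiallelic variation. Tests passing on
simulated panels therefore validate the statistical machinery, not
robustness to structure-driven confounding in field data.

## Numerical conventions and degenerate inputs

Statistics undefined for an input are reported `NA`, never coerced to 0:
Tajima's D at $S=0$, Fu & Li at $\eta = 0$, Ka/Ks at $K_s = 0$, LD at a
monomorphic locus, decay crossings with fewer than two bins. Reports
print diversities to 5 decimals, test statistics and p-values to 4, and
percentages to 2, which keeps rerun bundles byte-identical
(`run_pipeline()` writes a manifest sufficient to reproduce any bundle).
EM ties are resolved by the deterministic initialization; allele-
frequency ties by alphabetical order; missing genotype calls are handled
by complete cases per locus pair or block.

## Problem sizes used by the test suite

The suite exercises the full study scale where the property demands it
(200 replicate simulations at $2n = 220$ for the Watterson check, 1000
null ANOVA replicates, 500 planted-effect replicates) and reduced panels
(20-60 haplotypes, 0.5-3 kb) elsewhere, keeping the whole suite in the
low minutes on one CPU while leaving every statistical assertion at its
stated tolerance.

## Known limitations

* Sequence statistics refuse ambiguity codes rather than resolving
  heterozygous bases; diploid consensus input must be phased or
  simulated upstream.
* The per-site-class diversities depend on the reference row's codon
  context; heavily diverged references shift the NG86 site counts.
* `r2_contiguous` block building is order-greedy and will not recover
  blocks interrupted by a single low-LD locus.
* The EM estimator returns maximum-likelihood frequencies, not
  per-individual phases, and its likelihood surface can be multimodal
  for many loci with weak LD; the deterministic initialization trades a
  (rare) risk of a local optimum for exact reproducibility.
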