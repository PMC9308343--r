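---
title: "Allele-specific expression and chromatin analysis in F1-hybrid mouse cells"
author: "hybridase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific expression and chromatin analysis in F1-hybrid mouse cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridase)
```

# The problem

F1 hybrids of C57BL/6J (BL6) and *Mus castaneus* (cast) carry roughly one
strain-distinguishing SNP every 100–150 bp, which makes it possible to read
transcription separately off the two parental chromosomes. With reciprocal
crosses — BC (BL6 mother × cast father) and CB (cast mother × BL6 father) —
the parental origin of each strain allele swaps, so parent-of-origin effects
(imprinting, X-inactivation) can be separated from strain effects. On top of
this allelic readout the package layers a knockout-versus-wild-type
comparison: which allele(s) respond when a chromatin regulator (the
motivating case is the H3K27me3 demethylase KDM6A, an X-linked gene that
escapes X inactivation) is removed, what happens to sex-biased expression,
and how promoter chromatin (accessibility, H3K27me3) shifts per allele.

`hybridase` implements that full analysis as reusable, tested components:
pseudo-genome construction, SNP-based read assignment, mapping-bias-corrected
allelic quantification, negative-binomial differential expression with
allelic group classification, sex-bias loss/gain accounting, and allelic
promoter coverage — plus a synthetic-data generator that produces every
input with known ground truth.

# Allele assignment

## Pseudo-genome and read classes

Reads are expected to be aligned both to the BL6 reference and to a
"pseudo-cast" genome in which every known cast SNP allele has been
substituted (`buildPseudoGenome()`), so that neither haplotype pays an
alignment penalty for its own variants. Only uniquely mapped, primary
alignments with MAPQ ≥ 30 enter the analysis (`filterAlignments()`).

`classifyReads()` inspects, for each aligned read, the bases it places on
SNP positions (spliced and clipped alignments are decomposed into aligned
blocks, so SNPs under `N`/`S`/`I`/`D` CIGAR operations never vote):

* all covered SNP bases match the BL6 allele → `allele0`;
* all match the cast allele → `allele1`;
* no SNP covered, or every covered SNP base matches neither allele
  (a sequencing error) → `uncertain`;
* bases supporting both strains → `conflict`.

The `conflict` class is an implementation refinement: a read with evidence
for both strains cannot be "containing only" one strain's SNPs, and is
excluded from allelic counts. Error bases are ignored rather than counted as
evidence, which keeps classification tolerant of sequencing noise without
inventing support.

For paired-end data, `pairFragments()` applies the fragment rule: one
allele-certain end decides the fragment; ends certain for different alleles,
or any `conflict` end, discard it; two uncertain ends leave it uncertain.
Coordinate-based duplicate removal (`dedupFragments()`, a MarkDuplicates
stand-in keyed on the template's outer coordinates and strand) is applied to
ATAC/ChIP fragments only — RNA-seq counting does not deduplicate.

`countGeneAlleles()` counts a fragment for a gene when at least one aligned
base overlaps the gene's merged exon set; fragments touching exons of more
than one gene are counted for none (unambiguous assignment avoids double
counting).

## Coordinate conventions

Ranges live in `GRanges` objects and therefore follow the Bioconductor
1-based closed convention internally. All text interfaces are explicit about
their convention and converted exactly once at the boundary: the normalized
SNP TSV and BED regions are 0-based half-open, VCF input is 1-based, and the
`snpsInRegion()` query API takes 0-based half-open intervals.

# Allelic expression

For gene $i$ let $n_{i0}$ and $n_{i1}$ be its exonic BL6- and cast-allele
fragment counts. The raw BL6 proportion $p_{i0} = n_{i0}/(n_{i0}+n_{i1})$ is
systematically inflated because reference-strain reads still map slightly
better; the genome-wide correction factor is the autosomal allele-specific
ratio

$$ r_m = N_{A0} / N_{A1}, $$

computed per library (`mappingBias()`) over autosomes only, so that
X-inactivation cannot contaminate it. Bias is a property of a library, hence
the per-sample choice; a pooled value can be supplied where libraries share
a protocol. The adjusted proportion is

$$ \hat p_{i0} = \frac{n_{i0}}{n_{i0} + r_m\, n_{i1}}, $$

and the diploid TPM (exon-union length normalized, columns summing to
$10^6$; `computeTPM()`) is split as $\mathrm{TPM}_{i0} = \hat p_{i0}
\mathrm{TPM}_i$ and $\mathrm{TPM}_{i1} = (1-\hat p_{i0})\mathrm{TPM}_i$.
Genes with $n_{i0}+n_{i1}=0$ carry no allelic information: their proportions
are `NA` and they are excluded from allelic (not diploid) analyses.

The cross orients strain onto parent (`orientAlleles()`): BC makes allele0
maternal, CB swaps. In male cells the single X is maternal, so paternal
X-linked TPM is masked to zero (`maskXPaternal()`); female samples and
autosomes are untouched. TPM denominators include all counted genes, also
those later excluded from comparisons (exclusion is a comparison-level,
not a normalization-level, operation).

# Differential expression and allelic groups

`nbWaldTest()` is a deliberately simple negative-binomial Wald pipeline in
the DESeq2 mould — exact DESeq2 parity is a non-goal; the allelic framing,
not the DE engine, is the point. Components:

* **Normalization** — median-of-ratios size factors (`medianOfRatios()`),
  rescaled to geometric mean 1.
* **Dispersion** — per-gene method-of-moments estimates within each group,
  pooled, then shrunk in log space toward a robustly fitted trend
  $\alpha(\mu) = a_0 + a_1/\mu$. The moment estimate is clamped to an
   8-fold band around the trend before shrinking; the shrinkage weight is
  `priorDf / (priorDf + df)` with residual `df = n1 + n2 - 2` and
  `priorDf = 10`.
* **Test** — Wald statistic on the difference of log group means of
  normalized counts (0.5 pseudocount), with the NB variance
  $\mathrm{Var}(\log\hat m_g) \approx \frac{1}{n_g^2}\sum_s
  \frac{1}{m_g s_s} + \frac{\alpha}{n_g}$. P-values use a moderated $t$
  reference with `df + priorDf` degrees of freedom: the shrunk dispersion is
  far better determined than the per-gene residual df alone, but treating it
  as known (a normal reference) is measurably anti-conservative at $n=3$
  per group. With the moderated reference the empirical type-I error at
  nominal 0.05 sits near 0.044 in the package's null simulations, inside the
  [0.03, 0.07] band the tests enforce, while 4-fold effects at mean count
  200 are detected with essentially full power.
* **Not implemented** — independent filtering, Cook's-distance outlier
  handling, shrunken LFC estimators, multi-factor designs.

Diploid DEGs use FDR < 0.05 and ≥ 1.5-fold change (`callDegs()`), minus any
exclusion list (e.g. off-target deletion genes). Allele-specific DEGs are
called per parental allele on the oriented SNP-informative counts
(`allelicDegPipeline()`), each with its own size factors (the design leaves
open whether a joint interaction model was used; per-allele runs are the
simpler, more transparent choice). Genes whose estimated allelic TPM stays
below 1 in every sample of the contrast are removed afterwards, as are
masked paternal-X entries.

`classifyGroups()` assigns downregulated allelic DEGs to group A (maternal
only), B (paternal only) or C (both), and upregulated ones to D/E/F
symmetrically; one gene can hold a down-group and an up-group at once (up
maternally, down paternally). The allele-specific share of the down set is
$(A+B)/(A+B+C)$, recomputed — never carried — by `summarizeGroupTable()`
with round-half-up integer percentages.

`relaxedFoldOverlap()` intersects, across the reciprocal crosses, genes with
a ≥ 1.25-fold change of mean TPM. The fold is a TPM ratio, not a log2
difference: the two readings conflict in the source material and the ratio
reading is the one consistent with the strict 1.5-fold DEG cutoff. Replicate
averaging uses the arithmetic mean; all fold ratios in the package floor
their means at 0.5 TPM, which leaves well-expressed genes' folds untouched
(10 vs 4 is exactly 2.5-fold) while keeping ratios at zero finite.

# Sex-biased expression

A gene is sex-biased in wt when mean TPM differs ≥ 2-fold between the sexes
and a two-sided two-sample Student t-test gives p ≤ 0.05
(`callSexBiased()`; the equal-variance Student test is the literal
definition adopted here, Welch is available behind a flag). After KO:

* **loss** (`lossAfterKo()`) — fold-only: a wt-biased gene whose post-KO
  cross-sex ratio (female wt over male KO for female-biased genes; the
  mirrored ratio for male-biased ones, where female KO data are not
  available) drops below 2 is lost. No p-value is involved; the loss and
  gain definitions genuinely differ and are kept different.
* **gain** (`gainAfterKo()`) — the full fold + t-test criterion applied to
  the post-KO comparison, for genes unbiased in wt. Loss and gain are
  mutually exclusive per gene by construction.

`sexBiasSummary()` produces the wt / loss / gain contingency table with
percentages recomputed from its own count fields. `quantileNormalize()`
(through limma) supports comparisons against external wt datasets;
`callAllelicBias()` flags ≥ 2-fold allele imbalance in wt.

# Allelic promoter chromatin

Promoters are symmetric ±2 kb windows around the TSS (`makePromoters()`;
strand does not change a symmetric window). `regionCoverage()` counts
allele-assigned, deduplicated fragments per region — fragment-level, not
base-level, counting, which is reproducible without coverage-track
conventions — and scales to fragments per million assigned. ChIP signal is
divided by its matched input after depth scaling, with a pseudocount of 1 on
both depth-scaled values so empty promoters stay finite
(`inputNormalize()`). Quantile normalization across alleles and cell lines
(`qnAcross()`) rests on the stated assumption that promoter coverage is
similarly distributed between alleles and lines. Per-group shifts of
log2(KO/wt) are tested against zero with a two-sided Wilcoxon signed-rank
test (`groupShiftTest()`) — robust to heavy-tailed coverage ratios; a
one-sample t-test sits behind a flag. Identical ratios make the signed-rank
statistic degenerate; the result is flagged rather than faked.

# The synthetic hybrid generator

`SimConfig()` fixes one simulated study; the seed fully determines every
output. The defaults emulate the motivating study design at desk scale:

| parameter | default | why |
|---|---|---|
| samples per cross | 2 wt M, 3 KO M, 2 wt F | the clone panel of the study design |
| genes / chromosomes | 400 on 2 autosomes + chrX, 1 Mb each | enough genes that each planted group has ~12 members (a signed-rank test on fewer than ~9 cannot reach p < 0.01) |
| depth | 10^6 exonic fragments/sample | bulk RNA-seq at desk scale |
| informative fraction | 0.20 | ~11% + ~9% of reads are allele-specific in this hybrid background |
| mapping bias `rTrue` | 1.2 | the ratio implied by that 11%/9% split |
| NB dispersion | 0.05 | clonal ES lines |
| group effects | 4-fold, 3% of genes per group A–F | clearly detectable single-allele effects |
| sex bias | 8% female- / 3.4% male-biased (2.4:1), 3-fold | the observed female:male imbalance |
| loss probability | 0.32 | the observed total loss rate |
| imprinting | 1% of genes at maternal fraction 0.95 | a small imprinted contingent |
| reads | 75 bp paired, fragments 250 ± 30 bp | the sequencing configuration emulated |

Counts-level simulation (`simulateCounts()`) is the fast default: a diploid
NB total per gene and sample (variance $\mu + \alpha\mu^2$), split
*binomially* between the alleles, then thinned binomially to the
SNP-informative subset with the allele0 capture rate `rTrue`-fold the
allele1 rate. The binomial split is a modelling decision: clone-to-clone
overdispersion acts on a gene's total expression, while the allelic split
within one library is read sampling — if each allele instead carried
independent NB noise, no depth could push the allelic-proportion error below
the dispersion floor (~0.04 at $\alpha = 0.05$), which contradicts how
allelic ratios actually concentrate with coverage. Planted effect classes
(groups A–F, sex bias, imprinting) are drawn disjoint from one another so
each recovery test sees a clean background; the male X is maternal-only to
exercise masking. KO effects multiply the allele(s) a gene's group dictates;
sex-bias loss raises (or lowers) the male KO level to the other sex's.

Reads-level simulation (`simulateAlignments()`) samples fragments from exon
unions of the chosen haplotype sequence (reference or pseudo-genome), with
spliced CIGARs across exon junctions, substitution errors, planted
coordinate duplicates and low-MAPQ records, and writes valid SAM — this
exercises the parsing/classification machinery mechanically, independent of
the statistical tests. Transcript coordinates run in genomic order
regardless of strand; realistic splicing graphs, GC bias and alignment
errors are out of scope. `simulateChromatin()` emits counts-level promoter
coverage (ATAC, H3K27me3 ChIP and flat input) with the repressive-mark gain
planted on the affected allele(s) of the downregulation groups.

What passing tests on this generator do **not** show about real data: no
mapping artefacts beyond a global bias ratio, no allele-specific splicing,
no batch structure beyond library size, no dosage-compensation dynamics on
the female X, and sequencing errors are uniform substitutions. The
generator's job is to verify the estimators against a truth they should
recover, not to imitate every nuisance of a real experiment.

# Numerical choices and degenerate inputs

* Fold-ratio means floored at 0.5 TPM; NB log2 fold changes use a 0.5
  additive pseudocount on normalized means.
* Percentages round half-up to integers; the female/male ratio reports one
  decimal.
* Ties in quantile normalization take the mean of the quantile values they
  span; a single column is returned unchanged.
* Zero allelic information → `NA` proportions, excluded downstream; all-zero
  count columns are an error for TPM; an all-identical ratio vector is a
  flagged degenerate case in `groupShiftTest()`; duplicate SNPs with
  conflicting alleles are an error, identical duplicates collapse.
* The test suite and examples run at reduced problem sizes (hundreds of
  genes, ~10^4 reads for the classifier oracle, 2 000-gene calibration
  batches) — chosen so the full suite completes in a few minutes while every
  statistical check retains clear margins.

# Known limitations

* The DE engine is a documented stand-in, not DESeq2; results will differ in
  detail (no outlier handling, no independent filtering).
* Allelic DE treats the two alleles independently; a joint interaction
  model could borrow strength between them.
* Whether a read must map uniquely in *both* genomes (rather than in the
  combined alignment set) is left to the upstream aligner; classification
  here starts from one filtered alignment set plus the SNP index.
* Enhancer definitions are accepted as user BED files; deriving them from
  external histone data is out of scope, as are peak calling, GO enrichment
  and isoform-level quantification.
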