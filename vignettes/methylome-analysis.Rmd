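---
title: "Genotype-aware caste and sex methylome analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-aware caste and sex methylome analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`beemethyl` implements the post-alignment half of a whole-genome bisulfite
sequencing (WGBS) study design used for haplodiploid social insects such as
the bumblebee *Bombus terrestris*: colonies founded by one diploid queen and
one haploid male, sampled as queen, male and pooled reproductive-worker
libraries, with whole-genome re-sequencing of the parents. This vignette is
the package's own account of the statistical models, the tunable parameters,
the synthetic-data generator, and the design decisions taken where the
procedure was genuinely open.

```{r setup, eval = FALSE}
library(beemethyl)
```

## 1. Genotype-aware references

Bisulfite alignment is biased toward the reference allele wherever samples
carry non-reference variants, which distorts differential-methylation calls
between non-inbred individuals. The package therefore consumes parental
variant calls and:

1. **filters SNPs** (`filter_parent_snps()`) to biallelic SNVs with
   QUAL ≥ 20 and mean depth ≥ 10 that are homozygous-alternative in exactly
   one parent while the other parent is homozygous reference. A haploid
   male genotype `1` counts as homozygous-alternative. C↔T SNPs are removed
   because an unmethylated C reads as T after conversion, making those
   alleles indistinguishable from bisulfite signal. "Unique to one parent"
   is operationalised as *alt-homozygous in one AND ref-homozygous in the
   other*: only such sites are diagnostic for the parental origin of a read.
   Records with a missing genotype are skipped and counted, never errored.
   A site present in only one parent's single-sample VCF is treated as
   implied homozygous-reference in the other parent
   (`merge_parent_calls(missing_as_homref = TRUE)`); an explicit `./.` is
   treated as missing.
2. **N-masks** the colony reference at the retained positions
   (`mask_genome()`), so neither allele is favoured during alignment, and
3. builds **individualised references** (`build_alternate_reference()`) by
   substituting each queen's or male's homozygous-alternative alleles.
   Substitution is length-preserving and idempotent: re-applying a SNP whose
   alternative allele is already in place is a no-op, while any other
   disagreement between the record's REF and the genome is raised as a
   coordinate/genome-version error.

Only SNVs are handled; indels are out of scope, which also guarantees that
all individualised CDS copies of a gene stay alignable by position.

**Coordinates.** All tibbles in the package use 1-based closed intervals,
the convention of GFF3, VCF, Bismark coverage files and IRanges. Keeping a
single convention end to end is what prevents off-by-one drift; BED export
(`write_feature_bed()`) converts to 0-based half-open at the boundary. The
destranded CpG key is the 1-based position of the + strand cytosine of the
dyad.

## 2. Methylation calling against a conversion-error null

Bismark-style coverage counts are destranded (`destrand()`): the + strand C
at position *i* and the − strand C (a G on the + strand) at *i + 1* are one
CpG dyad and their counts are summed. A − strand record without a partner
still maps to the dyad key *i − 1* and is kept, with a logged count.

Coverage filtering (`filter_coverage()`) removes sites with fewer than 10
reads and sites above the sample's 99.9th coverage percentile (type-7
linear-interpolation quantile; the definition matters for exactness and is
fixed here). The negative-binomial coverage model in the simulator exists
precisely so this outlier filter has genuine outliers to remove.

Each library carries an unmethylated lambda-phage spike, so its
methylated-read fraction estimates the **non-conversion rate** *e*
(`conversion_rate()`), estimated per sample because every library has its
own spike. The per-site null is then that all apparent methylation is
non-conversion: with *m* methylated of *n* reads,

$$p = P(X \ge m), \qquad X \sim \mathrm{Binomial}(n, e).$$

The test is one-sided (upper tail) by design: only an *excess* of
unconverted reads is evidence of methylation. p-values are
Benjamini–Hochberg corrected and a site is *methylated* at q < 0.05.
Whether the original analysis corrected within each sample or globally is
not determinable; the package corrects **within each sample** by default
(per-sample site counts differ after coverage filtering, so a global
correction would couple unrelated samples), with `scope = "global"`
available. Sites methylated in no sample are dropped from the analysis set
(`drop_never_methylated()`).

**Weighted methylation** of a feature is the Schultz-style pooled level
$W = \sum m / \sum n$ over its covered CpGs; a feature with no covered CpG
is absent, never 0/0. Gene levels are classed as methylated when
*W* > 0.05, the conversion-error floor. Bins are: low (0.05 < W < 0.3),
medium (0.3 ≤ W ≤ 0.7), high (W > 0.7, strict). The published bin wording
("low: > 0 and < 0.3" and "high: > 0.7") overlaps the W ≤ 0.05 unmethylated
rule, so the low bin is tightened to start strictly above the floor — a
reconciliation decision, recorded here, with both edges configurable
(`bin_methylation()`, `pipeline_config(meth_floor=, bin_edges=)`).

## 3. Differential methylation

Per CpG, `dm_test_cpgs()` fits a binomial GLM with logit link on per-sample
(methylated, total) counts:

$$\mathrm{logit}(\pi_s) = \beta_0 + \beta_1\,\mathrm{group}_s +
\beta_2\,\mathrm{subspecies}_s ,$$

and tests $\beta_1 = 0$ with a 1-df **likelihood-ratio test** against the
covariate-only model. The LRT rather than a Wald test is chosen for
stability at extreme proportions (the referenced methylKit machinery uses a
chi-square test as well). The subspecies covariate absorbs the colony-level
cross-direction effect. The reported difference is the count-pooled group
difference in percentage points, matching the weighted-methylation logic
and robust to uneven coverage. Sites are tested only when every sample of
both groups has coverage (the original criterion is unstated;
`min_per_group` relaxes this). Non-convergent fits get `p = NA` and are
excluded with a count; a covariate perfectly confounded with group makes
the whole design non-identifiable, and no site is tested.

DM CpGs require |difference| ≥ 10 percentage points *and* BH q < 0.01,
both read as absolute percentage points. A **DM gene** needs an exon with
at least two DM CpGs and an exon-level |ΔW| > 0.15. A CpG counts for an
exon if either base of its dyad overlaps it, and a CpG inside overlapping
exons of two genes counts for both. Genes whose qualifying exons disagree
in sign are labelled `mixed` (hyper- and hypomethylated exons in one gene).
The hypermethylated-count balance of a comparison is tested with a Pearson
chi-square goodness-of-fit against equal counts (`gof_hypermethylated()`),
and hypermethylated gene sets are intersected upset-style
(`overlap_dm_gene_sets()`), whose exclusive counts conserve set sizes.

## 4. Codon degeneracy and the methylome–genome relationship

`label_degeneracy()` labels every base of every CDS (extracted from each
individual's own alternate reference with `extract_cds()`, which handles
strand, splicing and phase) with its synonymous-substitution count under
the standard genetic code: 0 (zero-fold) to 3 (four-fold). Substitutions
creating a stop codon are non-synonymous; stop codons themselves are not
labelled; codons containing N (e.g. under a mask) are untypeable and
skipped with a count. Note that standard-code enumeration yields zero-fold
*third* positions for ATG and TGG; the claim that zero-fold sites occur
only at codon positions one and two is therefore not exactly reproduced by
enumeration, and the package reports the table as enumerated rather than
forcing it.

A degenerate site is matched to a destranded CpG dyad strand-awarely: the
coding base of a + strand gene is the + strand C (key = pos), that of a −
strand gene is the − strand C, i.e. the + strand G (key = pos − 1).
Methylation is symmetric at CpG dyads, so either coding base in the CDS
links the site; proportions are computed over degenerate sites that overlap
a *called* CpG. Heterozygous queen positions keep the reference base (only
homozygous-alternative alleles are substituted), a documented limitation of
working from haploid-state references.

The fold effect on the proportion of methylated sites is modelled with a
**beta regression** written in the package (`fit_beta_regression()`):
Beta(μφ, (1 − μ)φ) likelihood, logit mean link, one constant precision φ
(no variable-dispersion submodel — the minimal model the analysis needs),
maximised by BFGS with Wald z from the inverse observed information.
Proportions at 0 or 1 are shrunk by (y(N − 1) + 0.5)/N before fitting,
since the beta likelihood is undefined at the boundary. Degeneracy enters
as the numeric synonymous-substitution level (0/2/3/4) plus sex, matching
the single reported fold statistic. Enrichment of zero-fold-methylated
genes across methylation bins uses an upper-tail hypergeometric test with
the methylated-gene universe and BH across bins
(`fold_bin_enrichment()`).

## 5. Selection: pN/pS

`compute_pnps()` counts polymorphic CDS sites across the allele panel (12
alleles in the reference design: 2 identical alleles per queen — a direct
consequence of substituting only homozygous-alternative SNPs — and 1 per
haploid male). A site is synonymous when every observed allele codon at its
codon translates identically, else non-synonymous; a site with more than
two bases still counts once. The ratio is the **raw count ratio pN/pS**, as
literally defined in this analysis tradition, *not* normalised by
synonymous/non-synonymous opportunity counts; the textbook site-normalised
estimator is available with `mode = "site_normalized"`. Genes with pS = 0
have no defined ratio and are excluded from the association model.
`methylation_vs_pnps()` is ordinary least squares of gene methylation level
on the ratio, reporting slope, t, F(1, n − 2) (= t² here) and p.

## 6. GO enrichment

`enrich()` is a margins-only upper-tail hypergeometric test with BH
correction. The universe is the background restricted to annotated genes;
terms are tested only with ≥ 1 background and ≥ 1 study hit by default,
mirroring common GO-enrichment practice and avoiding vacuous tests
inflating the BH denominator. No term-graph propagation is applied — the
gene-to-term map is used as given, because the upstream databases such maps
come from are themselves flat exports. The gene universe for the
differential contrasts is the union of methylated genes across groups
(the per-group alternative is a one-line change in the caller).

## 7. The synthetic-data generator

`simulate_study()` writes a complete miniature study — FASTA genome, GFF3
annotation, per-parent VCFs, per-sample Bismark-dialect coverage, lambda
counts, sample sheet, GO map — with truth tables for every layer, and a
ready `pipeline_config`. What it emulates, and how:

* **Design**: `n_colonies` = 4 colonies × (diploid queen, haploid male,
  pooled workers), two subspecies cross directions as a colony-level label.
  Pooled workers are drawn as the sum of three equally weighted latent
  individuals.
* **Genes**: 3 exons of whole codons (GFF3 phase 0 throughout — non-zero
  phase in `extract_cds()` is exercised by hand-built fixtures instead),
  ATG start, single stop, no internal stop, both strands, GT..AG introns.
  35% of coding codons come from the CpG-containing codon set so exons
  reliably carry CpGs.
* **Methylation truth**: each gene draws a class — unmethylated (60%), low
  (20%, p = 0.15), medium (12%, p = 0.5), high (8%, p = 0.85). The
  unmethylated majority with a graded minority reflects the sparse
  (< 1% of CpGs) gene-body methylation typical of these genomes; no
  canonical per-site distribution exists for them, so the mixture is a
  parameter, not an assertion. Non-genic CpGs have p = 0.
* **Differential truth**: per pairwise comparison, `n_dm_genes` low/medium
  genes get a `group_effect` (default 30) percentage-point shift on one
  designated exon, alternating the hypermethylated group. Because a shift
  in one group also moves its other pairwise contrast, truth for any
  comparison is evaluated from the per-site truth table, not from the
  assignment list.
* **Covariate**: colonies with the second subspecies label shift the logit
  of every methylated site's proportion by 0.25 (≈ 5 percentage points at
  mid-range levels) — the stated "percentage-point" shift is implemented on
  the logit scale so it respects the (0, 1) range.
* **Counts**: per-strand depth ~ NegBin(mean/2, size = 5); methylated reads
  ~ Binomial(n, p + (1 − p)e) with non-conversion e = 0.05 by default, the
  conversion error rate the analysis itself uses as the methylated-gene
  floor. Lambda counts use p = 0.
* **Variants**: informative mother/father SNPs plus guaranteed decoys —
  heterozygous, shared-by-both-parents, C↔T, and low-QUAL records — which
  the filter must remove; truth records each class.

**What it does not emulate** — and hence what passing tests do not show
about real data: read-level errors, mapping bias and PCR duplicates (counts
are the input boundary), non-CpG contexts, chromosome-scale genome
structure, linkage between SNPs, fold-class-dependent methylation (the
degeneracy/methylation association in real data is exactly what the
pipeline is meant to measure, so the generator deliberately does not build
it in), indels, and biological replicate-level variance beyond the binomial
and negative-binomial layers.

## 8. Numerical choices and problem sizes

* Binomial tails via `pbinom`, hypergeometric via `phyper`, BH via
  `p.adjust` — all checked in the test suite against hand-summed
  enumeration oracles (binomial tails exactly for n ≤ 30; hypergeometric
  for all margins ≤ 50 at 10⁻¹²).
* The per-CpG LRT uses `stats::glm` IRLS; the suite checks it against an
  independent BFGS maximisation of the same likelihood at 10⁻⁶. Fits that
  do not converge are excluded with a count rather than guessed.
* The beta regression starts from a logit-scale least-squares fit and a
  moment estimate of φ, optimises with BFGS (reltol 10⁻¹²), and errors on
  non-convergence carrying the optimiser's evaluation counts.
* Ties/boundaries: coverage exactly 10 is kept, coverage exactly at the
  99.9th percentile is kept; W exactly 0.05 is unmethylated; W exactly 0.3
  is medium, exactly 0.7 medium (high is strict); q exactly at a threshold
  is not significant.
* Test problem sizes: the property suite runs on genomes of 1–2 contigs ×
  8–30 kb with 6–30 genes; calibration checks use ~12,000 CpGs × 12
  samples; DM-gene recovery averages 5 simulated studies of 30 genes. These
  sizes give the stochastic checks comfortable margins (recovery
  sensitivity is ≈ 1 at 30 percentage points and 30× coverage) while
  keeping the suite quick to run.

## 9. Known limitations

* Queens contribute two identical alleles to the pN/pS panel; true
  heterozygosity is invisible to a pipeline that substitutes only
  homozygous-alternative SNPs.
* Promoters are putative: 500 bp upstream truncated at any gene-derived
  feature, and only the fragment abutting the gene start is kept. Where
  genes overlap, bp labels resolve exon > UTR > intron — a declared
  precedence, since feature annotation of overlapping genes has no single
  convention.
* The colony is not modelled in the per-CpG GLM beyond the subspecies
  label, matching the stated model contract.
* No GO term-graph propagation, no non-CpG contexts, no indels, no
  read-level processing.
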