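---
title: "Inferring sample sex from Y-linked gene expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring sample sex from Y-linked gene expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexcallr)
```

## The problem

Bulk RNA-seq studies on early embryos, biopsies, or archived tissue often
lack a recorded sex for each sample, yet sex is a major covariate for gene
expression. Before gonads are morphologically distinguishable — in the pig,
the tunica albuginea is not visible until about day 27 of gestation — sex
cannot be assigned by inspection at all. The data themselves carry the
answer: genes in the male-specific region of the Y chromosome (MSY; DDX3Y,
KDM5D, ZFY, EIF2S3Y, EIF1AY and relatives) are transcribed in males and
genetically absent in females. What a female sample shows at those loci is
not expression but a technical artifact: X and Y share regions of high
sequence similarity, so a small number of short reads from X homologs
mismap to Y gene models. The two regimes differ by two to three orders of
magnitude, which makes a simple summed-expression score a near-perfect
classifier.

sexcallr implements that inference for gene-level count data and ships a
packaged reference table — per-gene CPM of ten Y-linked genes across 35
pig conceptus samples (17 males, 18 females, embryos at 25 days and
fetuses at 35 days) — on which every stage of the pipeline can be
exercised against published numbers.

## The score and the classification rule

Counts are normalized to counts per million:

$$\mathrm{CPM}_{gs} = \frac{c_{gs}}{\sum_{g'} c_{g's}} \times 10^6,$$

where the denominator (the library size) is the column sum over retained
genes. HTSeq's `__no_feature`-style summary totals are excluded from both
the gene table and the denominator by default — the convention consistent
with counting reads *into genes* — but `compute_cpm(include_summary_totals
= TRUE)` switches the denominator to all processed reads for pipelines
that define CPM that way.

The per-sample score is the summed CPM over the selected Y-linked marker
genes,

$$\Sigma\mathrm{CPM}_{\mathrm{chrY}}(s) = \sum_{g \in G_Y} \mathrm{CPM}_{gs},$$

and the call is a pure threshold function of the score: **male** if
$\Sigma\mathrm{CPM} > 400$, **female** if $\Sigma\mathrm{CPM} < 2$,
otherwise **undetermined**. Both inequalities are strict and the open
interval $(2, 400)$ is deliberately left uncalled: on the reference data
males score 427–573 and females 0.00–1.75, so the gap is wide, and a
sample inside it is more plausibly contaminated, mislabeled, or aneuploid
than confidently either sex. Classification is monotone in the score by
construction, which the tests assert as a property.

```{r}
calls <- call_sex(conceptus_cpm(), conceptus_chrY_map())
glance(calls)
summarize_groups(calls)
```

## Selecting informative marker genes

Not every Y-annotated gene is usable: most show artifact-level counts in
*all* samples (pseudoautosomal or poorly annotated loci, or genes simply
not expressed in the tissue). The usable ("discrepant") genes are those
whose per-sample CPM is bimodal — high in every male, near zero in every
female. `select_informative_genes()` formalizes this with a largest-gap
rule: sort the gene's per-sample CPM, cut at the widest consecutive gap,
and select the gene iff

1. both sides of the cut hold at least `min_group = 2` samples,
2. the high side's minimum is at least `min_high_cpm = 0.3` CPM, and
3. the ratio high-minimum / max(low-maximum, 0.01) is at least
   `min_fold = 20`.

The `0.01` CPM floor keeps the ratio finite when the low group is exactly
zero, which is common (several markers show no mismapping at all in
females).

The defaults were calibrated once against the packaged reference table.
There, the weakest true marker separates 66.9-fold (KDM5D: high-group
minimum 5.35 CPM vs low-group maximum 0.08) and the faintest marker's male
expression bottoms out at 1.23 CPM (LOC396706), while artifact-level genes
sit near one-fold with CPM well below 1. `min_fold = 20` and
`min_high_cpm = 0.3` sit a factor of ~3 below the weakest genuine signal
and well above the artifact regime, leaving margin for sampling noise on
both sides. A stricter fold requirement (say 100) looks safer but would
silently drop three of the ten genuine markers on the reference data
itself (KDM5D at 66.9-fold, ZFY at 75.1, LOC110255257 at 81.3); the score
would still classify correctly, but the selection would no longer
reproduce the reference gene set. All three knobs are exposed in the API
and the command line.

Two caveats of the largest-gap rule are worth knowing. First, it assumes
both sexes are present: in a single-sex cohort nothing is bimodal, and an
all-female dataset selects nothing (tested). Second, with very few samples
per sex, the widest gap for a *weak* marker (male band 1–2 CPM) can fall
inside the male group rather than between the sexes, rejecting the gene;
with the reference design (17 + 18 samples) this does not occur, and the
score is in any case dominated by the strong markers.

## The MDS verification

As an orthogonal check that samples segregate by sex, the package embeds
samples by classical multidimensional scaling of pairwise leading
log-fold-change distances. Log-expression is $\log_2(\mathrm{CPM} +
p_s)$ with a per-sample pseudocount $p_s = \mathrm{prior}/L_s \times
10^6$ (prior = 2 counts scaled into CPM units; when library sizes are
unknown, 2 CPM). For each sample pair the distance is the root mean
square of the `top = 500` largest absolute log differences, the gene set
chosen per pair — the "pairwise" flavor popularized by edgeR/limma's
`plotMDS`, whose defaults we follow since they are the de facto standard
for this plot. The embedding is Torgerson's classical scaling
(`stats::cmdscale`): double-center the squared distances,
eigendecompose, scale eigenvectors by the square roots of their
eigenvalues. Negative eigenvalues (non-Euclidean distance sets) are
clamped to zero with a warning rather than an error, and axis signs are
arbitrary — tests assert separations, never signs. The test suite
verifies the whole path (distance plus embedding) against
`limma::plotMDS(gene.selection = "pairwise")` to near machine precision,
and verifies exact recovery of Euclidean configurations from their
distance matrices.

On the reference table restricted to the ten markers, every between-sex
distance exceeds every within-sex distance, and 2-means on dimension 1
reproduces the 17/18 split exactly.

## The synthetic generator

`generate_dataset()` exists so that every stage — including failure modes —
can be tested end-to-end without any sequencing data. It emulates the
features the method relies on, each with an explicit default:

* **Library sizes**: log-normal around 13 million counted reads (CV 0.1),
  the scale of the reference experiment after QC.
* **Autosomal background** (default 20,000 genes): log-normal
  gene-specific means, negative-binomial counts with dispersion 0.1 —
  standard bulk RNA-seq texture. Its only role is a realistic CPM
  denominator.
* **Informative Y genes** (default 10): in males, counts are Poisson
  around a CPM drawn uniformly from the per-gene band observed in the
  reference males (e.g. 143–200 CPM for the DDX3Y-like gene); uniform is
  assumption-minimal and keeps the summed score in the observed 427–573
  range. In females these genes receive sparse Poisson counts at the
  per-gene artifact rates observed in the reference females (0–0.09 CPM;
  ten-gene total ≈ 0.38 CPM). Poisson rather than negative-binomial
  because mismapping is sparse technical noise with many exact zeros.
* **Non-informative Y genes** (default 69): artifact-level Poisson counts
  in *all* samples, rates drawn once per gene from 0.02–0.5 CPM.

With these defaults the male fraction of reads on the Y chromosome comes
out at ≈ 0.05%, matching the reference study without being targeted at
run time — it follows from the marker bands summing to ≈ 500 CPM.

A configuration whose male bands fail to clear the artifact rates by the
`min_separation` margin (default 5×) is rejected *before* any sampling:
such a truth would be unrecoverable by construction, and a silent
overlap would make recovery tests meaningless. Reproducibility is
two-level: a gene-parameter stream seeded by `seed` fixes gene means and
rates, then each sample draws from its own derived substream, so adding
samples never perturbs existing columns (adding genes redraws gene
parameters).

The generator emulates magnitudes and sparsity, not everything real data
do: no gene-gene correlation, no batch or treatment structure, no
GC/length bias, no X-linked complement (the method is Y-only by design,
so XIST-style evidence is out of scope). Passing recovery tests
therefore demonstrate the pipeline's correctness under the stated model,
not robustness to annotation errors or contaminated libraries.

## Numerical and interface conventions

* Reports are written at two decimals with ties rounded away from zero
  (`round_half_up()`), matching how reference values are printed; base
  `round()`'s half-to-even would disagree on exact halves.
* Chromosome names are normalized by stripping a leading `chr`
  case-insensitively, so Ensembl ("Y") and UCSC ("chrY") annotations
  interoperate; the target chromosome is configurable for non-mammalian
  or W/Z systems, though defaults are tuned for Y.
* Ties in the largest-gap search break toward the first (lowest-CPM) gap,
  and gene order in selections follows input order — both choices keep
  identical inputs producing byte-identical outputs, which a test
  asserts on the written report.
* Duplicate gene rows are rejected, never merged: silent merging hides
  annotation errors.
* The command line (`exec/sexcallr`) exposes each stage as a subcommand
  (`classify`, `select-genes`, `mds`, `simulate`) with exit codes 0
  (success), 2 (usage), 3 (parse error), 4 (consistency error), so
  workflows can branch on the failure class. Undetermined samples are
  flagged in the log, not the exit code.

## Problem sizes used in validation

The test suite validates CPM against brute-force recomputation and
`edgeR::cpm` on random 50×5 matrices, the distance/embedding path against
`limma::plotMDS` on 300-gene datasets, and end-to-end recovery on
simulated datasets with a 2,000-gene autosomal background at the study's
sample sizes (17 + 18) across eight seeds. The acceptance script runs the
full study-scale configuration (20,079 genes × 35 samples) across 20
seeds. These sizes fully exercise every code path; the statistics of the
method do not change with more genes, only the denominator's smoothness.

## Known limitations

* A Y-only score cannot distinguish an XX male-labeled contamination from
  a low-quality male library; an undetermined call is a prompt for
  inspection, not a third sex.
* Very shallow libraries weaken the CPM-scale guards: at 2 million reads
  a single mismapped read is already 0.5 CPM, and the gap rule can then
  mistake a few stacked artifact reads for a high group. The defaults
  assume ≥ ~10 million counted reads; for shallow data, raise
  `min_high_cpm`.
* The thresholds 400/2 are tied to a ten-marker panel of this magnitude;
  a different species, tissue or panel needs recalibrated thresholds
  (both are arguments everywhere).
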