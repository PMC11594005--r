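---
title: "Methods: CNV population genomics from binned read depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV population genomics from binned read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvpop)
```

cnvpop analyses copy number variation (CNV) at the population level, the
workflow used in livestock resequencing studies: per-sample CNVs are called
from binned read depth, merged across individuals into CNV regions (CNVRs),
annotated against gene models, and used for population structure, selection
scans and gene-set enrichment. This vignette records the models, parameter
choices and numerical conventions; the README shows a worked run.

## The synthetic cohort and what it emulates

Every stage of the pipeline can be exercised against planted truth because
the generator (`sim_config()`, `simulate_cohort()`) produces the same
statistical objects a real cohort would:

* **CNV loci.** `n_loci` non-overlapping intervals placed on the 200 bp bin
  grid, each a biallelic deletion ("loss") or duplication ("gain") locus.
  Default lengths are 15–40 bins (3–8 kb). Real bovine CNVs reach hundreds
  of kilobases; a few kilobases keeps a desk-scale genome (megabases rather
  than gigabases) while every event still spans enough bins for the caller
  to be tested meaningfully.
* **Population differentiation.** Neutral loci follow the Balding–Nichols
  model: an ancestral frequency $p_0 \sim U(0.05, 0.95)$ and per-population
  frequencies $p_k \sim \mathrm{Beta}\big(p_0\frac{1-F}{F},
  (1-p_0)\frac{1-F}{F}\big)$, so the expected Weir–Cockerham $F_{ST}$
  between populations is approximately $F$ (`F_bg`). This makes the
  selection-scan oracle direct: the scan's genome-wide weighted $F_{ST}$
  should recover `F_bg`.
* **Selected loci.** A fraction `frac_selected` of loci emulate divergent
  selection: odd-numbered populations are pulled toward variant-allele
  equilibrium $0.5 + F_{sel}/2$ and even-numbered ones toward
  $0.5 - F_{sel}/2$, with Beta draws of concentration 20 around those
  targets. A symmetric high-drift Beta draw was rejected here: it is
  bimodal, so both populations fix the *same* allele about half the time
  and no detectable signature is planted — divergent equilibria are what
  "strongly differentiated selected loci" require.
* **Genotypes and admixture.** Individual ancestry $Q$ is one-hot by breed
  (`admix_alpha = 0`) or Dirichlet(`admix_alpha`); the variant-allele count
  is $\mathrm{Binomial}(2, \pi_{il})$ with $\pi_{il} = \sum_k Q_{ik}
  p_{kl}$, and the diploid copy state is $2-x$ (loss) or $2+x$ (gain) —
  states 0/1 are homozygous/heterozygous deletions, 3/4 single/double
  (or more) gains.
* **Depth tracks.** Per 200 bp bin, the expected count is
  $\mu_b = d \cdot (c/2)(1 + a\sin 2\pi g_b)$ with `mean_depth_per_bin`
  $d = 10$ (a ~30× genome at 150 bp reads has roughly this many reads per
  200 bp), copy state $c$, GC fraction $g_b$ varying smoothly in
  $[0.3, 0.7]$ and bias amplitude `gc_amp`. Counts are Poisson (negative
  binomial if `overdispersion > 0`). Mapping-quality-zero (q0) fractions
  are Beta(1, 19) per bin (mean 0.05), except 2% repeat-like bins drawn
  Beta(8, 2) (mean 0.8) shared across samples, as a genome property.

What the generator does **not** emulate: read-level artifacts (mappability
gradients, GC effects at the fragment level, alignment chimeras), linkage
between loci, overlapping or multi-allelic CNVs, and sex chromosomes. A
green suite therefore shows the algorithms are correct under the stated
model, not that the caller's sensitivity transfers to any given real
genome.

All randomness flows from one integer seed in a fixed order (frequencies,
genotypes, repeat-bin placement, gene models, then one stream per sample's
track), so identical configurations are byte-identical.

## Calling CNVs from depth

1. **GC correction** (`gc_correct`): bins are stratified by GC in 1% strata
   and rescaled by global/stratum typical depth. The typical depth is a
   20%-trimmed mean — robust to the minority of bins inside real CNVs,
   while a plain median of integer counts at depth ~10 jumps by whole units
   between strata and injects up to 10% spurious rescaling. Strata with
   fewer than 100 bins borrow the nearest populated stratum.
2. **Normalization** (`normalize_depth`): division by the genome-wide mean,
   so diploid bins have expectation 1 and copy state $c$ maps to $c/2$.
3. **Segmentation** (`segment_depth`): the exact minimizer of
   $\sum_{seg}\sum_b (x_b - \bar{x}_{seg})^2 + \beta \cdot \#segs$ with
   $\beta = \lambda\,\hat\sigma^2 \log B$, $\hat\sigma^2 =
   \mathrm{mad}(x)^2$ (falling back to $\mathrm{mad}(\Delta x)^2/2$ for
   constant signals) and $\lambda = 2$ by default. The optimizer is PELT —
   pruned exact dynamic programming whose pruning rule provably never
   discards an optimal candidate for this penalty — so it scans a 10 Mb
   chromosome in seconds yet equals the exhaustive optimum (property-tested
   against full enumeration for short signals). Ties in cost are resolved
   toward fewer segments by flooring $\beta$ at $10^{-12}$.
4. **State calling** (`call_states`): copy $= \min(\mathrm{round}(2d), 4)$
   with half away from zero, matching the 0/1/3/4 deletion–duplication
   taxonomy (state 4 buckets all gains of two or more copies); diploid
   segments are dropped and adjacent same-state segments merged. Each
   call's p-value is a two-sided one-sample t-test of its bins against 1.0
   (p = 1 for single-bin segments; p = 0 for zero-variance segments off the
   null, which is what an all-zero homozygous deletion produces). The call
   q0 is the count-weighted mean of bin q0.
5. **Breakpoint refinement**: after least-squares segmentation, each call
   edge is re-placed within ±10 bins by maximizing the Poisson likelihood
   of the raw corrected counts under the called-state rate versus the
   diploid rate. Least squares with a common variance underweights the
   evidence (Poisson variance scales with the mean); the refinement
   recovers most of that loss. With the likelihood-ratio drift per bin of a
   1.5× event at depth 10, even the exact known-rate MLE mislocates an edge
   by more than 2 bins ~17% of the time — a physical limit of depth-based
   calling that the tests document rather than hide.
6. **Filtering** (`filter_calls`): keep iff p < 0.001 **and** length
   > 1 kb **and** q0 < 0.5 **and** the chromosome is placed. All
   inequalities strict, so boundary values are removed.

## CNVRs, genotypes and annotation

Within each breed, calls overlapping by ≥1 bp are chained transitively
(`merge_cnvrs`); each chain's union span is a CNVR typed loss/gain/mixed
from its member states. CNVRs present in fewer than `min_carriers = 4`
distinct individuals are dropped — with a 30-animal cohort that is the
13.3% carrier-frequency convention; `carrier_frequency` expresses the same
filter as ⌈f·n⌉ per breed. Per-breed sets are then unioned across breeds
(`merge_across_breeds`) with deterministic ids by position. Individuals are
genotyped at each CNVR by their largest-overlap call (ties to the earlier
call start) and default to diploid state 2 — a deterministic stand-in for
statistical imputation of no-calls.

Annotation (`annotate_cnvrs`) classifies each CNVR by precedence
exonic > UTR > intronic > upstream > downstream > intergenic, where
"exonic" means coding-sequence overlap and the flanking windows are 1 kb
and strand-aware (the gene-based convention of standard annotators).
Exonic deletions are sub-classified by the deleted-CDS length: not a
multiple of 3 ⇒ frameshift deletion; a positive multiple of 3 ⇒
non-frameshift; zero (non-coding exon) ⇒ unknown. A deletion spanning a
whole gene is flagged `whole_gene`; since complete CDS totals are in-frame
by construction, such deletions classify as non-frameshift, which is the
mod-3 rule applied honestly rather than a special case.

## Population structure

CNVR genotypes are recoded to biallelic dosages (`recode_biallelic`): loss
CNVRs to deletion-allele dosage $2-c$, gains to $c-2$ (clipped to [0,2]),
and mixed CNVRs to two pseudo-loci so both allele classes remain visible.

* **Distances**: identity-by-state between individuals
  ($d_{ij} = \tfrac{1}{2L}\sum_l |g_{il}-g_{jl}|$) or pairwise multi-locus
  Weir–Cockerham $F_{ST}$ between breeds (ratio of sums, clipped at 0).
  The breed-level tree defaults to the $F_{ST}$ metric.
* **Neighbor joining** (`nj_tree`): Saitou–Nei agglomeration, ties broken
  by the smallest index pair, negative branch lengths clamped to zero,
  returned as an `ape` `phylo`. On additive matrices the tree metric
  reproduces the input exactly (tested to 1e-9, cross-checked against
  `ape::nj`).
* **PCA** (`cnv_pca`): monomorphic loci dropped; centering by $2\hat p$
  and scaling by $\sqrt{2\hat p(1-\hat p)}$ (the variance-standardized
  genotype-PCA convention); eigendecomposition of the sample covariance;
  per-PC sign fixed so the largest-magnitude coordinate is positive;
  variance shares sum to 100.
* **Admixture** (`admixture_em`): the standard K-population admixture
  likelihood $\ell = \sum_{il} g_{il}\ln\pi_{il} +
  (2-g_{il})\ln(1-\pi_{il})$, maximized by an EM scheme with closed-form
  updates (allele-origin responsibilities), frequencies clamped to
  $[10^{-6}, 1-10^{-6}]$, stopping at $\Delta\ell < 10^{-6}$ or 2000
  iterations, best of 5 seeded restarts. EM was chosen over quasi-Newton
  block relaxation because it is monotone by construction (asserted on
  every run) and simpler to verify; it maximizes the same likelihood.
  Missing dosages cannot occur because genotyping defaults to state 2.

## Selection scan and enrichment

`wc_fst` computes the Weir–Cockerham variance components $a$ (among
populations), $b$ (among individuals within populations) and $c$ (within
individuals) per locus from sample sizes, allele frequencies and observed
heterozygote (dosage-1) proportions; loci monomorphic in both groups are
undefined and excluded from ranking. The genome-wide weighted $F_{ST}$ is
$\sum a / \sum(a+b+c)$. `select_top` flags loci at or above the empirical
99th percentile (type-7 linear interpolation, fixed for reproducibility),
ties included, negative estimates retained unclamped. Candidate genes are
the genes overlapped ≥1 bp by selected CNVRs. The two-group comparison is
a mapping from breeds to groups, so one breed can be scanned against
several pooled others.

Enrichment (`enrich_test`) is the exact upper-tail hypergeometric
$P(X \ge k)$ of the query/term overlap against a universe defaulting to
all genes in the supplied annotation, with Bonferroni and
Benjamini–Hochberg corrections computed within each term namespace
(GO aspects and pathways separately). The EASE variant (tail at $k-1$) is
available as an option. Because the test is discrete, its attainable
type-I level at a nominal cutoff depends on the set sizes; the calibration
test uses a design whose attainable level (0.0466 at nominal 0.05) was
computed from the CDF beforehand.

## Problem sizes and numerical conventions

Internally all coordinates are 0-based half-open; VCF and GFF3 files are
written 1-based inclusive, BED 0-based — conversions happen only in the
I/O layer. Test and verification runs use desk-scale problems chosen to
give stable statistics: 2000 loci × 30 diploids per population for
$F_{ST}$ calibration (5 seeds per drift level), 1000 loci × 40 individuals
for admixture recovery, 10 Mb CNV-free genomes × 20 seeds for caller
specificity, and a 6-sample cohort of 40 planted loci for sensitivity.
`run_pipeline()` wires the stages together with a YAML-configurable
`run_config()` whose defaults encode the standard settings (200 bp bins,
p < 0.001, length > 1 kb, q0 < 0.5, 4 carriers, top 1%), writes every
artifact in the standard formats and records a manifest with per-file
checksums so re-runs are verifiably identical.

## Known limitations

Depth-only evidence cannot place breakpoints more precisely than the
information in the bin counts allows; heterozygous events at ~10 reads per
bin carry roughly one nat of evidence per bin, so a minority of edges land
more than 2 bins off no matter the estimator. Copy states above 4 are
bucketed. The caller is strictly per-sample (no joint calling), merging
uses the 1 bp-overlap convention (no reciprocal-overlap threshold), and
K-selection for admixture (e.g. cross-validation) is out of scope.
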