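---
title: "methbin: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methbin: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its statistical machinery:
the model behind each stage, the tunable parameters with their units and
defaults, what the synthetic-data generator does and does not emulate,
and the places where the design was genuinely open and a choice had to be
made. It states no empirical result that the test suite does not itself
compute.

## 1. The unit of analysis: gap-based CpG bins

Single-CpG methylation calls from whole-genome methylation sequencing are
noisy at clinically realistic depth, and neighbouring CpGs are strongly
co-methylated. `build_bins()` therefore clusters CpG sites into bins:
adjacent sites on a chromosome are merged whenever their plus-strand C
positions differ by **strictly less than `max_gap` = 65 bp**; a gap of 65
or more splits. The rule partitions all sites, singleton bins included,
and the boundary is tested explicitly (gap 64 merges, gap 65 splits). Bin
spans run from the first member CpG to the last member + 2 so the span
covers the final CpG dyad.

Two conventions were open and are fixed as follows:

* **Coordinates** are 0-based half-open (BED) everywhere internally;
  1-based report formats are converted at the parser boundary, and CpG
  dyads are collapsed onto the plus-strand C by summing counts (standard
  WGBS practice; it maximizes per-site coverage). Collapsing is a parser
  option (`collapse_strands`) because upstream pipelines differ.
* **Bins are built once, cohort-wide**, from the union of CpG positions
  across samples, so `bin_index` is stable across groups and runs —
  required for cross-group intersection and for referring to individual
  bins by index. A per-sample alternative would make indices
  incomparable.

The bin beta value is the **pooled read fraction**
$\beta = \sum_i m_i / \sum_i (m_i + u_i)$ over member CpGs — the average
methylation fraction — rather than the mean of per-CpG betas. Pooling is
the maximum-likelihood estimator under binomial sampling and is robust to
low-coverage member sites; the per-CpG mean is available as
`aggregate = "cpg_mean"` for comparison. Beta is missing wherever a bin
has zero coverage in a sample.

## 2. Association screening: Kendall tau-b

Within each base group (male/female × tissue/cfDNA), `screen_bins()`
correlates each bin's betas with fibrosis stage. Stages take five values
over at most ~20 samples, so ties dominate; tau-b is the only Kendall
variant defined under ties:

$$\tau_b = \frac{C - D}{\sqrt{(n_0 - n_1)(n_0 - n_2)}},\qquad
n_0 = \tfrac{n(n-1)}{2},$$

with $n_1, n_2$ the within-tie pair counts of the two vectors. The
two-sided p-value uses the asymptotic normal approximation of $S = C - D$
with the classical tie-corrected variance

$$\operatorname{Var}(S) = \frac{v_0 - v_t - v_u}{18}
 + \frac{\sum_j t_j(t_j{-}1)\sum_k u_k(u_k{-}1)}{2n(n-1)}
 + \frac{\sum_j t_j(t_j{-}1)(t_j{-}2)\sum_k u_k(u_k{-}1)(u_k{-}2)}{9n(n-1)(n-2)},$$

the default behaviour of the widely used scientific-Python
implementation; whether the original analysis used exact or asymptotic
inference for small groups is not documented, so the asymptotic form is
the default and an exact permutation p (n ≤ 8) is provided and used as a
test oracle. The implementation counts discordant pairs by mergesort
inversion counting; the acceptance suite checks it against an independent
O(n²) pair-counting oracle to 1e-12.

**Filters** (both tested): a bin is excluded from a group's screen when
observed in fewer than `min_individuals` = 4 samples or when its observed
betas round (to 6 decimals — unique-value counting needs a numeric
equality rule) to fewer than `min_unique` = 3 distinct values; a group
whose observed stages are all tied is likewise filtered, since tau-b is
undefined. Significance is strict, p < `alpha` = 0.05. **No
multiple-testing correction** is applied at this stage by design: the
cross-group intersection requirement is the error control, with the
stricter `alpha_extended` = 0.01 available for the extended gene-list
criterion. Missing betas are dropped pairwise per bin.

## 3. Cross-group intersection labels

`assign_label()` is a total function on the 16 subsets of significant
base groups: all four → `All`; a complete tissue pair → `Tissue`, cfDNA
pair → `cfDNA`, male or female pair → `Male`/`Female`; the two diagonal
pairs (differing in both sex and sample type) and singletons → `none`.
Every three-group pattern contains exactly one complete sample-type pair
and one complete sex pair; the priority order resolves it — tissue first,
then cfDNA, then sex. The tissue-before-sex rule is stated by the source
analysis; cfDNA-before-sex is the natural completion but is genuinely
ambiguous for patterns like {male tissue, male cfDNA, female cfDNA}, so
the order is a config switch (`priority`) rather than a silent guess.
Each bin receives exactly one label; the truth table is tested
exhaustively, as is the sex-swap symmetry (swapping male and female
everywhere maps Male↔Female and fixes the other labels).

## 4. Annotation

* **Nearest gene**: minimal gap between intervals, 0 when touching or
  overlapping (the convention of the interval toolkit the analysis
  ecosystem uses); ties break to the alphabetically first symbol for
  determinism; the sign is negative when the gene lies 5′ (lower
  coordinates) of the bin.
* **TSS proximity**: strand-aware TSS (interval start on `+`, end − 1 on
  `-`); a bin is TSS-proximal when its distance to any TSS is strictly
  below `tss_window` = 1500 bp (1499 in, 1500 out — tested).
* **CpG island**: ≥ 1 bp overlap. Shores/shelves are deliberately not
  zoned; a slop parameter (default 0) widens islands if a looser
  proximity notion is wanted.
* **First exon/intron**: per transcript, strand-aware (on `-` the 5′-most
  exon is the block with the highest coordinates), any-transcript
  semantics — the automatable superset of a manually curated call.
* **chromHMM state**: state of the segment with the largest overlap; an
  exact tie goes to the segment with the smaller start. Segmentation
  tracks are genome-tiling; uncovered bins get `NA` with a warning.

**Gene-list modes** (`select_pathway_input()`): `tissue_strict` = island
AND TSS-proximal (the validation criterion used for the tissue group);
`or_relaxed` = island OR TSS-proximal (used for the other groups to keep
input lists large enough); `extended` = Kendall p < 0.01 in every
contributing base group AND a chromHMM state difference between the two
annotated cell types. The source text is self-contradictory about whether
the tissue group used AND or OR, so both are implemented and the pipeline
uses strict-AND for Tissue.

## 5. Intergenic transition enrichment

Background = intergenic bins significant in **no** base group; associated
= intergenic bins with any valid label. For each, a 15 × 15 joint table
of (cell-type-A state, cell-type-B state) counts is converted to
proportions; the enrichment ratio is cell-wise associated/background.
Flags: `enriched` (ratio > `fold` = 1.5, strict), `low_support`
(associated count < `min_bins` = 30, rendered faded), `absent`
(associated count 0, displayed distinctly), `infinite` (background
proportion 0 with associated bins — reported separately, never counted as
enriched). Joint transitions, not marginals, are compared, because the
scientific question is about state *changes* between cell types. No
significance test is attached — the fold/count thresholds are the
published decision rule — and the gene list for downstream pathway tools
collects nearest genes of associated bins in enriched, adequately
supported cells.

## 6. Deconvolution

The published analysis used a fragment-level (read-state) deconvolution
tool with its own reference table; re-implementing that algorithm and
shipping its table is out of scope, so the module provides the standard
atlas formulation on bin betas: given atlas $A \in [0,1]^{M \times K}$,

$$\hat w = \arg\min_{w \ge 0,\; \mathbf 1^\top w = 1} \lVert A'w - b'\rVert_2,$$

with $A', b'$ restricted to observed markers (at least 50% required).
The solver is Lawson–Hanson NNLS written in-package; the simplex
constraint is enforced by renormalizing the NNLS solution (default;
well-conditioned and exact for noiseless mixtures) or by a heavily
weighted sum-to-one row (`method = "simplex"`). A rank-deficient
restricted atlas flags the result `unstable`. Atlas quality is encoded as
the per-marker-row spread requirement `separation` (default 0.5) rather
than fixed, because real reference data (e.g., FACS-sorted hepatocytes)
vary in purity. The pipeline also accepts externally produced proportion
tables so the downstream low/high fibrosis comparison (two-sided Wilcoxon
rank-sum, stage dichotomized at `fibrosis_cut` = 2) can run on real tool
output.

The Wilcoxon implementation wraps the stock R test: exact distribution
when both groups have n ≤ 10 without ties, tie-corrected normal
approximation with continuity correction otherwise; the acceptance suite
verifies it against exhaustive enumeration for all group sizes with
n₁ + n₂ ≤ 8.

## 7. The synthetic world

`sim_config()` fixes the cohort the tests run on:

| parameter | default | why |
|---|---|---|
| subjects | 38 (18 M / 20 F); 30 paired, 2+4 tissue-only, 2+0 cfDNA-only | the study's printed composition |
| stage margins | M 0/7/7/3/1, F 2/8/4/5/1 | the study's printed margins; they set realistic group sizes for power behaviour |
| CpG layout | island clusters (~3% of units, mean ~20 CpGs, internal gaps ≪ 65 bp) between geometric open-sea gaps (mean 300 bp) | produces both multi-CpG bins and singletons under the 65-bp rule, like a real methylome |
| coverage | NB mean 30× tissue / 10× cfDNA, dispersion 0.3 | plausible WGMS depths; nothing source-derived |
| baseline beta | bimodal on the logit scale: islands ~plogis(−1.6), open sea ~plogis(+1.6), sd 0.5 | methylomes are bimodal (hypomethylated islands, methylated open sea) |
| subject noise | logit sd 0.1 (~0.025 on the beta scale at mid-range) | inter-individual reproducibility of bin-level WGBS betas at ≥10× is high; noise enters on the logit scale *before* binomial sampling to avoid clipping artifacts |
| planted effects | Δ = 0.08 per stage, both directions, one bin per label; planted bins drawn from bins with ≥ 10 CpGs | island/TSS bins are the objects of interest; ≥ 10 CpGs guarantees the bins pass the association filters by construction |
| atlas | K = 10, M = 500, near-0/1 markers (separation ≥ 0.5), beta noise sd 0.02, hepatocyte base 0.2 + 0.15 fibrosis shift | mirrors marker-based reference atlases; the hepatocyte shift reproduces the liver-derived cfDNA increase the analysis is meant to detect |

Paired subjects share their per-bin deviations between tissue and cfDNA
samples; planted shifts apply in exactly the base groups the target label
implies (a Male-planted bin shifts male tissue *and* male cfDNA, never
female samples). All generators are deterministic given the seed and
restore the caller's RNG state.

**What a green test establishes — and what it does not.** The acceptance
suite shows the pipeline recovers known structure from data generated
under its own assumptions (binomial counts given a bin-level beta,
logit-normal subject variation, label-faithful plants, well-separated
atlas). It does not establish performance under covariate confounding
(age, batch), long-range co-methylation, atlas mismatch, or fragment-level
cfDNA effects — none of which the generator emulates. One structural
property worth knowing: with alpha = 0.05 and the tissue-first priority
rule, a sex-planted bin picks up an off-target false positive in one
opposite-sex group about 10% of the time and is then labeled
Tissue/cfDNA, so per-label recovery of sex plants is capped near 90% even
at perfect power; recovery is therefore assessed over all planted labels
together.

## 8. Numerical choices and degenerate inputs

* Unique-beta counting rounds to 6 decimals before `unique()`.
* `kendall_tau_b()` raises a distinct error when either vector is
  constant (denominator 0); the screen treats such bins as filtered.
* p-values are capped into (0, 1]; tau into [−1, 1] against floating
  drift.
* NNLS tolerance scales with the atlas magnitude; an all-zero solution
  (possible only for pathological inputs) falls back to uniform
  proportions with a warning.
* Zero-coverage records are retained by the parsers (beta undefined);
  empty files parse to empty record tables; chromosome order is natural
  (chr1…chr22, chrX, chrY) so genome-wide bin indices are deterministic.
* Config files are JSON (not YAML): the JSON reader is a hard dependency
  of the package already, and the config surface is flat enough that the
  format carries no cost.

## 9. Known limitations

* The deconvolution estimator is a bin-beta stand-in for the published
  fragment-level algorithm; absolute proportions from the two need not
  agree, though the downstream group comparison logic is identical.
* Screening is unadjusted for covariates (deliberately, matching the
  source analysis, which excluded age as a covariate); the generator
  correspondingly plants no covariate structure.
* The intersection rule treats the four group screens as exchangeable
  evidence; no meta-analytic weighting is attempted.
* Enrichment flags carry no uncertainty; with few associated bins the
  ratio is unstable, which is exactly what the 30-bin fade encodes.
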