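---
title: "Effective insertion density for comparative TnSeq: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective insertion density for comparative TnSeq: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnseqdiv)
```

## The model

A TnSeq library is a pool of mutants, each carrying one transposon
insertion at a genomic coordinate. After growth under a condition, the
number of reads at a site is proportional to the abundance of the mutant
lineage carrying that insertion. `tnseqdiv` treats each gene as an
ecological community: insertion sites play the role of species and read
counts the role of individuals. For a gene with per-site counts
$c_1, \dots, c_S$ and proportions $p_i = c_i / \sum_j c_j$:

$$H' = -\sum_i p_i \ln p_i, \qquad
  {}'D = \exp(H'), \qquad
  \mathrm{ED} = \frac{{}'D}{L},$$

where $L$ is the gene length in nucleotides. $H'$ blends richness (how
many distinct sites) with evenness (how equally reads are spread over
them), but raw Shannon indices lack the doubling property — doubling the
number of equally common sites does not double $H'$ — so indices are not
proportional between conditions. Its exponential ${}'D$, the Hill number
of order one, *is* linear in that sense: it is the number of equally
abundant sites that would give the same index. Dividing by gene length
yields a density comparable across genes. The interpretation contract:
lower ED for a gene under a condition means mutants of that gene are
disappearing there, i.e. the gene contributes to fitness under that
condition.

Assumptions worth stating: read counts at a site are a fair (if noisy)
proxy for mutant abundance; insertion position within the retained core
does not matter beyond disrupting the gene; and the two conditions share
the same library, so differences in per-gene site diversity reflect
differential survival, not library composition.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `trim_fraction` | 0.2 | fraction of CDS per end | insertions at the 5' end may reflect misannotated starts; 3'-end insertions often fail to disrupt function. `floor(0.2 L)` nt are cut from each end, so short genes keep a non-empty core and the rule is strand-symmetric. |
| `min_mapped_fraction` | 0.8 | fraction of reads | replicates with heavy contamination under-sample the target genome and depress ED globally; the rule is strict (exactly 80% is excluded). |
| `log2fc_cutoff` | 1 | log2 units | a two-fold change in effective density; the hit rule is strict (`> 1`), so exactly two-fold is not a hit. |
| `cooks_threshold_factor` | 4 | — | the conventional `4/n` influence rule for Cook's distance, with `n` the number of genes entering the regression. |
| Welch cutoffs | 0.05, 0.01 | p | inclusive (`p ≤ cutoff`); raw p drives the flags, BH-adjusted p is reported alongside. |
| `length_mode` | `"full"` | — | the ED denominator is the full annotated gene length; `"trimmed"` divides by the retained core length instead (see below). |

## Numerical and edge-case choices

- **Logarithm base.** Natural log throughout: the `exp()` in ${}'D$
  forces it, and it makes `effective_sites(rep(k, n)) == n` exact.
- **Empty genes.** A gene with no insertions gets $H' = 0$, ${}'D = 0$,
  $\mathrm{ED} = 0$ — an explicit extension, since the empty sum would
  give $\exp(0) = 1$ and wrongly credit a never-hit gene with one
  effective site. Empty genes are kept in all downstream tables.
- **ED denominator.** The definition divides by "gene length", which we
  read as the full annotated length (the default). Since sites can only
  fall in the central ~60%, ED values are bounded above by roughly
  0.6 × site density; `length_mode = "trimmed"` removes that ceiling and
  rescales all EDs by a per-gene constant. Both modes give identical
  fold changes for genes with equal trim proportions; full length is the
  default for fidelity to the definition.
- **Normalization is diversity-neutral by construction.** Median-of-ratios
  size factors divide every count in a sample by one scalar, which cannot
  change any gene's count proportions — so $H'$, ${}'D$ and ED are
  provably invariant to it (and a test asserts this to 1e-12).
  Normalization is still applied by default because the normalized
  gene totals are reported, and because per-sample scalars do matter for
  any downstream use of absolute counts. Size factors are estimated on
  gene-level summed counts (site-level rows are far too sparse for a
  median of ratios) and applied to site-level counts; a
  `pseudo_reference` option uses only positive entries per gene when no
  gene is covered in every sample.
- **Zero condition means.** `log2FC` is `+Inf`/`-Inf` when exactly one
  condition mean is zero (a hit, with direction), and 0 when both are.
  Infinite-fold-change genes are excluded from the regression (which
  needs finite values) but keep their fold-change flags; `n` in `4/n`
  counts only regression genes.
- **Regression orientation.** Treatment mean ED is regressed on
  reference mean ED. Cook's distance is nearly orientation-symmetric for
  the influence decision; the orientation mainly fixes the sign of
  residuals used for direction annotation.
- **Degenerate Welch tests.** Zero variance in both groups yields an
  explicit `welch_degenerate` flag with p = 1 (equal means) or p = 0
  (different means) rather than silent `NaN`.
- **Perfect regression fits.** With zero residual MSE Cook's distance is
  0/0; we define it as 0 (no point is influential in a perfect fit).
- **Strand.** Insertion strand is ignored: sites are positions, and
  disruption is orientation-independent for our purposes. Sites shared
  by overlapping genes count toward every overlapping gene, since the
  insertion disrupts each annotation; the audit table reports the
  double-counted read mass separately so totals remain checkable.
- **Duplicate input rows.** Duplicate (replicon, position) rows in input
  tables are summed with a warning — merged runs of one library
  legitimately produce them.

## What the simulator emulates — and what it does not

`simulate_experiment()` generates: a multi-replicon genome laid out with
intergenic gaps; a saturated Tn5-style library (default 100 sites/kb,
uniformly placed; a `site_grid` switch coarsens placement to a
TA-like grid for mariner-style data); heavy-tailed lognormal per-site
abundances (sdlog 1.5); two conditions × 4 replicates of 250,000 reads
drawn multinomially; one treatment replicate at 0.25× depth (emulating an
anomalously shallow real replicate); per-sample contamination emitted on
a decoy replicon and mirrored exactly in the sample sheet's
`mapped_fraction` (the defaults reproduce a design in which two reference
replicates fail the 80% rule); and 25 of 500 genes depleted by a fitness
factor d = 0.25 in the treatment condition, recorded as ground truth.
The default depth was chosen to match the saturation regime of real
libraries of this kind (~2.7 reads per site). That regime is
mechanistically important: a uniform multiplicative depletion of a gene's
site abundances leaves its within-gene proportions unchanged, so ED
responds to fitness costs *through sparse-sampling site dropout* — at
unrealistically deep coverage the ED signal of a pure abundance
depletion vanishes. Each sample draws from its own seed-derived random
stream, so removing a sample never perturbs the others, and a fixed
master seed reproduces the experiment byte-for-byte.

Not emulated: generation-by-generation growth dynamics and lineage
extinction (the depletion factor subsumes them), positional insertion
bias, PCR jackpots beyond the lognormal tail, multi-mapping artifacts,
and batch structure between replicates. Passing tests on this generator
therefore demonstrate the statistical machinery under a fair null and a
known alternative — not robustness to every artifact of real libraries.

## Validation problem sizes

The test suite validates the Cook's-distance closed form against
leave-one-out refits on 200 random regressions of 20–100 genes (1e-9),
the Welch statistic against the reference implementation on 1000 random
cases (1e-10), null calibration on twenty 1000-gene no-effect
simulations (p ≤ 0.05 fraction within 0.05 ± 0.02), and recovery of 25
depleted genes (d = 0.25) in a 500-gene 4 vs 4 design (≥ 80% flagged by
at least one statistic). These sizes keep the whole suite in the
low minutes on one CPU while leaving each check statistically
meaningful.

## Known limitations

- With 4 replicates per condition, Welch's t-test runs on tiny samples;
  its p-values are approximately calibrated (the null simulations bear
  this out) but individual genes deserve scrutiny, and the test is the
  statistic most sensitive to an outlying replicate — which is exactly
  why the subset-rerun machinery exists.
- ED comparisons across conditions inherit any global difference in
  usable depth; the QC rule and subset reruns mitigate but do not remove
  this.
- Sites on both strands at one coordinate are collapsed on input; if a
  protocol encodes strand meaningfully, that information is lost.
- Genes appearing in the annotation but absent from every profile are
  indistinguishable from truly never-hit genes (essential in *all*
  conditions); comparative statistics say nothing about them beyond
  ED = 0 in both conditions.
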