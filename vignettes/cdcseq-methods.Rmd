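---
title: "Methods and design choices in cdcseq"
author: "cdcseq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in cdcseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cdcseq packages a complete bulk RNA-seq characterisation workflow for
collecting duct carcinoma (CDC) and its comparators — upper tract
urothelial carcinoma (UTUC), normal kidney, and the common renal cell
carcinoma subtypes. This vignette is the package's own account of the
models it fits, the parameters that matter, what its synthetic data do and
do not emulate, and the places where the design was genuinely open.

## The count model and differential expression

Counts for gene $g$ in sample $j$ are modelled as negative binomial,
$K_{gj} \sim \mathrm{NB}(\mu_{gj}, \alpha_g)$ in the mean/dispersion
parameterisation $\mathrm{Var} = \mu + \alpha \mu^2$, so $\alpha = 0$ is
the Poisson limit. The mean is linked to the tissue type through a
cell-means log-linear model with a per-sample offset,
$\log \mu_{gj} = \beta_{g,\,\mathrm{tissue}(j)} + \log s_j$, where $s_j$
are median-of-ratios scaling factors. The choice of a cell-means (one
coefficient per tissue) design makes every pairwise contrast a simple
difference $\hat\beta_A - \hat\beta_B$.

*Scaling factors.* "Scaling factor" normalisation is implemented in its
standard RNA-seq meaning: per-gene geometric-mean reference over samples
(genes containing any zero are excluded from the reference), per-sample
factor = median over genes of count/reference. The factors are rescaled to
geometric mean 1; nothing downstream depends on that constant, but it fixes
an identifiable scale so factors can be compared across runs.

*Expression filter.* A gene is excluded when its CPM
($10^6 \cdot$ count / library size) stays below 1 in **every** sample.
The filter statement "below one per million in all samples" admits two
parses (exclude if low everywhere vs. exclude if low anywhere); we use the
literal and more permissive one and expose the threshold as an argument.
Library sizes are the column sums of the *unfiltered* matrix — "per
million total mapped reads" — and are deliberately carried through
filtering unchanged, which also makes the filter idempotent.

*Dispersion.* The per-gene dispersion is estimated by method of moments on
the normalised counts: within each tissue group,
$\hat\alpha_\mathrm{g} = (s^2 - \bar m)/\bar m^2$, pooled across groups by
degrees of freedom and truncated at zero. No shrinkage is applied. This
was an open choice — the workflow's description names the NB model but no
estimator — and the unshrunk moment estimator was preferred because it has
a closed form that tests can verify directly, and because, at the study's
group sizes (9–11 per tissue), its calibration is adequate: under a null
simulation at $\alpha = 0.05$ and $n = 10$ per group the Wald test's
type-I error at nominal 0.05 stays within a few thousandths of 0.06
(measured by the acceptance script at 2,000 genes). Empirical-Bayes
shrinkage as in the major DE packages would improve power at small $n$ but
is deliberately out of scope.

*Fitting and testing.* Each gene is fitted by iteratively reweighted least
squares (Fisher scoring with weights $\mu/(1+\alpha\mu)$), convergence
declared when the coefficient change drops below $10^{-10}$, capped at 50
iterations. All-zero genes are flagged degenerate and not tested;
unconverged genes (e.g. a tissue with all-zero counts, whose MLE diverges)
are reported with missing p-values and called `ns`, never dropped
silently. The Wald statistic uses the standard normal reference — the
conventional choice for NB GLMs — not a t distribution. At $\alpha = 0$
the machinery reduces to Poisson closed forms (log group means, standard
errors $\sqrt{\sum 1/y}$-style), which the tests exploit as an oracle.

*Multiple testing and calls.* Benjamini–Hochberg is applied within each
contrast across all post-filter genes (one universe per comparison, the
convention behind "out of 18,417"-style counts). Calls use an inclusive
fold-change boundary and a strict FDR boundary: signed fold change
exactly $\pm 2$ passes, $q$ exactly 0.05 fails, matching the
"$\ge 2$ / $\le -2$ and FDR $< 0.05$" reading. The signed fold change is
$\mathrm{sign}(\mathrm{lfc}) \cdot 2^{|\mathrm{lfc}|}$, so its magnitude
is never below 1.

## Clustering and PCA

Samples are clustered on $d = 1 - r$ (Pearson correlation over the
selected genes) with Ward's linkage implemented as the Lance–Williams
"ward" update applied to those distances as given. Ward's criterion is
formally defined for squared Euclidean distances; applying its update to a
correlation distance is a methodological quirk of this workflow that we
keep rather than correct, because it is the stated combination. The
update's coefficients guarantee monotone merge heights, which the tests
assert, and the merge sequence is validated against a naive $O(n^3)$
re-scan agglomeration. Which genes enter the distance was unspecified;
the default is the top 2,000 most-variable genes on the log scale
(pseudocount 1), both exposed as arguments, with ties in the variance
ranking broken lexicographically so selections are reproducible.

Flat clusters come from cutting the tree, with clusters renumbered by
first-leaf order so labels are stable across platforms. Concordance with
tissue labels is quantified by the adjusted Rand index (permutation-model
closed form) plus per-cluster purity. PCA is a gene-centred SVD; the
sign of each component is fixed by making its largest-magnitude loading
positive.

## Cell-of-origin mapping

The mapping mirrors the published supervised design. Tumor profiles are
centred per gene on the *mean centroid of designated comparator cohorts*
(by default every cohort except CDC): the centroid is the mean of the
cohort means, so equal-sized and unequal-sized cohorts weigh equally.
Centring on comparators rather than the grand mean matters: a disease
signature shared by all samples of the cohort of interest would be erased
by centring on itself — the null result one observes if a single cohort is
centred on its own mean. Atlas profiles are centred on the per-gene median
across that species' profiles, independently per species.

Gene symbols are matched case-insensitively (human `GATA3` meets mouse
`Gata3`); case-folded collisions are dropped with a warning, order follows
the tumor matrix, and fewer than 100 shared genes is an error (the real
analysis had ~4,000; 100 is a floor below which segment correlations are
too noisy to rank). Pearson correlations are computed for every (atlas
profile, tumor sample) pair; per tumor group the assignment is the argmax
segment of the mean correlation, with a confidence margin of
$\Delta r = 0.05$ — calls whose top-two gap is smaller are flagged and all
segments within the margin are reported. Human and mouse atlases are
analysed separately and both reported, since which one the published
heatmaps used per panel is unstated.

## Enrichment

Over-representation uses the upper-tail hypergeometric p-value after
intersecting each set with the universe, BH-adjusted across sets.
Preranked GSEA uses the weighted running sum (hits add
$|\mathrm{score}|^w$ normalised to one, misses subtract $1/(N - N_h)$);
the default weight is 1, with 0 available. The null permutes gene labels
(random reassignment of set membership along the fixed ranking), not
phenotypes — the appropriate choice for preranked mode and a documented
divergence from the desktop tool's phenotype default. NES divides ES by
the mean absolute same-sign null ES; the nominal p is the add-one
empirical two-sided tail. The default ranking metric for DE-driven GSEA is
the signed Wald statistic. DAVID-style modified Fisher scores and any live
ontology services are out of scope; gene sets come from plain GMT files.

## TIL statistics

"Nonparametric t-test" is interpreted as the Mann–Whitney U test, the
standard nonparametric two-group location test at these sample sizes
(~12 cases). p-values are two-sided: exact by enumeration when
$n_a + n_b \le 12$ with no ties, otherwise the normal approximation with
tie and continuity correction. The two branches agree within 0.02 at
$n = 6 + 6$, which the tests verify against full enumeration.

## What the synthetic data emulate — and what they do not

The generator reproduces the statistical structure the analysis assumes,
with the study's own design as defaults: 11 CDC, 9 muscle-invasive UTUC
and 3 normal kidney libraries; NB counts with planted per-contrast log2
fold changes; library sizes drawn uniformly and applied as multiplicative
offsets (relative depth), precisely to exercise the normalisation stage.
Since no depth or dispersion estimates are published for these libraries,
defaults were chosen once for testability at realistic magnitudes:
baseline mean 100 counts/gene with a mean-preserving lognormal spread
(`baseline_log_sd = 1`, giving the right-skewed expression distribution
real data show; 0 recovers a constant-baseline model for moment checks),
dispersion 0.05 (a typical bulk RNA-seq order of magnitude), library-size
range 5×10⁵–2×10⁶.

The atlas generator plants eight nephron segments (Glom, PT1, PT2, mTAL,
cTAL, DCT, CCD, OMCD) with disjoint signature blocks (default 50
genes/segment, log-scale elevation 2, noise SD 0.5 — an effect four times
the noise), replicates per segment, and a mouse copy whose gene symbols
are title-case so cross-species matching is genuinely exercised. Tumor
cohorts are seeded from segment signatures: the cohort of interest
(labelled CDC) from a configurable segment, plus reference cohorts
(KIRC from PT1, KIRP from PT2, KICH from cTAL — proximal origins for
clear-cell and papillary, distal for chromophobe, as in the kidney-cancer
literature) that exist so the centroid centring has comparators; without
them the mapping is structurally uninformative, as explained above. TIL
records are normal location models clipped to [0, 100], baselines 20%
(CD3) and 10% (CD8) mirroring the reported magnitudes, with a location
shift for metastatic cases.

What passing tests therefore show: the pipeline recovers *planted*
structure of the kind the analysis assumes, at the study's sample sizes.
What they do not show: robustness to features real data have and the
generator omits — correlated genes, batch effects, outlier samples,
gene-length and GC biases, overlapping segment signatures, partial
orthology between species. Results on real cohorts depend on those.

The packaged clinical table is transcribed verbatim from the published
17-case cohort, including its typography (one `PT3a` capitalisation, rows
lacking the `p` prefix). Metastatic status is parsed from the `M1` suffix
of the pTNM string — the only place the table encodes it — which yields
8/17 = 47.1% metastatic at diagnosis, while the accompanying text says
44%; the table is kept verbatim and the discrepancy documented rather than
reconciled. Printed percentages (1.7%, 3.1%, 77.8%, 22.2%, 44.4%) are
recomputed from their stated numerators and denominators; the underlying
gene universe of 18,417 cannot be reconstructed without the undeposited
raw data, so absolute DE counts are treated as non-reproducible, as are
the per-case TIL percentages behind the published medians.

## Numerical choices and degenerate inputs

- IRLS: tolerance $10^{-10}$ on the max coefficient change, 50 iterations,
  means capped at $10^{12}$ to avoid overflow on diverging fits.
- BH: computed over non-missing p-values with $m$ = number tested; missing
  p-values (untestable genes) propagate.
- Variance ties in gene selection and correlation ties in assignment are
  broken deterministically (lexicographic order; all within-margin
  segments reported).
- Determinism: every generator takes an explicit seed and restores the
  caller's RNG state; pipeline stages derive stream-specific seeds from
  the run's master seed, all below $2^{31}$.
- Degenerate inputs error early with actionable messages: empty groups,
  non-integer or negative counts, duplicate identifiers, constant sample
  profiles (undefined correlation), gene sets covering the whole ranking
  (miss decrement undefined), zero-member GMT lines.

## Problem sizes used by the test-suite benchmarks

The calibration and recovery suites run at sizes chosen to estimate the
relevant rates with comfortable margin: the null calibration at 2,000
genes × (10 + 10) samples; fold-change recovery over 20 replicates of
1,000 genes with 100 planted genes; origin recovery over 20 replicates per
segment at 800 genes with 25-gene signatures (and 5 replicates per segment
in the acceptance script); the clustering benchmark at 1,000 genes over
the 11/9/3 design. These are the package's own choices of benchmark size;
the estimated rates are stable across seeds at these sizes.

## Known limitations

- No empirical-Bayes dispersion shrinkage or independent filtering; power
  at very small $n$ trails the major DE packages by design.
- Single-factor designs only (tissue type); no additional covariates.
- Ward-on-correlation is used as specified, not as Ward's criterion is
  formally defined.
- Cross-species matching is by symbol case-folding, not orthology.
- GSEA FDR for a single set equals its nominal p; collection-level runs
  get BH across sets rather than the desktop tool's NES-based FDR.
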