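# cdcseq

Bulk RNA-seq analysis of collecting duct carcinoma (CDC), a rare and
aggressive kidney cancer whose differential diagnosis against upper tract
urothelial carcinoma (UTUC) is a recurring clinical problem. The package
implements, as tested and reusable R functions, the transcriptomic workflow
used to characterise CDC against UTUC, normal kidney and the common renal
cell carcinoma (RCC) subtypes: count normalisation and filtering, per-gene
negative-binomial differential expression, unsupervised clustering and PCA,
gene-set enrichment, a nephron-atlas "cell of origin" correlation mapping,
and tumor-infiltrating-lymphocyte (TIL) comparisons. It is aimed at
computational biologists who want to run the same analysis on their own
count matrices, or to study its statistical behaviour under known ground
truth.

No sequence data are publicly deposited for this tumor type, so the package
also ships a first-class synthetic-data generator (negative-binomial counts,
a segment-annotated nephron atlas, TIL records — all with planted truth) and
the published 17-case clinical table, letting every stage run end to end out
of the box.

## The statistics at the core

* **Normalisation** — median-of-ratios scaling factors: with counts
  $K_{gj}$, the reference for gene $g$ is the geometric mean
  $(\prod_j K_{gj})^{1/n}$ over samples (genes with any zero excluded), and
  sample $j$'s factor is $s_j = \mathrm{median}_g\, K_{gj} / \mathrm{ref}_g$,
  rescaled to geometric mean 1. Genes below 1 count per million in every
  sample are excluded.
* **Differential expression** — a negative-binomial GLM per gene,
  $K_{gj} \sim \mathrm{NB}(\mu_{gj}, \alpha_g)$ with
  $\mathrm{Var} = \mu + \alpha\mu^2$,
  $\log \mu_{gj} = \beta_{g,\mathrm{tissue}(j)} + \log s_j$, dispersion by
  method of moments, fitted by IRLS. Any two tissues are compared with a
  Wald test $z = \hat\beta_A - \hat\beta_B$ over its standard error, p-values
  adjusted by Benjamini–Hochberg within each contrast, and genes called
  up/down at signed fold change $\ge 2$ (or $\le -2$) and FDR $< 0.05$.
* **Unsupervised structure** — hierarchical clustering on the Pearson
  correlation distance $d = 1 - r$ with Ward's linkage (Lance–Williams
  update applied to these distances as given), plus gene-centred PCA.
* **Cell of origin** — tumor profiles are centred per gene on the mean
  centroid of designated comparator cohorts, atlas profiles on the per-gene
  median; the Pearson correlation between every tumor sample and every
  nephron-segment profile over the case-insensitively matched gene symbols
  yields a segment assignment per tumor group (argmax of the mean
  correlation, with a confidence margin).
* **Enrichment** — hypergeometric over-representation of DE gene lists and
  weighted running-sum preranked GSEA with a gene-label permutation null.
* **TIL comparisons** — Mann–Whitney U, exact by enumeration for small
  tie-free samples.

## Worked example

```r
library(cdcseq)

cfg <- simulation_config(
  n_genes = 1000, group_sizes = c(CDC = 11, UTUC = 9, NORMAL_KIDNEY = 3),
  dispersion = 0.05,
  lfc_spec = list(lfc_entry(1:40, c("CDC", "NORMAL_KIDNEY"), 2),
                  lfc_entry(41:80, c("CDC", "NORMAL_KIDNEY"), -2)),
  seed = 17)
sim <- simulate_counts(cfg)
de <- run_pairwise_de(sim$counts, sim$annotations,
                      contrasts = list(c("CDC", "NORMAL_KIDNEY")))
table(de$call)
#> down   ns   up
#>   38  923   39
```

Eighty genes were planted at a true four-fold change (40 up, 40 down in CDC
versus normal kidney); the workflow calls 77 of them plus no more than a
handful of borderline extras, e.g.:

```r
head(de[de$call == "up", c("gene_id", "log2fc", "signed_fc", "q_value")], 2)
#>     gene_id   log2fc signed_fc      q_value
#> 1 GENE00001 1.836907  3.572434 7.819299e-12
#> 2 GENE00002 2.341036  5.066662 4.260936e-29
```

`log2fc` is the Wald contrast estimate on the log2 scale and `signed_fc`
the linear fold change with sign (so −2 means two-fold down). The clinical
table and the origin mapping run the same way:

```r
summarize_clinical(load_clinical_fixture())
#> 17 cases; median age 60 (range 17-78); M/F 11/6
#> AJCC stages 2/3/4: 1/8/8; metastatic at diagnosis: 8 (47.1%)
#> RNA-seq available: 11; IHC available: 12

atl <- simulate_atlas_and_tumors(atlas_simulation_config(seed = 17))
res <- map_cell_of_origin(atl$tumors, atl$atlases$human,
                          cohort_labels = atl$tumor_cohorts)
res$assignment[, c("group", "segment", "mean_r", "confident")]
#>   group segment    mean_r confident
#> 1   CDC     DCT 0.2749273      TRUE
#> 2  KIRC     PT1 0.2092054      TRUE
#> 3  KIRP     PT2 0.2123214      TRUE
#> 4  KICH    cTAL 0.2175884      TRUE
```

The CDC-like cohort, planted on the distal convoluted tubule (DCT)
signature, is mapped back to the DCT; the comparator cohorts map to their
own seeding segments. `run_pipeline()` chains all stages with provenance
records; see the methods vignette (`vignettes/cdcseq-methods.Rmd`) for the
modelling choices and their rationale.

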