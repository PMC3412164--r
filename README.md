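# sigrank

Rank-ordering of expression profiles by gene-set signature strength, for
choosing cell-based models objectively.

## The problem

Intestinal and colorectal-cancer research leans on a large panel of cell
lines (Caco-2, HT29, SW480, SW620, T84, ...) whose suitability for a given
question — tumor invasion, drug absorption, chemosensitivity — is usually
decided by habit. A more objective alternative: score each line (and
reference tissues such as microdissected normal epithelium and tumor cells)
against gene-set signatures of the traits that matter — epithelial–
mesenchymal transition (EMT), Wnt target activity, intestinal stem-cell
genes, transporter families (SLC/ABC), proliferation — and pick models by
their rank.

`sigrank` implements that pipeline end to end, offline, with a synthetic
data generator that plants known structure so every stage is testable
without downloads.

## The core procedure

Given a log2 expression matrix **X** (features × samples), replicate groups
*g*, and gene sets *S*:

1. **Quantile-normalize** the columns of **X**.
2. **Collapse probes to genes**: per gene keep the probe set with the
   highest standard deviation across all samples (ties → lexicographically
   smaller probe id).
3. **Center gene-wise** across *all* samples: `x̃_ij = x_ij − mean_j(x_ij)`.
4. **Score**: for set *S* and sample *j*, `score_j(S) = mean_{i∈S} x̃_ij`;
   a group's score is the mean over its replicates.
5. **Rank**: per signature, groups sorted by descending score; rank 1 =
   strongest signature.

Around it:

- **GSEA** with the weighted Kolmogorov–Smirnov enrichment score
  (exponent *p*, default 1) and a **gene-set-resampling null**: the null
  ES distribution comes from random gene sets of the same cardinality drawn
  from the ranked list, not from phenotype permutation. p-values use the
  add-one estimator over same-sign nulls; NES = ES / mean |same-sign null
  ES|; FDR q from the pooled sign-normalized null.
- **GI50 mining**: correlate gene expression with −log₁₀(GI50) across a
  cell-line panel, keep genes with |r| > 0.5 for ≥ 3 compounds, split them
  into response-positive / response-negative signatures by average-linkage
  clustering of the correlation profiles.
- **Survival stratification**: dichotomize a cohort at the mean signature
  score (or at 0), Kaplan–Meier curves, two-group log-rank test.

## Worked example

```r
library(sigrank)

spec <- synthetic_spec(seed = 42, n_genes = 400, n_groups = 6, replicates = 3,
                       signatures = list(EMT_like = list(size = 40, delta = 0.8)),
                       n_decoy_sets = 2, decoy_size = 25)
comp <- generate_expression_compendium(spec)

expr <- quantile_normalize(comp$expr)
expr <- collapse_probes_max_sd(expr, comp$probe_map)
rt   <- build_rank_table(center_genes(expr), comp$sets, comp$grouping)
print(rt)
#> RankTable: 6 group(s) x 3 signature(s)
#>     EMT_like decoy01 decoy02
#> G01        1       1       1
#> G02        2       2       4
#> G03        3       3       6
#> G04        4       6       5
#> G05        5       5       2
#> G06        6       4       3
```

The planted ordering was `G01 > G02 > ... > G06` (mean shifts spaced 0.8
log2 units, noise SD 0.5): the `EMT_like` column recovers it exactly; the
decoy columns mostly don't (their partial agreement at the top comes from
decoy sets sampling a few planted genes).

```r
gsea_two_condition(comp$gene_level, comp$grouping, "G01", "G06", comp$sets,
                   n_resamples = 1000, seed = 42)
#>       set size    es   nes p_value   fdr
#>  EMT_like   40 1.000 1.953 0.00101 0.000
#>   decoy01   25 0.503 0.965 0.58792 0.899
#>   decoy02   25 0.412 0.770 0.82618 0.831
```

Only the planted set is enriched in the G01-vs-G06 contrast (NES 1.95,
p ≈ 1/(n_same_sign_nulls + 1); decoys stay at chance).

```r
score  <- colMeans(center_genes(comp$gene_level)$values[comp$sets$EMT_like, ])
cohort <- generate_survival_cohort(spec, score)
cohort <- dichotomize_by_score(cohort, "zero_split")
#> dichotomize_by_score (zero_split): 9 low, 9 high
logrank_test(cohort)
#> Log-rank test: chisq = 13.3084 (1 df), p = 0.0002642; n = low: 9, high: 9
```

The generator gives high-score samples a hazard ratio of 2 per unit score,
and the log-rank test sees it even at n = 18.

## Command line

```sh
inst/cli/sigrank simulate --seed 3 --out-dir sim/
inst/cli/sigrank rank --expr sim/expression.tsv --groups sim/groups.tsv \
    --gmt sim/sets.gmt --probe-map sim/probe_map.tsv --out table1.tsv
inst/cli/sigrank run --config cfg.json   # declarative multi-stage run
```

`run` executes any subset of the stages `rank`, `gsea`, `gi50`, `survival`
from one JSON config and writes a manifest with input MD5 checksums and the
seed, so reruns are verifiably identical.

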