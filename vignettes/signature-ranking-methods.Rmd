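---
title: "Signature scoring, enrichment and response mining: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature scoring, enrichment and response mining: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigrank)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, and the choices made where
the design was genuinely open. It states no empirical result that the test
suite does not itself compute.

## 1. The signature score and rank table

The scoring model is deliberately simple. For a gene-level log2 matrix with
samples organized into replicate groups (cell lines, microdissected tissue
pools), the score of gene set $S$ in sample $j$ is

$$ \mathrm{score}_j(S) \;=\; \frac{1}{|S'|}\sum_{i \in S'} \tilde x_{ij},
\qquad \tilde x_{ij} = x_{ij} - \frac{1}{n}\sum_{j'} x_{ij'} , $$

where $S'$ is the intersection of $S$ with the matrix's genes. Group scores
are means over replicate samples; per signature, groups are ranked by
descending score (rank 1 = strongest).

Assumptions worth making explicit:

* **Centering is compendium-relative.** Genes are zero-centered across
  *all* samples supplied, so a score is relative expression against the
  average of whatever compendium you assembled. Adding or removing samples
  changes every score (the rank table is a property of the compendium, not
  of a sample in isolation). The test suite checks the complementary
  invariance: adding a constant to the whole matrix changes nothing.
* **Replicate aggregation point.** Samples are scored first and group
  scores are means of sample scores. Because the set-average and the
  replicate-average are both linear, averaging in the other order gives the
  same number for complete data; scoring per sample first keeps groups with
  2 vs 3 replicates exactly comparable and makes per-sample scores
  available (they feed the survival module).
* **Missing set genes are dropped**, not imputed as zero: a zero is a real
  statement ("expressed at the compendium average"), and padding with zeros
  would shrink scores toward 0 by an amount depending on annotation
  coverage rather than biology.
* **Ties.** Exact score ties get ranks in group order (order of first
  appearance in the grouping file). On real data exact ties have measure
  zero; the rule exists so outputs are deterministic and order-independent
  tests can be written.

Upstream of scoring, two preprocessing rules mirror standard microarray
practice: quantile normalization of the already-summarized columns, and
probe-to-gene collapse keeping the probe set with the **largest sample
standard deviation** (denominator $n-1$; the convention matters less than
fixing one) across all samples. SD ties break to the lexicographically
smaller probe id — again determinism, not biology.

## 2. Enrichment analysis with a gene-set-resampling null

The enrichment score is the weighted Kolmogorov–Smirnov running-sum
statistic: walking down a ranked list of $N$ genes, a member of $S$ at
position $i$ adds $|m_i|^p / \sum_{k \in S}|m_k|^p$ and a non-member
subtracts $1/(N - N_h)$; ES is the signed maximum deviation from zero
(positive preferred on an exact magnitude tie). The weight exponent $p$
defaults to 1, the standard weighted form; $p = 0$ gives the classical
equal-weight statistic. When all metrics are zero (a group contrasted with
itself) the weights degenerate; the implementation falls back to equal
weights so the statistic is still defined.

The null model is **gene-set resampling**: ES values of random sets of the
same cardinality drawn uniformly (without replacement by default) from the
ranked list's genes. This tests "is this set more extreme than a random set
of genes of the same size on this fixed ranking" — it is *not* the
phenotype-permutation null of canonical GSEA and does not account for
inter-gene correlation under label exchange. It is cheap, needs no
replicate structure, and is the appropriate null when the ranking itself is
a fixed derived quantity (e.g. one cell line against a pooled tissue
panel). A `replace = TRUE` flag provides a bootstrap-flavored variant
(duplicates collapse); without replacement is the default because a gene
set is a set.

Estimator choices:

* $p$-value: add-one estimator over same-sign nulls,
  $p = (1 + \#\{|ES_0| \ge |ES|\}) / (1 + \#\text{same-sign nulls})$.
  It can never be exactly 0; a published "p = 0.000" is read as "below
  resolution".
* NES $= ES / \mathrm{mean}\,|ES_0^{\text{same sign}}|$; undefined (NA,
  flagged `unstable`) if no same-sign nulls exist.
* FDR: pooled sign-normalized null scores across all tested sets; $q$ =
  (tail fraction of pooled same-sign normalized nulls beyond NES) / (tail
  fraction of observed NES beyond it), capped at 1.
* Seeding: one integer seed; in collection mode each set gets `seed + i` so
  results are independent of collection order and bit-reproducible.

The ES implementation exists twice on purpose: the user-facing
`enrichment_score()` builds the full $O(N)$ running-sum profile, and an
internal $O(|S|)$ closed form evaluates null draws (extrema can only occur
at a hit or immediately before one). The suite proves the two equal on
random inputs, and both equal a step-by-step loop oracle to $10^{-12}$.

## 3. GI50 response mining

Drug sensitivity is encoded as $-\log_{10}(\mathrm{GI50})$ (molar), so
larger = more sensitive; base 10 is the NCI convention and is configurable.
The mining chain is: drop drugs not measured in every line or with SD
$\le 0$ across lines; Pearson-correlate (Spearman optional) each gene with
each drug over pairwise-complete lines (minimum 3 observations per pair);
keep genes with $|r| > 0.5$ (strict) for $\ge 3$ compounds; split the kept
genes into two clusters by average-linkage hierarchical clustering of
their correlation profiles with distance $1 - r$ (or $1 - \rho$); the
cluster with the larger mean profile is the response-positive signature.
The two-cluster cut is the dendrogram root ($k = 2$); if all profiles are
identical there is no structure and the function errors rather than
inventing a split. Pearson on log2-vs-$-\log$ values is the default because
both axes are already variance-stabilized logs.

`rank_response_association()` closes the loop to the rank table: per drug,
the Spearman correlation between a signature's rank order over a line panel
and $-\log(\mathrm{GI50})$. Since rank 1 is the *strongest* signature, a
negative correlation means stronger signature goes with greater
sensitivity.

## 4. Survival stratification

Cohorts (time, 0/1 event, per-patient signature score) are dichotomized
either at the cohort mean score or at zero — the source material states the
split both ways, so both are implemented and neither is privileged; scores
exactly at the split go to "low" (strict `>`). Kaplan–Meier is the plain
product-limit estimator (censored-at-event-time patients count as at risk);
the log-rank test is the two-group Mantel–Haenszel form with hypergeometric
variance and a $\chi^2_1$ reference. Both are authored in the package and
cross-checked in the suite against a per-event-time 2×2 oracle and against
`survival::survdiff`.

## 5. The synthetic world

`synthetic_spec()` fixes a stated world; its defaults are the conditions
the pipeline was designed around, chosen once:

| parameter | default | why |
|---|---|---|
| `replicates` | 3 | matches the 2–3 replicates per sample of the motivating design |
| `noise_sd` | 0.5 log2 units | typical replicate-level spread of RMA-summarized arrays |
| signature | 50 genes, shift spacing `delta` = 1 | spacing = 2×noise SD, the regime the rank-recovery property is stated at |
| probes/gene | 2–4, one informative | the max-SD collapse rule must have something to choose between; non-informative probes carry 20% of the signal plus jitter (SD 0.25) |
| `baseline_mean`, `baseline_sd` | 7 ± 1 log2 units | plausible microarray intensity scale; scores are centering-invariant to it |
| GI50 block | 50 drugs × 59 lines, 30+30 coupled genes, slope 1, response noise 0.3 | NCI60-shaped; the published panel filter ("all 59 lines, SD > 0") applies as-is |
| survival | baseline hazard 0.05, log HR = log 2 per unit score, 30% censoring | one event per 20 time units at score 0; a clearly detectable but not degenerate effect |

One generator detail is load-bearing enough to spell out: the drug-response
generator **injects a shared latent sensitivity factor** $u(\text{line})$
into the coupled genes ($+u$ for the positive half, $-u$ for the negative)
before computing responses as slope × signed mean of coupled centered
expression + noise. Without a shared factor, thirty independent genes each
correlate only $\approx 1/\sqrt{30}$ with their own average, and no slope
could ever push individual genes past the $|r| > 0.5$ selection threshold —
the planted-recovery property would be vacuously unattainable. The
generator therefore returns the modified expression matrix alongside the
response matrix.

What the generator deliberately does **not** emulate: batch effects,
heavy-tailed or intensity-dependent noise, correlated decoy sets,
probe-level saturation, informative censoring, and cohort covariates. A
green recovery test therefore establishes correctness of the *procedure*
under its stated assumptions, not robustness to the full messiness of real
arrays.

All generators are pure functions of (spec, seed); the three generators use
seed offsets +0/+1/+2 from the spec's master seed so one spec can drive all
three without stream collisions.

## 6. Numerical and testing choices

* Quantile normalization assigns the rank-mean vector through `order()`,
  which resolves ties by input position — making the operation exactly
  idempotent (checked as identity, not with a tolerance).
* Expression TSVs are written with 17 significant digits so read/write
  round-trips are bit-exact.
* PCA drops null-variance components and fixes each component's sign so its
  largest-magnitude loading is positive.
* The rank-symmetry acceptance check (`delta = 0` ⇒ every group equally
  likely to rank first) uses a chi-square goodness-of-fit test at the 99.9%
  quantile rather than a per-group ±2 SE band: ten simultaneous 2 SE bands
  would reject a *correct* implementation roughly 40% of the time, which is
  a property of the band, not of the code.
* Monte-Carlo calibration tests (GSEA and log-rank type-I error in
  [0.037, 0.065] at $\alpha = 0.05$, 1000 replicates) use fixed seeds; the
  add-one p-value estimator makes both tests mildly conservative, which the
  stated band accommodates.

## 7. Known limitations

* The pipeline starts at summarized log2 matrices; CEL-file processing,
  background correction and RMA summarization are out of scope.
* The gene-set-resampling null ignores inter-gene correlation; its
  p-values are calibrated against random gene sets, not against phenotype
  exchangeability.
* Probe-to-gene collapse depends on the annotation release used to build
  the probe map; results on real arrays inherit that dependency.
* Published signature memberships (EMT, Wnt targets, stem-cell sets) are
  consumed as GMT inputs; only the fold-change-within-family rule (e.g.
  SLC genes ≥ 2-fold in small intestine vs a pooled reference) is
  re-derivable from data.
* `run_pipeline()` emits tables, not figures; plotting is left to the
  caller.
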