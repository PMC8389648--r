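---
title: "Gene set regularity analysis: model, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene set regularity analysis: model, assumptions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsreg)
```

## The model

`gsreg` asks, per gene set, whether the *relative ordering* of member
gene expression values — not their magnitudes — is conserved between a
case group and a control group. The approach descends from differential
rank conservation (DIRAC): rank statistics are insensitive to monotone
normalization differences between array platforms, which is what makes
pooling heterogeneous cohorts workable.

**Template.** For a set of $m$ genes there are $\binom{m}{2}$ unordered
pairs. Each control sample votes on each pair by strict comparison of
the two expression values; the template stores the majority direction
and its support (fraction of controls voting that way, necessarily in
$[0.5, 1]$). The per-pair majority maximizes the summed pairwise
agreement with the control cohort, which is the precise sense in which
the template is "the most common gene expression ordering" of the
controls.

**GSR index.** A sample's index is the fraction of pairs whose
in-sample ordering matches the template:
$$\mathrm{GSR} = \frac{\#\{(i,j): \text{sample agrees with template}\}}{\binom{m}{2}} \in [0, 1],$$
so 1 means the set's regularity is intact and 0 means every pair is
reversed. Under a uniformly random ordering each pair agrees with
probability $\tfrac12$, so the null expectation is 0.5 — a useful
calibration point that the test suite checks by simulation. The vector
of indices over the whole collection is the sample's functionome
profile.

**Screening.** Case and control per-sample GSR values are compared per
set with a two-sided Mann–Whitney U-test; p-values are adjusted across
sets by Benjamini–Hochberg. The test is exact for pooled sample sizes
up to 20 without ties, otherwise the normal approximation with tie and
continuity corrections is used. Sets on which every sample of both
groups has an identical index carry no ordering information and are
assigned $p = 1$ rather than an undefined value, so null fixtures and
degenerate sets behave sanely.

**Term and pathway rankings.** Two deliberately different countings are
first-class outputs:

* *Dysregulated GO terms* are the $q$-significant sets, ranked by the
  cluster weight index $\mathrm{CWI}_t = w_t / \sum_u w_u$ with
  $w_t = -\log_{10}\max(q_t, \varepsilon)$, the sum running over all
  clustered significant terms, so $\sum_t \mathrm{CWI}_t = 1$. Clusters
  are connected components of the subgraph the significant terms induce
  on the GO graph's undirected is_a edges (one global cluster when no
  ontology is supplied); the cluster label is reported per term.
  Optionally each $w_t$ is multiplied by the absolute weight the term
  receives from a fitted classifier (`svm_weights`), tying the ranking
  to discriminative importance.
* *Dysfunctional pathways* are ranked by raw $p$ with a less stringent
  default threshold (unadjusted $p < 0.05$). Reported real-data
  countings of "pathways" are far larger than countings of "terms" under
  the same screen, which is only reproducible with a laxer criterion;
  both rankings are exposed and the threshold is configurable
  (`adjusted = TRUE` uses $q$).

## Tunable parameters

| parameter | default | units / range | rationale |
|---|---|---|---|
| `min_set_size` | 5 | genes, floor 2 | fewer than ~5 genes gives a very coarse index (steps of $1/\binom{m}{2}$) |
| `alpha` | 0.05 | significance level | conventional; applied to $q$ for terms, raw $p$ for pathways |
| `epsilon` | 1e-16 | floor on $q$ | keeps $-\log_{10} q$ finite at $q = 0$ |
| `k` | 50 | list length | the usual top-k reporting depth for ranked term/pathway lists |
| `folds`, `repeats` | 5, 10 | cross-validation design | five-fold CV with ten repeated reshufflings |
| `C`, `sigma` | 1, median heuristic | SVM regularization / RBF bandwidth | no hyperparameter search; the median pairwise distance heuristic ($\sigma = 1/(2h^2)$) is scale-adaptive and deterministic |

**Tie rule.** Expression ties within a sample (and exact 50/50 template
votes) are broken by "the lexicographically smaller gene symbol is
deemed lower", identically during template voting and index scoring.
Any fixed symmetric rule works; this one is deterministic, involves no
RNG, and cancels out between template and sample — the dedicated tie
tests exercise both sides. Rank ties in all orderings (CWI, p-value,
intersection output) break by set identifier, so every reported rank is
a reproducible permutation.

**Decision-score orientation.** The underlying SVM library's decision
value sign convention depends on the order classes appear in the
training data, so decision scores are re-oriented against the model's
own predicted labels on the training fold before pooling; AUC is then
computed by the rank (Mann–Whitney) formulation with ties counted
one half.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` draws distinct gene baselines $\mu_g \sim
U(0, 10)$ (re-jittered in the measure-zero event of ties, so the
canonical control ordering is unambiguous), and control samples are
$\mu_g + N(0, \sigma^2)$. Case samples are identical *except* that
within each designated dysregulated set, independently per case sample,
$\lceil \theta m \rceil$ of the $m$ member genes have their baselines
randomly permuted among themselves before noise is added. This destroys
ordering regularity with controlled intensity $\theta$ while leaving
each gene's marginal intensity distribution untouched — exactly the
alternative the GSR index is designed to detect, and one a mean-based
differential-expression test cannot see. Scrambling is drawn per sample
(not once per group) so cases are exchangeable draws from a disordered
distribution rather than carriers of a second fixed ordering.

Defaults (200 sets of 10 genes, 30 controls vs 30 cases, $f = 0.2$,
$\theta = 1$, $\sigma = 0.1$ on baselines spread over $[0, 10]$) give a
well-powered but not trivial screen at roughly the per-group sample
scale of the smaller disease groups in published serous ovarian cohort
studies.

The generator deliberately does **not** emulate: platform batch
effects, probe-level noise or probe-to-gene mapping ambiguity,
correlated genes outside the scrambled sets, partial overlap between
gene sets (sets are disjoint by default), missing data, or survival
outcomes. Passing the recovery and calibration suites therefore shows
the statistics behave as designed under their own model — it does not
certify performance on real microarray compendia, whose headline
numbers (group mean GSR per stage, 95–100% classification ranges) are
functions of 1,100+ GEO samples that are out of desk scope here.

## Numerical and design choices

* **Exactness boundary.** The Mann–Whitney implementation switches from
  the exact distribution to the tie-corrected normal approximation at a
  pooled $n$ of 20; GSR values from small sets are heavily tied, so the
  tie-corrected path is the common one at realistic sizes.
* **Duplicate gene rows** (multiple probes per symbol) collapse by
  per-sample maximum on ingest: deterministic, monotone, and
  platform-agnostic. Alias resolution is out of scope; symbols match by
  case-sensitive string equality.
* **Missing data** drops the whole sample profile (with a warning), not
  the gene: a profile with missing cells cannot vote on all pairs, and
  abandoning it keeps every template built from complete profiles.
* **Pooled control template.** One template per set is built from the
  pooled control group and reused against every case group. Per-dataset
  templates are a possible variant when batch structure is strong; the
  pooled choice matches a single-reference-ordering design and keeps
  case groups comparable against one reference.
* **Group summary "correction".** The per-group summary reports the
  case grand mean GSR *alongside* the control grand mean rather than
  applying an arithmetic correction, since published "corrected" group
  means coincide with raw case means; both numbers are always present
  so any rectification convention can be applied downstream.
* **Curated inputs stay inputs.** The three-category regrouping of the
  25 common dysregulated terms is expert curation, so it ships as a
  fixture (`top25_term_categories()`); the per-category most-relevant
  genes are packaged as an expected-output reference
  (`category_top_genes()`) for regression comparison, not asserted as
  algorithm output. Likewise the survival screen is an external filter:
  `apply_gene_filter()` accepts a keep list (e.g. genes with consistent
  progression-free and overall survival effects) rather than computing
  hazard ratios.

## Problem sizes used in validation

The test suite validates at sizes chosen to make the statistical
properties sharp while staying quick: 200 random oracle instances at
set sizes up to 6; 10,000 random orderings of an 8-gene set for the
0.5-calibration; 20 null cohorts (200 sets, 30 vs 30) for FDR
calibration; one recovery cohort (200 sets, $f = 0.2$, $\theta = 1$,
30 vs 30, seed 1) for sensitivity/precision and SVM accuracy; and a
five-point $\theta$ grid (40 sets, 50 vs 50) for monotonicity.

## Known limitations

* The GSR index ignores pair support: a pair conserved in 51% of
  controls counts the same as one conserved in 100%. Support is stored
  on every template, so a weighted index is a natural extension.
* With strongly tied expression (e.g. zero-inflated single-cell
  counts), the lexicographic tie rule injects an arbitrary but fixed
  ordering; indices remain well-defined but their null expectation
  shifts away from 0.5.
* The CWI clustering depends on which ontology edges are supplied;
  with no graph it degenerates to a single cluster, making CWI a pure
  $-\log_{10} q$ share.
* `intersect_top_pathways()` requires presence in *every* group's
  top-k list; a pathway ranked 51st in one group drops out entirely.
  The mean-rank ordering of survivors partially mitigates this
  all-or-nothing behavior.
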