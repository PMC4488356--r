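---
title: "chemodev: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chemodev: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`chemodev` detects genes whose expression in drug-resistant tumour
samples escapes the "normal range" spanned by chemotherapy-sensitive
samples, and carries that signal through subgrouping, gene allocation,
pathway scoring, network hub selection and classifier validation. This
vignette records the statistical model, the package's conventions for
every ambiguous or degenerate case, and the reasoning behind design
choices that were genuinely open.

## The deviation statistic

For each gene the sensitive (CR) samples define a normal range
`mean ± sd` (sample standard deviation, `n − 1` denominator — used
consistently everywhere a spread is computed in this package; with the
small group sizes typical of these cohorts the distinction from the
`n` denominator is material). Each resistant (NOCR) sample contributes
the signed clamped excess beyond the range, and the per-gene score is
the sum of contributions.

Two accumulation conventions are provided:

* `statistic = "signed"` (default): contributions keep their sign, so a
  gene deviating upward in one subgroup and downward in another can
  partially cancel. This is the statistic as printed in the source
  method. Significance is assessed two-sided, on `|score|`.
* `statistic = "absolute"`: contributions enter as magnitudes. This
  variant cannot cancel and is the more powerful choice when
  subgroup-restricted deviations of opposite sign are expected; it is
  provided because the method's own outputs track up- and downregulated
  genes separately, which suggests direction matters downstream.

The default stays faithful to the printed formula; the alternative is a
documented robustness option, not the default.

**Permutation test.** Group labels are reassigned uniformly at random
(sampling without replacement, preserving `n1`/`n2`), the range and
score recomputed per permutation, and the p-value is the add-one
empirical tail `(#{|score_b| ≥ |score|} + 1)/(B + 1)`. The add-one
correction avoids `p = 0` at finite `B` and makes the minimum
attainable p-value `1/(B + 1)`. One shared, seeded sequence of label
shuffles is reused across genes: this is substantially faster than
independent streams, makes the full gene table reproducible from a
single seed, and induces only the weak across-gene dependence that any
common relabelling scheme has (each gene's marginal null is exact
either way). Significance is called at raw `p < 0.05`; no
multiple-testing correction enters the pipeline's calls, matching the
method being reproduced, but a Benjamini–Hochberg column is emitted so
users can apply a stricter convention.

Degenerate cases: a gene constant across all samples scores 0 in every
permutation and gets `p = 1`; a zero-variance sensitive group yields a
degenerate (point) range with a warning.

## Subgrouping

Clustering operates on the significant-gene submatrix only. The
protocol mirrors the Cluster 3.0 conventions: median centering (one
pass over genes, then one pass over samples — not iterated to
convergence), centred Pearson correlation converted to the distance
`1 − r`, and average-linkage (UPGMA) agglomeration. Merge ties are
resolved by `stats::hclust`'s deterministic ordering, so results are
invariant to sample input order up to subgroup relabelling.

The source method cut its dendrograms by visual inspection and never
stated `k`. The package exposes `k` directly and, when `k` is not
given, selects it from `2..min(10, n − 1)` by maximal mean silhouette
width on the same correlation distance — a reproducible, principled
stand-in for visual cutting. A subgroup is flagged *resistant* when
NOCR samples form a strict majority; ties flag sensitive, with a
warning, and tied dominant labels are broken lexicographically and
flagged.

## Gene allocation

The *fluctuation range* of a reference group is read as
`mean ± sd` over that group's samples, mirroring the normal-range
construction of the deviation statistic — the source text is ambiguous
(it could also mean the span of per-subgroup means), and internal
consistency favours the former. The span reading is available via
`range_method = "span"`. A significant gene is specific to a resistant
subgroup when its subgroup mean escapes the sensitive range; sensitive
allocations use the pooled resistant samples as reference. Genes may be
specific to several subgroups at once — the method's own subgroup gene
counts require overlapping sets — and `common_resistant` is the
intersection across resistant subgroups (`common_scope = "all"`
additionally intersects the sensitive allocations, covering the
alternative reading of "intersection of subgroups 1–4").

Allocation is a deterministic rule, not a second hypothesis test; no
re-testing of allocated genes is performed.

## Pathway analysis

Over-representation uses the hypergeometric upper tail
`P(X ≥ k)` with the universe set to the genes present in **both** the
expression matrix and the pathway collection (the original analysis
delegated this to a web service whose universe is unknown; ours is
explicit and configurable by passing a different `universe`).
Benjamini–Hochberg q-values are reported; significance is called on raw
`p < 0.05` to match the reproduced procedure.

The pathway deviation score is
`A(P) = log10((1/N) Σ_i (X̄_i − Ȳ_i)²)` with `N` the number of
significant genes annotated to the pathway, `X̄_i` the gene's mean in
the scored subgroup and `Ȳ_i` its mean over all sensitive samples. Two
conventions in the source conflict: the displayed equation includes the
`1/N` factor, the prose ("cumulative sum") omits it. The displayed
equation is the default; `variant = "cumsum"` gives the prose reading.
`N` is taken as the pathway's significant genes — the same set for
every subgroup — so scores are comparable across a profile row. When
the mean squared deviation is exactly 0 the logarithm is undefined and
the score is reported as `NA` (never `-Inf`, keeping TSV round-trips
clean); note that scoring the entire sensitive group against itself is
such a case by construction.

## Network biomarkers

The interaction network is restricted to the candidate genes (members
of significantly enriched/deviating pathways) plus the common
resistance genes, and degrees are counted **inside** this induced
subgraph — matching the description of hubs interacting with candidate
and common genes; degrees in the full input graph are available by
passing the full gene set as `node_set`. Edges are unweighted and
undirected; self-loops and duplicate orientations are removed on
reading; confidence scores, if present in the input, are ignored.

Selection uses the base-2 log-degree threshold 4.7 with a **strict**
inequality, i.e. degree ≥ 26. The source states both "at least 25
partners" and "log2 degree > 4.7"; these disagree at degree 25
(`log2 25 ≈ 4.64`), and the logarithmic threshold — the one used to
produce the reported biomarker table — is taken as operative.
Degree-0 nodes have no finite log-degree (`NA`) and are never selected.

## Classifier validation

Biomarker expression is ternarized per cohort: values strictly above
`μ + s` map to 1, strictly below `μ − s` to −1, all else (boundaries
included) to 0, with `μ`, `s` computed within each cohort
independently — this per-cohort standardization is what absorbs
platform differences between discovery and validation data. The rule
commutes with any increasing affine per-gene transform, so z-scored and
raw inputs discretize identically. A classification tree (Gini
impurity, minimum split 2, minimum leaf 1, no pruning, fixed seed; all
exposed) is trained on the discovery cohort and scored on validation.
The report gives per-class precision, recall, F1 and support plus
accuracy and **both** macro and support-weighted averages: the
reproduced work's summary row matches neither convention exactly, so
both are reported and neither is privileged.

## The synthetic generator

`synthetic_config()` defaults describe the study conditions the package
is tested under: 24 sensitive / 22 resistant patients (a basal-like
discovery cohort), two latent subgroups per phenotype, 600 genes of
which 60 are common resistance genes, 60 per resistant subgroup are
subgroup-specific and 60 per sensitive subgroup are sensitive-subgroup
markers, all shifted by `effect_size = 2` baseline standard deviations
(`noise_sd = 1`) with a per-gene random sign; 20 pathways of 15 genes
(one planted per resistant subgroup at ≥ 80% subgroup-specific
membership); 9 network hubs of guaranteed degree 32 over a 1%
background edge density. Counts were chosen to keep every stage's
recovery measurable at realistic cohort sizes: signatures of tens of
genes and an effect of two noise standard deviations are typical of
what microarray studies report for strong subtype markers.

Two structural choices deserve note:

* **Biology vs noise seeding.** Gene roles and shift directions derive
  only from `seed`; per-sample noise derives from `noise_seed`. A
  validation cohort drawn with a different `noise_seed` therefore
  shares the study's biology (same signal genes, same directions) while
  containing entirely new patients — without this split, cross-cohort
  validation would be testing against a different disease.
* **Hub wiring.** Hubs are drawn from the common resistance genes and
  preferentially wired to other common resistance genes: hubs sit at
  the intersection of the subgroups' mechanisms, and this wiring keeps
  their connectivity inside the candidate + common node set that the
  biomarker stage restricts to.

What the generator does **not** emulate: probe-level artifacts, batch
effects, RMA preprocessing, correlated co-expression modules,
non-Gaussian heavy tails, or annotation noise in pathways and
interactions. Passing recovery tests therefore demonstrates the
pipeline's correctness and statistical calibration under an idealized
Gaussian shift model — not its performance on real microarray cohorts.

## Problem sizes and determinism

The test-suite and acceptance checks run at the generator's default
sizes (600 genes × 46 samples) with 1,000 label permutations for
calibration/power checks and 10,000 for the end-to-end run and the
small-sample enumeration comparison; these sizes give binomial
tolerances well inside the asserted bands while keeping a full run in
seconds. Exhaustive-enumeration cross-checks use cohorts of ≤ 10
samples, where all `C(n, n1)` label splits are enumerable. Every
random quantity (generation, permutations, tree fitting) is driven by
explicit integer seeds, and the pipeline writes a manifest sufficient
to reproduce a run byte-for-byte.

## Known limitations

* The permutation p-value resolution is `1/(B + 1)`; at `B = 1000` the
  significance call at 0.05 effectively thresholds at `p ≤ 0.04995`.
* Silhouette-based `k` selection favours compact, well-separated
  subgroups; at weak effect sizes it may merge the sensitive subgroups
  (their markers rarely reach significance, so the clustering matrix
  carries little signal for them). This mirrors the behaviour of visual
  dendrogram cutting on weak structure.
* With the signed statistic, a gene deviating symmetrically in opposite
  directions across subgroups can score near 0 and be missed; use the
  absolute statistic when such genes are the target.
* The decision tree is deliberately simple (no cross-validation or
  hyperparameter search); it validates biomarker informativeness rather
  than maximizing predictive performance.
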