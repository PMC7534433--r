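---
title: "Validating regulatory-network predictions with shared-ratio overlap statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating regulatory-network predictions with shared-ratio overlap statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnoverlap)
```

## The problem

Genome-scale network-inference methods such as GENIE3 rank millions of
putative regulator-target links from expression compendia, but the ranking
itself carries no guarantee of biological relevance. A cheap, direct check is
to confront the predicted target set of a regulator with independent
experimental evidence: the genes that change expression when that regulator
is knocked out. If the network is informative, a regulator's predicted
targets should overlap the knockout's differentially expressed genes (DEGs)
far more than the targets of a randomly chosen transcription factor do.

`grnoverlap` implements that validation for hexaploid-wheat-style settings:
a trimmed weighted edge list, DEG tables at one or more timepoints, and the
polyploidy-specific structure of homeolog triads (the A/B/D subgenome copies
of a gene) with their expression-movement categories.

## The shared ratio

For two gene sets $A$ and $B$ the package's overlap statistic is

$$\mathrm{SR}(A, B) \;=\; \frac{|A \cap B|}{\min(|A|, |B|)},$$

the fraction of the smaller set that the two sets share. It is symmetric,
lies in $[0, 1]$, equals 1 exactly when the smaller set is contained in the
larger, and 0 exactly when the sets are disjoint. Unlike the Jaccard index
it is not penalised when the two sets differ greatly in size — the natural
choice when a ~80-gene predicted target set is compared against a ~900-gene
DEG list. We define it with $\min(|A|,|B|)$ uniformly so the equal-size case
is covered, and define one-empty-set comparisons as 0 (two empty sets are an
error). Worked example: sets of sizes 5 and 10 sharing 2 genes give
$2/5 = 0.4$.

## Resampling null and the sign test

An observed focal-regulator ratio is judged against a resampling null: draw
`n_null` (default 1000) transcription factors from the network's regulator
frame, compute each one's shared ratio against the same DEG set, and ask
whether the observed value exceeds the null's median via an exact binomial
sign test — ties with the observed value are discarded and the count of null
samples above it is referred to $\mathrm{Binomial}(n, 1/2)$. The default
alternative is one-sided (`greater`) because the scientific question is
directional; a two-sided option exists. Sampling is without replacement by
default, and the focal regulator is *not* excluded from its own frame
(exclusion is a flag): with 1000 draws from thousands of regulators either
choice moves the null by at most one sample.

Two properties are worth keeping in mind when reading these p-values:

* With a large null sample the sign test is essentially an indicator that
  the observed value exceeds the null median; it answers "is this regulator
  above the typical regulator", not "how far above".
* When the DEG set is obtained by thresholding q-values at $q < 0.05$, every
  gene in the universe enters the set with probability at least 0.05 (the
  uniform background of non-DEGs). A focal regulator with $t$ targets and
  *no* true signal therefore overlaps the thresholded set with a
  $\mathrm{Bin}(t, 0.05)$ leak; with $t = 79$ and a null median near 0.085,
  the chance of spuriously clearing the null median is
  $P(X \ge 7) \approx 0.10$. This is a property of thresholding, not of the
  test; the package's planted-recovery tests separate the two by measuring
  the zero-signal case against exact DEG membership.

## Pairs, families, triads

Pairwise target-set overlap between regulators uses unique *ordered* pairs
of distinct regulators, $N(N-1)$ in total — the only convention consistent
with a 3-member family admitting 6 pairs. Requests beyond the admissible
count are capped (small families yield all their pairs). Since the ratio is
symmetric, ordering affects counts, never values.

For homeolog triads (syntenic 1:1:1 A/B/D copies), the three pairwise
comparisons A-B, A-D, B-D are computed per triad — 708 triads give 2,124
comparisons. Movement categories (Dynamic / Mid 80 / Stable: decreasing
variability of relative homeolog expression across tissues) are consumed as
per-category gene lists; a triad is labelled by any member's list
membership, conflicts are errors, unlisted triads are `Unclassified`
(excluded from category tests, included in the all-homeolog distribution).
Category distributions are compared with two-sided rank-sum tests by
default (the directional question can be asked with a one-sided flag).
No genome-of-origin filter is applied in triad analyses — all three
subgenomes are needed — whereas DEG-facing analyses accept a filter (e.g.
`c("A","B")` when the expression evidence comes from a tetraploid).

Genome-of-origin association asks whether regulators preferentially target
their own subgenome: per regulator, the A/B/D composition of its targets
(unknown-genome targets excluded from the denominator); per target-genome
proportion, two-sample Kolmogorov-Smirnov tests between regulator-genome
groups, Benjamini-Hochberg adjusted across all tests in the invocation
(per-stratum adjustment when movement-stratified). The KS samples are
per-regulator proportions; an alternative construction on per-target
indicator counts would weight large regulons more heavily — we use the
per-regulator reading so every regulator contributes equally.

## Candidate regulators

The candidate scan returns every regulator whose shared ratio with a DEG set
*strictly* exceeds the focal regulator's at one or more timepoints, labelled
by the timepoints at which it exceeds, its shared-target count with the
focal regulator, and (when an expression matrix is supplied) its senescence
fold change. Strict inequalities are used throughout ($q <$ threshold,
ratio $>$ focal), so the focal regulator can never be its own candidate. The
scan annotates rather than tests: no multiple-testing correction is applied.

The fold change is the ratio of group means,
$(\bar{x}_{\mathrm{sen}} + \varepsilon)/(\bar{x}_{\mathrm{non}} +
\varepsilon)$ with pseudocount $\varepsilon = 0.01$ TPM (configurable), with
samples first averaged within (tissue, senescent) groups so unevenly
replicated tissues weigh equally; `upregulated` means fold $> 1$ and
`twofold` means strictly $> 2$.

## Quartile positions in the ranked DEG list

To ask where a gene subset sits within the DEG list, DEGs are ranked by
ascending q (ties broken by gene id for determinism) and split into four
equal-size rank bins, any remainder going to the earlier bins; the subset's
counts per bin are returned. Rank bins, not q-value quantiles, are used:
q-values pile up near zero, so value-based quartiles would collapse.

## The synthetic-data generator

All tests run on generated data with planted, recoverable structure.

* **Background network.** Each of `n_background_tfs` (default 3,000)
  transcription factors draws `targets_per_tf` (default 20–120) targets
  uniformly from an `n_genes` (default 20,000) universe. Two random TFs then
  share targets only by chance, reproducing the empirical behaviour that a
  random TF pair typically shares nothing (the generated all-TF pair
  distribution has median 0 and mean ≈ 0.004).
* **Triads.** Per-category triad counts default to 44/530/52
  (Stable/Mid 80/Dynamic) plus 82 unlabelled — 708 in all, i.e. one third of
  the 132/1,590/156/2,124 pairwise-comparison counts. Planted category means
  default to 0.41/0.39/0.35. Each triad's three members share a core of
  `round(rho * t)` targets and draw the remainder mutually disjoint, so each
  within-triad ratio is exactly `round(rho * t)/t` — exact planting, no
  rejection sampling, at the cost of no within-category spread beyond the
  rounding jitter (real categories are far more dispersed; rank-sum power
  on generated data is therefore optimistic).
* **DEGs.** One designated causal TF receives exactly `focal_targets`
  (default 79) targets; a DEG set of `n_deg` genes contains
  `round(r * 79)` of them (defaults 12/79 at 12 days after anthesis, 4/79
  at 22, with 866 and 130 DEGs — the focal validation geometry). DEG members
  draw q-values from Beta(0.5, 20), everything else from Uniform(0, 1),
  reproducing a density peak near $q = 0$ over a flat background. Under this
  model ~84.5% of DEG q-values fall below 0.05, so thresholded recovery is
  deliberately noisy.
* **Expression.** Log-normal baselines (meanlog = log 10, sdlog = 1),
  a planted fold applied to senescent samples of upregulated genes,
  multiplicative log-normal noise (default sd 0.1 on the log scale).

Identical configuration and seed give byte-identical outputs; every
pipeline stage derives its stream from the single run seed at a fixed
offset. What passing these tests shows is that the statistics recover
structure *of the kind planted*; real networks add correlated regulons,
hub structure, annotation errors and shared-pathway overlap that the
generator deliberately omits.

## Worked run

```{r example, eval = FALSE}
cfg <- simulation_config(n_background_tfs = 300, n_genes = 20000,
                         triad_counts = c(Stable = 10, Mid80 = 25,
                                          Dynamic = 10),
                         triad_overlap = c(Stable = 0.41, Mid80 = 0.39,
                                           Dynamic = 0.35))
bundle <- simulate_bundle(cfg, seed = 1)
suite <- run_full_suite(bundle$network, bundle$annotation,
                        degs = bundle$degs, triads = bundle$triads,
                        expression = bundle$expression,
                        focal_tf = bundle$causal_tf,
                        n_null = 1000, n_pairs = 1000, seed = 1)
suite
write_suite(suite, "results/")
```

## Numerical and design choices

* Quartiles and distribution summaries use linear interpolation between
  order statistics (`quantile` type 7).
* Trimming to the top `n` edges breaks weight ties lexicographically by
  (regulator, target), making the trim deterministic and idempotent;
  regulators trimmed to zero edges leave the sampling frame.
* Gene identifiers are opaque case-sensitive strings; a gene's subgenome
  comes from the annotation table, never parsed out of the identifier.
* Duplicate edges, q-values outside $[0,1]$, genes in two triads or two
  movement lists, and samples without metadata are validation errors, not
  warnings — silent repair of inputs is never attempted.
* Degenerate statistics raise classed errors rather than returning
  misleading values: two empty sets have no shared ratio, and a sign test in
  which every null sample ties the observed value is refused.
* Problem sizes in the test suite are chosen to exercise the study geometry
  (3,000-TF frames, 1000-sample nulls, 708 triads, 100-replicate recovery
  loops) while keeping a full run in a few minutes.

## Limitations

* The shared ratio ignores edge weights beyond the initial top-`n` trim.
* The resampling null conditions on the network as given; it does not model
  uncertainty in network inference itself.
* Candidate regulators are ranked by a single statistic with no FDR control;
  they are hypotheses for follow-up, not discoveries.
* The generator's planted triad overlaps have no biological within-category
  dispersion, and its genome labels are i.i.d.; both are idealisations.
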