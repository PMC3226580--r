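---
title: "Hub pathways and anti-correlated meta-activity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hub pathways and anti-correlated meta-activity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubpath)
```

## The problem

Livers (and other organs) confronted with many distinct chemical insults
do not respond pathway by pathway at random: a small set of molecular
pathways responds to almost everything, and their activities are locked
into a mutually inverted two-group pattern under toxicopathological
conditions. `hubpath` turns the analysis that discovers this structure —
from replicated expression tables to the final anti-correlation table —
into a tested, reusable pipeline with a synthetic ground-truth generator.

## The model, stage by stage

**Gene ranking.** For each condition the treated and control replicates
are compared per gene with a Student (pooled-variance) two-sided t-test —
Welch's form is available via `var_equal = FALSE`, but "Student's t-test"
denotes the pooled form and that is the default. The ranking metric is
`log10(1/P)`, signed by the treated-minus-control mean difference. The
sign convention is a design decision: on log-ratio expression data the
mean difference is the natural effect direction. P-values are floored at
`p_floor = 1e-16` before the logarithm so the metric stays finite; among
floored genes the order falls to the deterministic tie rule (descending
metric, then ascending gene identifier). Two-sided tests are assumed
throughout; a one-sided reading would only rescale the metric
monotonically within each direction.

**Enrichment.** The enrichment score is the signed maximum deviation of
a running sum that increases by `|metric|^weight / Σ_hits |metric|^weight`
at gene-set members and decreases by `1/(N − n_hits)` elsewhere.
`weight = 1` (the weighted statistic) is the default; `weight = 0` gives
the classic equal-increment Kolmogorov–Smirnov form. A tie between the
largest positive and largest negative deviation resolves to the positive
one — rare on continuous metrics, but it must be fixed for determinism.
The null is a *gene-set permutation*: random same-size gene sets drawn
from the ranked list. Preranked enrichment has no phenotype labels to
permute, so phenotype permutation is not meaningful here. The nominal
p-value is the add-one same-signed tail fraction, and
`NES = ES / mean(|null ES| of the same sign)` — the standard
operationalization of "normalized to the size of the set". Sets with
fewer than 10 mapped genes are excluded (`min_size = 10`). Permutation
nulls are cached per distinct mapped set size with substream seeds
derived from the size alone, making results independent of the order of
sets in the GMT file. The per-permutation score is computed from the
hit-position prefix sums in O(set size), which is what lets
~200 sets × 40 conditions × hundreds of permutations run in seconds.

**Responsiveness.** `n_i` counts conditions with nominal p < α
(α = 0.05); missing cells — pathways not testable in a condition — never
count. The Normalized Pathway Coverage, `NPC(θ) = mean_{n_i ≥ θ} n_i/C`,
summarizes how much of the condition panel the surviving pathways cover;
plotted against the percentage of surviving pathways it guides the
HR/MR/LR cutoffs (defaults 10 and 5). An empty survivor set yields a
missing NPC value, not 0 — a zero would fabricate a point on the curve.
Threshold selection itself stays a human decision; the package computes
the curve but fits no elbow.

**Network.** NES values are z-scored per condition (column), using the
sample (n−1) standard deviation, before correlating pathways. Column-wise
scaling makes heterogeneous perturbations comparable; row-wise scaling
would be a no-op for Pearson correlation (which is invariant under
positive affine rescaling of rows — a property the test suite asserts).
Correlations use pairwise-complete conditions with `min_overlap = 10`;
the no-correlation p comes from `t = r·sqrt((n−2)/(1−r²))`. An edge
requires |PCC| strictly above 0.5 *and* p below `p_max`. The default
`p_max = 1e-4` follows the stricter of the two published variants; 1e-3
is exposed as a configuration alternative because both appear in the
source material, and `reproduce_published_network()` reports both.
Degrees are computed over all pathways, not hubs only.

**Hubs and bipartition.** A hub needs `n_i ≥ 10` and degree ≥ 10. The
signed hub subgraph is two-colored by traversal (keep color across
positive edges, flip across negative). If the graph is structurally
balanced the coloring exists and is unique per connected component; the
side containing a configured anchor pathway (else the larger side, ties
to the lexicographically smallest member) is labelled Group A — the A/B
naming is semantic, not structural, so the anchor merely fixes
orientation. If the graph is frustrated, the offending edges are reported
and no labels are assigned; no frustration-minimizing partition is
attempted.

**Anti-correlation scoring.** Seed conditions are those where both hub
groups have a defined consensus (at least `min_hubs = 3` significant hubs;
direction = sign of their mean NES) and the consensuses are opposite.
For each pathway and seed condition with a significant response, the
pathway's NES sign matches exactly one group's consensus; the scoring is
a symmetric transfer: +1 to the matching group's score, −1 to the other.
This reading makes `A_score ≥ +3` equivalent to `B_score ≤ −3` and
guarantees `|A_score| ≤ n`, which the anti-correlation score
`max(A_score, B_score)/n` requires to stay within [−1, 1]. Assignment
needs a group score of ≥ 3 (hence n ≥ 3); the anti-correlation call
additionally needs the score to exceed 0.7 *strictly*. When a group's
significant hubs split in sign, the mean-NES consensus decides — a
declared design choice, since pathological sign splits admit no obvious
rule.

## The synthetic generator

`simulate_meta_activity()` plants the structure the pipeline is supposed
to find. Defaults mirror the scale of the motivating study: 43
conditions (20 toxicopathological, the rest physiological), 189 pathways
with 8 + 8 hubs, and a background fraction of 0.75 so that ~31 non-hub
pathways are weaker group members — about the number of non-hub
anti-correlated pathways the reference analysis reports. Each toxic
condition draws a severity `s(c) ~ Uniform(0.5, 1.5)` (heterogeneous but
consistently signed conditions exercise the correlation, not just the
sign agreement) and follows Scheme B (Group B up, Group A down) with
probability 0.85, Scheme A otherwise, matching the observed predominance
of Scheme B. Hubs carry the full ±s(c); non-hub members respond in only
a Bernoulli(0.35) subset of toxic conditions at 0.8 amplitude, which
keeps their expected responsiveness below the hub threshold while leaving
them enough significant seed responses (n ≥ 3) to be scored. Gene sets
are disjoint by construction, isolating the statistics from gene-sharing
confounds that real pathway collections do have (glycolysis and
gluconeogenesis share enzymes, for example).

`simulate_expression()` realizes the truth at gene level: member genes
of pathway p get treated mean `m(p,c) · effect_size`, control mean 0,
Gaussian noise everywhere. The default `effect_size = 2.8` with
`noise_sd = 1` and 4 replicates per group gives a closed-form per-gene
t-test power of ≈ 0.91 at severity 1 (`gene_level_power(2.8)`);
`effect_for_power()` inverts the closed form when a specific power is
wanted. `simulate_nes_matrix()` bypasses the gene level for fast tests:
NES = planted meta-activity + noise, with significance drawn at
`power_param` for planted cells and `sig_alpha` for null cells.

What the generator does *not* emulate: array-level artifacts (dye bias,
spatial effects), sex and dose covariates, overlapping gene sets, and
correlated noise between pathways sharing regulation. Passing the
recovery tests therefore shows the chain of statistics is implemented
correctly and has the claimed power under clean conditions — not that
real microarray data will be as well behaved.

## Numerical choices and degenerate inputs

* Random streams: every stage derives substream seeds from the root seed
  and stable labels (stage, condition, set size) via a small string hash,
  so reproducibility never depends on execution order.
* A gene set covering the whole ranked list, or mapping to none of it,
  is an error (the running sum is undefined), as are empty gene sets,
  duplicate set names, duplicate genes in an RNK file, and ragged
  matrices. Readers reject rather than repair.
* Both groups constant and equal in a t-test gives p = 1 with a
  degeneracy flag; constant but different gives the floored minimum p.
* An all-zero metric draw in a weighted permutation falls back to equal
  hit weights (the weighted increment is otherwise 0/0).
* Matrix persistence uses 17 significant digits, so write/read is a
  bitwise round trip; missing cells are the literal string `NA` because
  0 is a meaningful NES.
* A zero-variance condition column becomes all-missing with a warning
  rather than dividing by zero.

## Problem sizes used in validation

The test suite validates the enrichment statistic exhaustively on small
lists (all 510 subsets of an 8-gene list against a step-by-step oracle;
all C(4,2) permutations against direct enumeration) and the pipeline
end-to-end on simulated studies of 150 pathways × 40 conditions with
200 permutations across 10 seeds, plus 10 null runs — sizes chosen to
exercise the full analysis at study-like scale while keeping a complete
validation run in minutes on a single core. The published-scale network
statistics (mean degree 7.43, 57 highly connected pathways, 16 hubs)
can be recomputed with `reproduce_published_network()` whenever the
original study's supplementary NES matrices are available on disk; they
are not redistributable with the package.

## Known limitations

* FDR-adjusted enrichment reporting is out of scope; all calls use the
  nominal p, matching the downstream definitions.
* The bipartition reports frustration instead of resolving it; a
  frustration-minimizing cut is a different (NP-hard) problem.
* Probe-to-gene collapsing and homolog mapping are upstream concerns;
  gene identifiers are opaque case-sensitive strings.
* The seed-condition list can be supplied manually (mirroring a curated
  choice) or derived automatically by the opposite-consensus rule; the
  two need not coincide on borderline conditions.
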