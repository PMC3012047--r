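---
title: "Condensing typed molecular networks with differential link scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condensing typed molecular networks with differential link scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcondense)
```

## The model

A typed molecular network consists of nodes (genes/proteins) and edges of
three kinds: undirected physical **interactions**, and directed
**stimulations** and **inhibitions** from a regulator to its target. Given
one measured value per node in each of two conditions E1 and E2 (or replicate
means with variances), every node gets a differential

$$D_A = M_{A,E2} - M_{A,E1},$$

standardized, when replicate variances $\mathrm{Var}_{A,E1},
\mathrm{Var}_{A,E2}$ and counts $n_1, n_2$ exist, by Welch's pooled standard
error:

$$D_A = \frac{M_{A,E2} - M_{A,E1}}
             {\sqrt{\mathrm{Var}_{A,E1}/n_1 + \mathrm{Var}_{A,E2}/n_2}}.$$

This is the Welch two-sample t statistic; it is used as a variance-aware
effect size only. No p-values are attached, because that would require
distributional assumptions the method deliberately avoids, and the scores are
compared with each other rather than against a null.

Each edge receives a signed **link score**: $D_A + D_B$ for interactions and
stimulations, $D_A - D_B$ for an inhibition of $B$ by $A$. Positive scores
mark startups, negative scores shutdowns. Two properties motivate this
choice:

* On log-transformed abundances, the interaction score equals
  $\log\frac{[A]_{E2}[B]_{E2}}{[A]_{E1}[B]_{E1}}$ — the log change of
  mass-action complex activity. (No equilibrium constants or kinetics are
  estimated; only this ratio interpretation is used.)
* Anticorrelated endpoint changes cancel in the sum (and correlated changes
  cancel in the inhibition difference), so links whose endpoints change
  incoherently are automatically driven toward zero and drop out first when
  condensing.

The score is antisymmetric under exchanging the two conditions, and the
interaction score is symmetric in its endpoints, so undirected edges need no
orientation convention for scoring (the package still stores them with
lexicographically ordered endpoints so output files are reproducible).

## Consistency classes

A link's score says *how much* changed; the consistency class says *how
coherently*. With $s, t$ the dead-banded signs of the source and target
differentials (|d| ≤ `epsilon` counts as zero) and "agreement" meaning
$s = t$ for interactions/stimulations and $s = -t$ for inhibitions:

* both nonzero, agreeing → `consistent`;
* both inside the dead-band → `no_change`;
* source nonzero and dominant ($|d_s| > |d_t|$) against a zero or disagreeing
  target → `source_principle`: trusting the network, the regulator's change
  justifies the startup/shutdown call and the target is presumed counteracted
  by effectors outside the network;
* symmetric case → `target_principle`;
* otherwise → `inconsistent`.

The default `epsilon` is 0 (a strict sign test). The dominance cutoff is a
deliberate design choice: descriptions of the two principles require the
"telling" change to exceed the conflicting one, so an exact tie of
disagreeing magnitudes is classified `inconsistent` — neither principle
dominates. All three non-consistent classes are flagged `wavy` in the style
map and drawn dashed.

## Thresholds and the quantile convention

Condensation keeps a link iff its score is ≤ the lower cutoff or ≥ the upper
cutoff (boundaries inclusive), then removes nodes left without any kept link.
Cutoffs come from a `threshold_spec`:

* **absolute** mode passes the cutoffs through unchanged (`lower ≤ 0 ≤
  upper`); `(0, 0)` keeps everything.
* **quantile** mode takes tail masses $q_\text{lo}, q_\text{hi} \in [0,
  0.5)$ of the *signed* score distribution (two independent tails, not
  |score|).

For tail mass $q$ on $n$ scored links, the cutoff is resolved as the
$\lfloor qn \rfloor$-th smallest (respectively largest) score, so exactly
$\lfloor qn \rfloor$ links survive per tail, plus any ties sitting exactly on
a cutoff. We chose this order-statistic convention over interpolating
quantile estimators deliberately: interpolation-based cutoffs keep
$\lfloor (n-1)q \rfloor + 1$ links per tail, which overshoots the nominal
tail mass by up to one link per tail at practically relevant $n$ (e.g. 7
rather than 6 of 206 links at $q = 0.03$), whereas the order-statistic rule
makes the removed fraction $1 - 2q$ (94% at $q = 0.03$) to within one link
at every size. $q = 0$ resolves to $(-\infty, +\infty)$ and keeps nothing.
Unscored links (endpoints without measurements under the `keep_unscored`
policy) are always removed and counted.

Condensation is idempotent at the same resolved absolute cutoffs, and kept
sets are nested as specs tighten, which `condensation_series()` exploits as
the batch analogue of an interactive threshold slider.

## Preprocessing

`preprocess_measurements()` reproduces standard microarray preparation: an
elementwise log transform first (log2 by default in the examples; values must
be positive), then quantile normalization across sample columns — delegated
to `limma::normalizeQuantiles` with tie averaging — then per-condition means
and, with ≥ 2 replicates per condition, variances. Nothing is transformed
implicitly elsewhere: scoring consumes the measurement table as given, so the
mass-action reading of interaction scores holds exactly when the user
supplies log-scale values.

Mixed variance coverage (variances for some nodes only) is rejected: Welch
and raw differentials live on incomparable scales, and quantile thresholds
across a mixture would be meaningless. A zero pooled variance is a hard
error by default; `var_floor` (e.g. `1e-12`) substitutes a floor with a
warning, because silently dividing by zero would fabricate infinite scores.

## Visual encoding

Node colors use a green–white–red scale anchored at the 10%, 50% and 90%
quantiles (interpolating type-7 quantiles; the exact estimator is immaterial
here since the anchors only steer a color ramp) of the pooled measurement
values from both conditions; values outside the outer anchors clamp to full
green/red. Each node is drawn as two half-circles: E1 left, E2 right. Edge
color is red for startups and green for shutdowns, with saturation and line
width growing linearly in |score| up to the largest kept |score| (a
degenerate single-score network maps to full width). The default palette is
green (0, 200, 0) / white / red (220, 0, 0) and is configurable; note that
monotonicity of individual RGB channels along the ramp holds for fully
saturated palettes, while the default's slightly muted endpoints trade that
for less glaring colors. `style_network()` exposes all of this as plain data
frames, `write_style()` writes byte-stable TSVs, and `render_figure()` /
`plot()` produce a deterministic static figure for a fixed layout seed.

## The synthetic fixture generator

`generate_fixture()` emulates the structure of a curated network overlaid
with two-condition log-scale microarray data: node baselines drawn
$N(7, 1.5^2)$ on the log2 scale, a uniform random network over distinct node
pairs, and a planted set of differential links. Defaults mirror a
medium-sized curated network of 124 nodes and 206 edges with 3 startups and 3
shutdowns of effect size 2 log2 units per endpoint and condition noise 0.2 —
sizes at which the quantile arithmetic and recovery behavior of the method
are representative. Planted startups shift both endpoints up for
interactions/stimulations and shift inhibitor up / target down for
inhibitions (shutdowns mirrored), so each planted link scores about twice the
effect size with the sign of its label.

Planted edges are chosen with pairwise-disjoint endpoints and no bystander
edge connecting two planted nodes; self-loops are not generated (an
inhibition self-loop scores identically zero, which would create score ties).
With zero noise this construction makes the planted links exactly the
top-|score| set, which the recovery tests exploit. What the generator does
*not* emulate: realistic scale-free topology, correlated noise between
replicates, probe-level effects, or missing measurements — so passing
recovery tests demonstrate the pipeline's arithmetic and ranking behavior,
not performance on real arrays. The package itself accepts self-loops,
duplicate edges and partial measurement coverage from real inputs.

## Problem sizes in the test suite

The suite verifies the scoring path against an independent edge-by-edge
reference on 1,000 random networks of up to 50 nodes, runs round-trip and
property checks on dozens of generated fixtures, and exercises condensation
at sizes 100–400; the full suite completes in well under a minute, which we
consider the right budget for a routine check of a package whose individual
operations are all sub-second.

## Known limitations

* Scores of edges sharing a node are dependent; the method ranks links and
  does not claim significance. Replicate variances sharpen comparability but
  the score remains descriptive.
* The five consistency classes operationalize qualitative reasoning; the
  dead-band `epsilon` is 0 by default and any nonzero choice is the user's.
* GPML input is not supported (SIF/GraphML/XGMML cover the interchange
  needs); session archives are read at the zip/XGMML level only.
* Network content is taken as given — no construction from interaction
  databases, no active-subnetwork search.
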