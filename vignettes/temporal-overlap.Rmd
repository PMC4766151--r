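---
title: "Measuring edge persistence in temporal contact networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring edge persistence in temporal contact networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temponet)
library(dplyr)
```

## The model

A temporal contact network is observed as a set of time-stamped events:
on day *d*, node *u* contacted node *v*. Livestock movement registries
are the motivating case — holdings as nodes, animal shipments as events —
but nothing in the package is specific to them. Cutting the observation
period into consecutive, non-overlapping windows of *w* days and placing
an unweighted edge between two nodes whenever at least one event links
them inside a window yields an ordered sequence of `M = floor(T / w)`
simple graphs over one fixed node universe of size N. A trailing window
shorter than *w* is discarded rather than aggregated, so every snapshot
summarises the same amount of time.

For a node *i* and a consecutive snapshot pair, the topological overlap
`C_i` is the size of the intersection of its two neighbour sets divided
by the geometric mean of its two degrees — a cosine similarity of 0/1
adjacency rows, so `0 <= C_i <= 1` by Cauchy–Schwarz, with 1 exactly for
identical nonempty neighbourhoods. A node without edges in either
snapshot has an undefined (0/0) similarity; the package defines it as 0.
This convention is what makes "the two snapshots share no edges" and
"summed overlap is zero" coincide, and it is applied uniformly at the
node level.

The per-pair average overlap divides the summed node overlaps by a
normaliser, and the temporal correlation coefficient is the mean of the
per-pair values over the `M - 1` pairs. The three normalisers are the
point of the package:

* **all nodes** (`method1`): divide by N. Simple, but two identical
  snapshots score `A / N < 1` when only A of the N nodes are active, so
  persistence is systematically understated on sparse networks.
* **largest component** (`method2`): divide by the larger of the two
  snapshots' largest-connected-component sizes. Repairs the isolated-node
  problem but overshoots: when active nodes are spread over several
  components, the normaliser can be smaller than the number of active
  nodes and the "overlap" exceeds 1, which has no probabilistic reading.
* **active nodes** (`method3`): divide by the larger of the two
  snapshots' active-node counts. Always in `[0, 1]`, and 1 exactly for
  identical edge-bearing snapshots.

The per-pair ordering `method1 <= method3 <= method2` is structural: the
three normalisers satisfy max-largest-component <= max-active <= N
whenever the values are defined.

## Degenerate inputs and numerical conventions

* `method3` on a pair of edgeless snapshots is 0/0 and is reported as
  `NA`. `temporal_correlation()` takes an `undefined` policy: `"skip"`
  (default; the pair leaves both numerator and denominator, with the
  skipped count messaged), `"zero"`, or `"error"`. The default is
  `"skip"` because a 0/0 pair carries no information about persistence,
  but both readings are defensible, so all three are provided.
* An edgeless snapshot on a nonempty universe has largest-component size
  1 (an isolated node is a component of size 1), so `method2` on an
  edgeless pair is 0/1 = 0. This case sits outside the worked examples
  and is fixed here by convention so that sweeps never fail.
* All values are carried at full double precision; rounding to the
  2 decimals used in display happens only in the command-line front end
  and in printed summaries.
* Movement records are directed (supplier to purchaser), but the overlap
  formula uses a symmetric adjacency; `aggregate_windows()` therefore
  symmetrises by default, with `directed = TRUE` available, in which case
  overlap compares out-neighbour sets while "active" and component sizes
  keep their undirected meaning. Self-contacts are dropped with a
  warning; repeated contacts within one window collapse to one edge.

## Distortion ratios and bounds

On every defined pair, the quotient of the all-nodes overlap by the
component-normalised one equals `max[N(t_m), N(t_m+1)] / N` exactly, and
by the active-node one `max[A(t_m), A(t_m+1)] / N` — not approximately:
numerator and denominator share the summed node overlaps, so the values
cancel. `pairwise_ratios()` returns both the value quotient and the
closed form, and their exact agreement is enforced as a property test.
Averaging the closed form over pairs (`averaged_underestimation()`) gives
the mean factor by which the all-nodes normalisation understates
persistence.

For the summary coefficients, only bounds are available.
`correlation_bounds()` computes them from extreme component sizes and
active-node counts over time together with `minC`, the global minimum of
node overlaps over all nodes and pairs. Taken literally, the index set of
`minC` includes inactive nodes, so `minC` is 0 on any realistic sparse
network, the upper bounds degenerate to infinity and the lower bounds to
0 — correct, but vacuous. The default follows the literal definition;
`min_over = "active"` restricts the minimum to nodes active in both
snapshots of each pair, which is the variant that can produce informative
intervals. The bound inequalities are verified on randomly generated
dense networks with strictly positive `minC` (200 instances per test
run).

## The example networks

Three built-in three-snapshot networks (`build_fixture()`) isolate the
failure modes: a 4-node star splitting into two pairs (no isolated
nodes); the same with a fifth, permanently isolated node; and a 7-node
variant whose second snapshot has components of different sizes (2 and 3)
plus two isolated nodes. In all three, snapshots 2 and 3 are identical,
so the final pair probes how each normalisation scores perfect
persistence. The 7-node example is reconstructed from its published
per-node overlap values rather than from its drawing: the printed
normalisers force three isolated nodes in the first snapshot and a 2+3
component split with two isolated nodes afterwards, and the package
follows the numbers. The internal wiring of the 3-node component (a star
at node 5) is one of several wirings consistent with those values; the
choice is arbitrary but fixed, and every published per-node, per-pair and
summary value is asserted exactly in the test suite.

The convergence experiment (`extend_with_last()`, `convergence_curve()`)
appends copies of the final snapshot until the series has 100 members.
Appended pairs are identical graphs, so the active-node curve rises to 1
(closed form: `(sum of original overlaps + tail length) / (length - 1)`),
the all-nodes curve converges to the active fraction of the final
snapshot (0.8 and 5/7 for the two examples with isolated nodes), and the
component-normalised curve exceeds 1.

## The synthetic event generator

`generate_events()` emulates a regional trade registry for tests and
demonstrations: Poisson daily event counts and endpoint draws weighted by
a power-law holding activity (`rank^-skew`), giving a few hub holdings
and many rarely-trading ones. The defaults — 483 holdings, a 1096-day
period, 4.23 events per day, skew 1 — mirror the scale of a three-year
registry of 4635 movements between 483 holdings, the regime the methods
were designed for. A single seeded stream drives the whole record, so a
seed fixes every event. What the generator reproduces is the structural
regime that matters for the overlap methods: sparse daily snapshots whose
aggregation at longer windows forms ever larger components absorbing most
nodes (asserted as a rank-correlation trend test). What it does not
emulate: batch sizes, age groups, seasonality or the ~180-day production
periodicity of real pig-trade data, and any calendar structure (weekends,
holidays). Passing tests therefore certify the arithmetic and the
qualitative regime, not distributional fidelity to any specific registry.

## Problem sizes in the test suite

The suite keeps instances small and numerous: random snapshot universes
of 7–12 nodes, 200 randomised instances per property (ratio identity to
1e-12, normaliser ordering, bound violations, neighbour-set oracle),
sweeps over 30–60-day synthetic records, and the full 100-length
convergence curves for all three examples. Component metrics are checked
against a hand-written flood-fill oracle and the moment conventions
(population moments, non-excess kurtosis) against an independent
implementation. These sizes were chosen to exercise every code path many
times while keeping a full run around a minute.

## Limitations

* Overlap is defined between adjacent snapshots only; no lagged overlap.
* Snapshots are unweighted and single-layer; batch sizes are ignored.
* Windows are consecutive and non-overlapping, anchored at day 1; no
  sliding windows.
* The distortion bounds are the published ones; no attempt is made to
  tighten them, and under the literal `minC` definition they are usually
  vacuous.
* No inferential statistics are fitted to the covariates; the grouping
  utility only prepares the categorical variables.
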