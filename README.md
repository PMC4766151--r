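# temponet

Quantifying edge persistence in temporal networks: the topological overlap
of consecutive snapshots and the temporal correlation coefficient, under
three normalisations.

## The problem

Contact systems such as livestock trade networks are inherently temporal:
holdings (farms) are nodes, and a movement of animals between two holdings
on a given day is a time-stamped edge. Aggregating the contacts of each
time window into a static snapshot yields an ordered sequence of graphs,
and a natural question is how stable the edge configuration is from one
snapshot to the next — the average probability for an edge to persist
across consecutive time steps. That stability is measured by the
**temporal correlation coefficient**, and how you normalise it matters as
soon as the network has isolated nodes or several components.

For node *i* and consecutive snapshots *t<sub>m</sub>*, *t<sub>m+1</sub>*
with unweighted adjacency *a<sub>ij</sub>*, the node-level **topological
overlap** is the cosine-type similarity

```
C_i(t_m, t_m+1) = Σ_j a_ij(t_m) a_ij(t_m+1) / sqrt( Σ_j a_ij(t_m) · Σ_j a_ij(t_m+1) )
```

The per-step average overlap C<sub>m</sub> divides Σ<sub>i</sub> C<sub>i</sub> by a
normaliser, and the temporal correlation coefficient C is the mean of
C<sub>m</sub> over the M−1 consecutive pairs. The three normalisations
implemented here are:

| method | normaliser | behaviour |
|---|---|---|
| `method1` | N, all nodes | < 1 on identical snapshots if isolated nodes exist |
| `method2` | max largest-component size of the pair | can exceed 1 with multiple components |
| `method3` | max active-node count of the pair | stays in [0, 1]; 1 iff identical (nonempty) snapshots |

`method3` — normalising by the maximal number of nodes that actually carry
an edge — is the only one of the three that both respects the [0, 1] range
and scores identical consecutive snapshots as 1. The package also provides
the exact per-pair distortion ratios between the methods (the value
quotient C¹<sub>m</sub>/C²<sub>m</sub> equals max[N(t<sub>m</sub>), N(t<sub>m+1</sub>)]/N
identically), analytic lower/upper bounds on the quotients of the summary
coefficients, window-length aggregation and sweeps, per-pair structural
covariates, descriptive moment summaries, a convergence experiment, and a
seeded synthetic trade-event generator.

## Worked example

The 5-node example network (a star that splits into two pairs, with one
permanently isolated node) separates all three methods:

```r
library(temponet)
net <- build_fixture("example2")
tidy(net)
#> # A tibble: 3 × 4
#>       t n_edges n_active largest_component
#>   <int>   <int>    <int>             <int>
#> 1     1       3        4                 4
#> 2     2       2        4                 2
#> 3     3       2        4                 2

dplyr::select(overlap_series(net), m, method1, method2, method3)
#> # A tibble: 2 × 4
#>       m method1 method2 method3
#>   <int>   <dbl>   <dbl>   <dbl>
#> 1     1   0.315   0.394   0.394
#> 2     2   0.8     2       1

for (m in overlap_methods())
  cat(sprintf("C (%s) = %.2f\n", m, temporal_correlation(net, m)))
#> C (method1) = 0.56
#> C (method2) = 1.20
#> C (method3) = 0.70
```

Snapshots 2 and 3 are identical, yet `method1` scores the pair 0.80 (the
isolated node caps it at the active fraction 4/5) and `method2` scores it
2 (two components of size 2, normaliser 2 < 4 active nodes). Only
`method3` returns 1. Appending copies of the last snapshot shows the same
story in the limit:

```r
curve <- convergence_curve(net, target_length = 100)
dplyr::filter(curve, length == 100)
#> # A tibble: 3 × 4
#>   length method      C appended_overlap
#>    <int> <chr>   <dbl>            <dbl>
#> 1    100 method1 0.795              0.8
#> 2    100 method2 1.98               2
#> 3    100 method3 0.994              1
```

`autoplot()` renders the curve, an overlap series or a window-length
sweep; `correlation_bounds()` returns the analytic distortion report with
`tidy()`/`glance()` methods.

Movement records are read from CSV (`date,source,target,...`) with
`read_events()`, aggregated with `aggregate_windows()`, and swept over
window lengths with `sweep_window_lengths()`. A thin command-line front
end with the same operations ships at `inst/cli/temponet`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","temponet",package="temponet"))')" \
  overlap --fixture example1 --method all
```

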