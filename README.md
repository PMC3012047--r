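# netcondense

Condensation of typed molecular networks by differential link scoring.

Molecular interaction networks — protein–protein interactions, transcriptional
stimulations and inhibitions — describe what *can* happen in a cell, not what
*changes* between two conditions. `netcondense` overlays a typed network with
per-node expression measurements from two experimental conditions (E1 and E2)
and asks, for every link, whether the relationship it encodes is **starting
up** or **shutting down**. Links with little evidence of change are removed,
leaving a small condensed network in which the most strongly altered
interactions stand out. Typical users are systems biologists comparing, e.g.,
*in vivo* versus cultured cells, treated versus untreated stem cells, or young
versus old tissue, with a curated or database-derived network in hand.

## The method

For each node *A*, the differential between the conditions is

```
D_A = M_A,E2 − M_A,E1
```

or, when replicate means and variances are available, the Welch-standardized
version (the Welch t statistic, used as a variance-aware effect size — no
p-values are computed):

```
D_A = (M_A,E2 − M_A,E1) / sqrt(Var_A,E1/n1 + Var_A,E2/n2)
```

Each edge then receives a signed **link score** according to its type:

| edge type                 | link score    | rationale                                   |
|---------------------------|---------------|---------------------------------------------|
| interaction, stimulation  | `D_A + D_B`   | on log scale: mass-action log activity ratio of the complex |
| inhibition (A ⊣ B)        | `D_A − D_B`   | inhibitor and target are expected to anticorrelate |

Positive scores are startups, negative scores shutdowns. Condensation removes
every link whose score fails a two-sided threshold (absolute cutoffs, or
quantile tails of the signed score distribution) and prunes nodes left without
links. Each surviving link also gets a consistency class: `consistent` when
both endpoints change in the pattern the edge type predicts, the
`source_principle` / `target_principle` classes when one dominant endpoint
alone carries the call, and `inconsistent` otherwise; non-consistent links are
rendered with dashed ("wavy") lines. Node colors encode both condition values
in one two-half circle on a green–white–red scale anchored at the 10/50/90%
quantiles of all measurements.

## Worked example

```r
library(netcondense)

fx  <- generate_fixture(seed = 2026)        # 124 nodes, 206 typed edges,
                                            # 3 planted startups + 3 shutdowns
fit <- linkscore(fx$network, fx$measurements)
fit
#> Link scores (single basis): 206 edges, 124 nodes
#>   score range [-4.59, 4.815]; 125 startup, 81 shutdown, 0 neutral

res <- condense(fit, threshold_spec("quantile", 0.03))
res
#> Condensation (quantile 0.03/0.03): kept 12 of 206 links (removed 94%), 18 nodes
#>   resolved cutoffs: [-2.118, 2.737]

summary(res)
#> Condensed network: 12 links, 18 nodes (removed 194 links, 0.94)
#> Strongest links:
#>  source interaction_type target     score direction consistency_class
#>    N006      interaction   N034  4.815431   startup        consistent
#>    N050      interaction   N087  4.743080   startup        consistent
#>    N011      interaction   N029 -4.590406  shutdown        consistent
#>    ...
```

Keeping the 3% tails on both sides removes 94% of the 206 edges; the twelve
surviving links include all six planted ones (scores near ±4, i.e. twice the
planted per-node effect of 2 log2 units), and the resolved cutoffs show the
absolute score a link needed to survive. From here,
`write_network(res, "condensed.graphml", include_attributes = TRUE)` exports
the condensed network with scores and measurements, `style_network(res)`
computes the color/width attributes, and `plot(res)` renders a figure.

Real data enter through `read_network()` (SIF / GraphML / XGMML, edge types
as literal names or SBO terms), `read_measurements()` (TSV; one value per
condition, or mean + variance with replicate counts), and
`preprocess_measurements()` (log transform + quantile normalization of a raw
sample matrix). `run_condense()` and the `inst/cli/netcondense.R` script wire
the whole workflow together from a YAML config or command-line flags.

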