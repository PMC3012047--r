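Package: netcondense
Title: Condensation of Typed Molecular Networks by Differential Link Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores every link of a typed molecular network (interaction,
    stimulation or inhibition edges) for startup or shutdown between two
    experimental conditions, using per-node expression differentials that are
    optionally standardized by Welch's formula when replicate variances are
    available. Links whose signed score survives an absolute or quantile
    two-sided threshold are kept, orphaned nodes are pruned, and the condensed
    network is exported with Cytoscape-compatible style attributes (two-half
    node colors on a 10/50/90 percent quantile scale, edge color and width
    driven by the link score). Includes readers and writers for SIF, GraphML
    and XGMML, a synthetic fixture generator with planted startups and
    shutdowns, and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    igraph,
    jsonlite,
    limma,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
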