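Package: oceanexposure
Title: Exposure of Marine Biodiversity to Extreme Rates of Ocean Warming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the exposure of marine biodiversity to extreme
    centennial rates of sea-surface warming by comparing the deglacial past
    with 21st-century scenario projections. Detects extreme 100-year warming
    windows against a control-run percentile threshold, computes per-cell
    pattern-scaled signal-to-noise ratios of SST trends, compares past and
    future exposure distributions within biogeographic realms
    (Kolmogorov-Smirnov tests with Benjamini-Yekutieli correction and kernel
    density overlap), delineates species-richness hotspots and their
    exceedance of realm-level thresholds, and finds nearest future thermal
    analogues by sea-only shortest-path distance. Ships a synthetic world
    generator with ground truth for end-to-end testing, and a minimal
    NetCDF-3 reader/writer for gridded inputs and outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
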