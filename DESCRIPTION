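Package: channelfe
Title: Seasonally Forced Channel Model of Eddy Iron Supply and Southern
    Ocean Productivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A latitude-depth (y-z) tracer-transport and biogeochemistry
    model of an iron-limited, seasonally forced Southern Ocean channel,
    together with the eddy parametrizations used in coarse-resolution
    ocean models: a Visbeck-scaled Gent-McWilliams (GM) eddy-induced
    streamfunction with boundary-layer tapering, Redi isopycnal tracer
    diffusion, a mixed-layer-instability (MLI) restratification
    streamfunction, and KPP-like seasonal boundary-layer mixing.  A
    reduced iron-phytoplankton-zooplankton-detritus ecosystem with
    multiplicative light and iron limitation is coupled to the transport
    operators, and a per-process flux ledger supports closed iron
    budgets.  Diagnostics include mixing-layer depth, vertically
    integrated biomass, bloom onset and apex phenology, limitation-factor
    medians, cross-mixing-layer-base vertical iron fluxes, and a
    snapshot-anomaly eddy-flux operator, allowing sensitivity experiments
    on how isopycnal eddy stirring controls the iron supply that sustains
    primary production.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
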