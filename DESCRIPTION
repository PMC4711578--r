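Package: plumetime
Title: Temporal Structure of Turbulent Odor Plumes and Burst-Neuron
    Encoding of Time for Olfactory Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools to study how the timing between odor encounters in a
    turbulent plume carries navigational information, and how a population
    of rhythmically bursting olfactory receptor neurons (bORNs) can encode
    and decode it.  Provides a parametric statistical model of plume
    intermittency (exponential whiff inter-arrival times, Gamma-distributed
    instantaneous concentration), delay embedding and recurrence-time
    statistics of the first and second type for concentration time series,
    a renewal-process model of heterogeneous bORN populations with
    maximum-likelihood decoding of time since the last odor encounter, and
    an agent-based bilateral-sensor search simulator comparing timing-based
    and concentration-based chemotactic strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
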