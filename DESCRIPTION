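Package: snnweaver
Title: Data-Driven Construction of Spiking Neural Network Models and
    NEST Simulation Scripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A file-based workflow for turning anatomical and physiological
    data into runnable spiking neural network simulations.  Models are
    described as JSON documents holding neural populations, projections,
    simulator model templates and simulation settings, where every attribute
    may carry multiple flagged contributions that are resolved into a single
    collective value at build time.  Transfer functions convert biological
    quantities (post-synaptic potential amplitudes, dendritic geometry,
    bouton counts, projection percentages, redundancy) into leaky
    integrate-and-fire synaptic weights and indegree/outdegree connection
    rules, and a deterministic code generator emits a resolved model
    description together with a PyNEST script for NEST 3.  Includes
    importers for connectome node/edge files and simulator model templates,
    a grid-search calibration utility over firing-rate target intervals,
    and programmatic builders for a balanced cortical network and a
    striatal microcircuit example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
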