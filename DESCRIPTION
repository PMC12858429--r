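Package: spinalcpg
Title: Spiking Network Model of the Flexor-Extensor Spinal Locomotor CPG
    in Health and ALS-Like Degeneration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the flexor-extensor central pattern generator (CPG) of
    one side of the lumbar spinal cord as a network of adaptive exponential
    integrate-and-fire neurons coupled by peak-normalized beta-function
    conductance synapses. Provides a declarative scenario engine that
    transforms the healthy network into staged ALS-like degeneration
    (progressive V1 interneuron dysregulation, late motoneuron and V2a loss,
    cholinergic V0c compensation) and intervention conditions (V1 synaptic
    stabilization, cell sparing and rescue, slowed synaptic dynamics), plus
    burst, frequency, firing-rate and phase metrics for the motoneuron
    output, seed batteries with outlier exclusion, and the nonparametric
    statistics (Wilcoxon signed-rank, Kruskal-Wallis with Dunn's post hoc)
    used to compare conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
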