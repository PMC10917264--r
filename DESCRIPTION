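Package: enercode
Title: Metabolically Efficient Information Transmission in Recurrent Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and information-theoretic analysis of a recurrent
    network of leaky integrate-and-fire neurons receiving shared external
    input. Provides a conductance-based network simulator with
    Ornstein-Uhlenbeck background input, spike-count response statistics
    (noise correlations, single-neuron and population Fano factors,
    interpolated input-output curves and discretized Gaussian channels), an
    ATP-based metabolic cost model of spiking and excitatory synaptic
    currents, cost-constrained channel capacity via the Blahut-Arimoto
    algorithm, information-metabolic efficiency via a Jimbo-Kunisawa style
    ratio maximizer, Fisher-information low-noise approximations of the
    optimal input distribution, and population decoding through PCA-reduced
    multivariate Fisher information with Cramer-Rao channels and quadratic
    sampling-bias extrapolation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
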