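Package: thalamostim
Title: Thalamocortical Neural Mass Modelling of Centromedian Nucleus Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the frequency-dependent neocortical response to electrical
    stimulation of the centromedian nucleus of the thalamus with a two-compartment
    neural mass model. The thalamic compartment couples a thalamocortical relay
    population to fast- and slow-kinetics reticular inhibitory populations and
    implements Tsodyks-Markram short-term plasticity, extrasynaptic GABA
    accumulation with tonic inhibition, and a presynaptic GABA-B self-inhibition
    gate engaged at high stimulation frequency. The layered neocortical
    compartment (two pyramidal masses, PV, SST, VIP and neurogliaform
    interneurons) produces a simulated SEEG field potential exhibiting 3-4 Hz
    interictal spike-wave discharges. Includes a fixed-step stochastic
    integrator (compiled core), biphasic RC-distorted stimulation waveforms,
    interictal spike detection and suppression-window quantification, dynamic
    time warping similarity, mechanism-ablation experiments, and codimension-one
    bifurcation analysis (equilibria continuation, Hopf and saddle-node
    detection, periodic orbit characterisation) of the neocortical subsystem.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    signal,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
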