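Package: memlif
Title: Memristive Leaky Integrate-and-Fire Neuron Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time simulation of leaky integrate-and-fire (LIF) and
    memristive LIF (MLIF) spiking neurons. Provides piecewise charge- and
    flux-controlled memristor device models with pinched-hysteresis sweeps, a
    library of stimulus generators (pulse trains, steps, ramps, seeded noise,
    biphasic trains), spike detection and burst/adaptation analysis, a
    memristive compartmental cable neuron (passive attenuation and active
    propagation with synapse, dendrite and soma devices, including an STDP
    synapse curve), and a Morse-code application that encodes text as timed
    current pulses, reads the evoked spike groups (two spikes per dot, four
    per dash) and decodes them back to text. All results are returned as
    tibbles with tidy()/glance()/autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
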