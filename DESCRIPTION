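Package: cotransport
Title: Stoichiometry Analysis of Electrogenic Cotransporters from Voltage-Clamp and Radiotracer Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to infer the ion-coupling stoichiometry of electrogenic
    plasma-membrane cotransporters (SLC6-type Na+/Cl-/substrate symporters)
    from two-electrode voltage-clamp and radiotracer uptake experiments.
    Implements the thermodynamic reversal-potential model of coupled
    transport, slope-per-decade stoichiometry inference, charge-to-flux
    ratio estimation from integrated currents and tracer counts, I/V curve
    analysis (evoked-current subtraction, normalization, reversal-potential
    interpolation, rectification degree), Hill and Michaelis-Menten fitting
    of uptake kinetics with mock-cell background subtraction, and a seeded
    synthetic-experiment generator so the full analysis chain is testable
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
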