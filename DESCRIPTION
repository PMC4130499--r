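Package: protomotive
Title: Bioenergetics of Protocells in Natural Proton Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulator of ion electrodiffusion and chemiosmotic
    free energy for a protocell straddling the interface between an acidic and
    an alkaline fluid, as at an alkaline hydrothermal vent. Passive fluxes of
    H+, OH-, Na+, K+ and Cl- follow the Goldman-Hodgkin-Katz flux equation,
    the membrane potential follows the Goldman-Hodgkin-Katz voltage equation,
    and mechanistic flux operators model the ATP synthase, the
    energy-converting hydrogenase (Ech), an electroneutral 1:1 sodium-proton
    antiporter, and a generic H2-dependent ion pump, all restricted to the
    acid-facing hemisphere. The simulator time-steps the proton balance with
    water self-ionization re-equilibrated at every step and reports the
    electrochemical free energy (-deltaG), membrane potential and internal pH
    over time and at steady state. Named scenario presets and sweep drivers
    cover membrane permeability, pH-gradient, protein surface-fraction and
    external-pH-fluctuation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
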