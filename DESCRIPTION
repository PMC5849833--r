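Package: neutronvault
Title: Neutron Shielding Assessment for Single-Room Proton Therapy Vaults
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing secondary-neutron shielding of compact
    (in-room cyclotron) passive-scattering proton therapy vaults. Implements
    spherical angular/energy fluence scoring with fluence-to-ambient-dose
    conversion, a three-source (cyclotron target, treatment nozzle, water
    phantom) adaptation of the Moyer point-loss barrier model with
    angle-dependent source terms and attenuation lengths, worst-case
    gantry-angle search with NCRP design-goal compliance reporting, an
    in-room neutron ambient dose equivalent per therapeutic dose (H*/D)
    predictor, and seeded generators for synthetic Monte-Carlo-like
    particle crossings and vault geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
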