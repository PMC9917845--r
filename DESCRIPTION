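Package: srbcolumn
Title: Geochemical Modelling of Sulfate-Reducing Bioreactor Columns Treating Acid Mine Drainage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-dimensional advective reactive-transport model of an
    ethanol-supplemented sulfate-reducing bacteria (SRB) column treating
    neutralized acid mine drainage. Couples microbial kinetic rate laws for
    aerobic and sulfidogenic ethanol/acetate oxidation and sulfate reduction
    with a Newton-based aqueous equilibrium speciation solver (Davies activity
    model, embedded thermodynamic table) and equilibrium precipitation of metal
    sulfide and carbonate phases, via operator splitting at unit Courant
    number. Includes weighted least-squares calibration of the kinetic
    constants to depth profiles, linear combination fitting (LCF) of XANES
    spectra against reference libraries with R-factor reporting, and seeded
    synthetic-data generators for column observations and reference spectra.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
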