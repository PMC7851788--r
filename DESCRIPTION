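Package: ctlensdose
Title: Occupational Eye-Lens Dosimetry for CT-Assisting Staff
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for occupational eye-lens dose monitoring of
    medical staff who assist patients inside the CT room. Converts
    radio-photoluminescent dosimeter air-kerma readings to the personal dose
    equivalent Hp(3) via the beam effective energy (semi-empirical tungsten
    anode spectrum, aluminium half-value layer and its monoenergetic
    inversion, bundled photon interaction and Hp(3)/air-kerma conversion
    tables), aggregates multi-dosimeter readings per procedure, estimates
    dose-reduction efficiencies of protective glasses, bag-valve-mask
    extension tubes and protective curtains, combines measures
    multiplicatively, projects annual dose-limit compliance, and compares
    facility dose indices with diagnostic reference levels. Includes
    tie-corrected Kruskal-Wallis and Dunn-Bonferroni tests implemented from
    their rank formulas and a seedable synthetic cohort generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
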