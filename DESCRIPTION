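Package: prmQuant
Title: Targeted PRM Quantitation of Intact-Protein Survival Across Digestion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a parallel-reaction-monitoring (PRM) quantitation
    workflow for measuring how much of an orally fed protein survives intact
    across gastrointestinal digestion. Provides monoisotopic mass and m/z
    arithmetic for tryptic peptides (including stable-isotope-labeled
    internal standards) and polyethylene-glycol oligomer ladders, in-silico
    tryptic digestion with uniqueness checking and surrogate-peptide
    ranking, transition-list construction, extracted-ion-chromatogram peak
    integration, linear and logarithmic calibration with LOD/LOQ, and the
    two-stage normalization (stable-isotope-labeled peptide correction,
    then dilution-factor correction from a co-fed non-digestible marker)
    that yields percent survival per digestive compartment. A synthetic
    chromatogram generator with known ground truth supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
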