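Package: dsfshift
Title: Thermal-Shift (DSF) Ligand-Binding Analysis for Receptor
    Ligand-Binding Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for differential scanning fluorimetry (DSF)
    ligand screens against a heterodimeric receptor ligand-binding domain.
    Calls apparent melting temperatures (Tm) from plate melt curves by the
    derivative-maximum definition, including the right-side-peak rule for
    biphasic profiles; infers apparent dissociation constants from thermal
    shifts with the Schellman two-state model, both by nonlinear
    least-squares dose-series fitting and by single-point inversion with
    validity windows; estimates EC50 from single-concentration receptor
    responses under a fixed-maximum Hill relation; and relates binding to
    receptor response via correlation and classical QSAR regression on
    amino-acid side-chain descriptors. A seeded synthetic-data generator
    produces melt curves, plates, dose series and response panels with
    known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
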