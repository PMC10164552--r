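Package: nmrcsp
Title: Chemical Shift Perturbation Analysis for NMR Titration Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of protein-observed NMR titration experiments in the
    fast-exchange regime. Reads per-point 2D (1H-15N HSQC) peak lists, tracks
    residue peaks across titration points, computes weighted chemical shift
    perturbations, classifies significantly perturbed residues with a
    trimmed mean-plus-k-SD threshold, fits per-residue single-site binding
    isotherms that account for ligand depletion, aggregates dissociation
    constants over significant residues with upper-limit reporting, and
    compares conditions (mutant fold-change, ternary enhancement). Includes
    a seeded two-state fast-exchange titration simulator that provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
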