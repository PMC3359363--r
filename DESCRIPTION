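Package: inteinsite
Title: Prediction of Intein Insertion Sites in Host Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for nominating intein insertion sites in host proteins.
    Enumerates candidate Cys/Ser/Thr (+1) sites in an extein sequence and
    scores each with four features of native insertion sites: positional
    sequence conservation from a PSI-BLAST position-specific scoring matrix
    (entropy rank among C/S/T sites), a class-weighted linear support vector
    machine over one-hot encoded seven-residue insertion-site cassettes,
    proximity of the site's C-alpha atom to annotated active-site or
    dimer-interface residues, and distance to the nearest secondary
    structure/loop junction.  Includes ROC analysis with Youden-point cutoff
    selection, a leave-one-extein-out ranking protocol for the cassette SVM,
    C-beta contact-density burial, Kabsch superposition and per-residue
    snapshot flexibility, a synthetic-data generator for end-to-end testing,
    and the bundled 20-site XynB xylanase case study.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    e1071,
    seqinr,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
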