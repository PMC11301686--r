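Package: venompep
Title: Viper Venom Peptidomics, Intact-Mass Proteoform Inference and
    Snake Venomics Quantification
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact monoisotopic and average mass arithmetic for
    pyroglutamate-initiated venom peptides, their multimer ions and b/y
    fragment ladders; a modular consensus grammar for
    bradykinin-potentiating peptides (BPP) with K/N/R family
    classification and substitution naming against natriuretic-peptide
    references; proteoform inference from deconvoluted intact-mass lists
    (glycan ladders, small-shift relations, disulfide-bridge counting
    between reduced and nonreduced conditions); and the three-evidence
    snake venomics relative quantification turning chromatogram
    integrals, gel densitometry and top3 ion intensities into
    toxin-family venom compositions. Includes seeded synthetic-data
    generators for every input kind so the full pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, graphics, jsonlite, pracma
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
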