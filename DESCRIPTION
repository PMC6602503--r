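Package: mmejdesign
Title: Microhomology-Mediated End Joining Target Prediction and Knock-In
    Oligo Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing gene-editing experiments that exploit
    microhomology-mediated end joining (MMEJ). Enumerates and scores all
    microhomology-mediated deletion patterns spanning a nuclease-induced
    double-strand break, scans loci for target sites likely to yield a
    single predominant MMEJ deletion allele (with CRISPR, TALEN and
    staggered-cutting nuclease support), predicts the MMEJ-repaired
    fraction of deletion outcomes with a random-forest regressor on six
    microhomology summary features, and designs homology-arm
    oligonucleotides for homology-mediated end joining knock-in
    constructs. Includes seeded synthetic-data generators for validation.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    randomForest,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
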