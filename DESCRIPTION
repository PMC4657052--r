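Package: metox
Title: Sequence and Structure Determinants of Methionine Oxidation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical and structural analysis of methionine sulfoxide
    formation in proteins. Implements per-site sequence-environment z-score
    comparisons between oxidation-prone and oxidation-resistant methionines,
    bootstrap nulls for methionine content, nearest-residue distance features
    with random-forest training and recursive feature elimination,
    sulphur-to-aromatic-ring motif geometry with a 7 Angstrom contact call,
    Shrake-Rupley solvent accessibility with exposed/buried stratification,
    exact Fisher and binomial tail tests, a rule-based reactivity classifier
    (S-aromatic motif implies low reactivity), and a synthetic-data generator
    with planted effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    caret,
    pROC,
    randomForest,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
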