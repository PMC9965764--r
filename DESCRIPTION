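Package: chemophen
Title: Untargeted Metabolomics Chemotaxonomy of Plant Taxa
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conditions untargeted LC-MS metabolite feature tables, projects
    them into compound-class, superclass and molecular-descriptor spaces via a
    chemical ontology, computes chemical diversity indices (richness, unique
    variables, Shannon H', Pielou J), selects chemophenetic marker variables by
    PLS-DA variable importance, builds chemotaxonomic dendrograms, and
    quantifies their congruence with a reference DNA phylogeny using the Mantel
    statistic and cophenetic correlation. Also links RGB spectral traits of
    phenotype images to compound-class composition through distance-based
    redundancy analysis with forward selection. Includes a synthetic-data
    generator (species tree, Brownian species effects, planted marker
    features) so the whole pipeline can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    tiff,
    withr
Config/testthat/edition: 3
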