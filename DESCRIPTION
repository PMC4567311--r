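Package: chestnutgall
Title: Associational Resistance Analysis of Chestnut Gall Wasp Damage
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify crown damage caused by the Asian chestnut
    gall wasp (Dryocosmus kuriphilus) on sweet chestnut (Castanea sativa)
    and to test associational-resistance hypotheses along tree-diversity
    gradients. Converts class-coded crown-condition assessments into
    total defoliation and total damaged-crown indices, reconstructs tree
    neighborhoods from stand maps (crown-circle proximity, coppice-clump
    collapsing, plot-margin exclusion), computes plot- and
    neighborhood-level diversity covariates (species richness, Shannon
    index and host proportion on basal-area shares, abundance-weighted
    taxonomic diversity, oak cynipid-gall incidence) and a tree apparency
    index, screens outliers with a parametric-simulation envelope, and
    fits linear mixed models on log defoliation compared by
    small-sample-corrected Akaike information criterion (AICc) with
    Akaike weights, minimum-adequate-model selection and sequential
    variance decomposition. A synthetic stand generator reproduces the
    sampling design so the full pipeline runs end-to-end without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
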