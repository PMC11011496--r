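Package: ryf
Title: Reverse-Yield Factors for Disaggregating Composite Foods into Raw
    Primary Commodities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes reverse-yield factors (RFs), the grams of each
    ingredient -- ultimately a raw primary commodity (RPC) -- required to
    produce one gram of a processed or composite food, directly from a
    food-composition table. Closed-form water/salt mass balances cover
    dried and salted foods and three pickle variants (rice-bran, vinegar,
    soy-sauce/miso); fermentation stoichiometry covers alcohol- and
    acetic-acid-fermented foods; a nutrient-balance linear system solved
    by Gauss-Jordan elimination covers mixed foods.  Per-step RFs are
    chained across processing tiers to express any composite food in RPC
    terms, as needed for dietary exposure assessment.  A forward
    simulator generates composition tables with known ground-truth RFs
    so every engine is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
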