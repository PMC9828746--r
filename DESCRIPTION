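Package: beescreen
Title: Screening-Level Pollinator Risk Assessment for Spray Adjuvants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tier-1 (screening-level) honey bee risk assessment toolkit for
    agricultural spray adjuvants, exercised on three trisiloxane polyether
    surfactants. Computes caste-resolved contact and dietary doses and risk
    quotients under either the default residue-unit-dose exposure model or
    empirical residue inputs; cleans pesticide-use-report application rates
    (IQR outlier fence, order-of-magnitude error filter, neat-versus-mixture
    selection); converts replicate residue measurements with censoring
    metadata into exposure-model inputs; and estimates toxicity endpoints
    (trimmed Spearman-Karber LD50 with confidence limits, no-observed-effect
    doses via Williams' test, Cochran-Armitage step-down, or Fisher's exact
    with Holm adjustment). Includes seeded generators for all input families
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
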