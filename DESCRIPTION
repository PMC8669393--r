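Package: drgpricing
Title: Stackelberg-Bargaining Game Models for DRG Medical Service Pricing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solvers for a three-stage game model of prospective medical-service
    pricing under diagnosis-related groups (DRGs). A government-patient alliance
    and a medical institution play two Stackelberg price/quality games (each with
    a closed-form follower best response, a bounded one-dimensional leader
    optimization, first-order-condition verification and an independent
    grid-search oracle), the two equilibria are combined by a Rubinstein
    alternating-offers bargaining split, and a social-welfare-loss-minimizing
    insurance co-payment ratio closes the model. Includes a config-driven
    scenario and parameter-sweep engine with monotonicity reporting, a seeded
    admissible-parameter fixture generator, and CSV export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
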