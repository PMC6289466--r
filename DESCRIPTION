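Package: drplearn
Title: Deterministic Response Strategies in Trial-and-Error Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trial-by-trial computational modelling of a deterministic-feedback
    stimulus-response learning task in which four novel stimuli map one-to-one
    onto four response keys. Implements four behavioural model families --
    standard Q-learning, free optimal play (an ideal observer over the 24
    candidate stimulus-response mappings), binarized play, and deterministic
    response patterns (fixed response-order strategies with forced inference) --
    together with maximum-likelihood grid fitting on initial-learning-phase
    trials, a hierarchical Wilcoxon signed-rank model-comparison procedure,
    learning-curve and error-taxonomy analyses, generative model checks, and a
    reproducible synthetic-cohort simulator for parameter- and model-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
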