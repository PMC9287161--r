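Package: sigcrf
Title: Signal Peptide Type, Cleavage-Site and Region Prediction with a
    Grammar-Constrained Conditional Random Field
Version: 0.1.0
Authors@R:
    person("sigcrf", "developers", email = "sigcrf@example.org", role = c("aut", "cre"))
Description: Predicts the five classes of N-terminal signal peptides
    (Sec/SPI, Sec/SPII, Sec/SPIII, Tat/SPI, Tat/SPII), their cleavage sites
    and their n-, h- and c-subregions with a linear-chain conditional random
    field whose transitions are constrained to a biological region grammar.
    Includes rule-based multitag (weak supervision) region labeling of
    annotated training data, a small trainable sequence encoder, a
    composition-divergence regularizer computed from CRF marginals,
    homology-aware dataset partitioning via Needleman-Wunsch identity and
    single-linkage clustering, Matthews-correlation evaluation metrics with
    cleavage-site tolerance windows, and a synthetic sequence generator so
    the full pipeline trains and evaluates at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
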