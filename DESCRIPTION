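Package: kinweave
Title: Pedigree Reconstruction, Reproductive-Practice Statistics and
    Identity-by-Descent Networks for Burial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing multi-generation pedigrees from
    pairwise relatedness degrees constrained by uniparental haplogroups,
    age at death and identity-by-descent (IBD) segment summaries, and for
    quantifying the social structure those pedigrees imply: reproductive
    unions and levirate detection, patrilineage and matrilineage
    classification, female exogamy and juvenile sex ratios, and
    consanguinity checks from pedigree inbreeding coefficients and runs of
    homozygosity.  Includes dyad-covariate exponential-family network
    models for IBD connectivity with AIC model selection, and QAP
    permutation tests on site-level IBD sharing.  A forward gene-dropping
    simulator of patrilocal communities (female exogamy, polygyny,
    levirate, crossover-level IBD and ROH, burial sampling and degree
    classification noise) provides ground truth for validating every
    analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
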