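Package: cebp
Title: Causal Effect Estimation of Somatic Mutations on Cancer Biological Processes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the average treatment effect (ATE) of individual somatic
    mutations on the activity of a cancer biological process (for example DNA
    replication or the epithelial-mesenchymal transition). Per-sample process
    activity is scored from expression data by core-gene selection and
    regression against the cohort-mean core profile; the causal effect of each
    candidate mutation is then estimated with a variational-autoencoder causal
    model that learns a latent confounder from the background mutation matrix
    and predicts counterfactual outcomes under both treatment arms. Includes
    readers for expression/mutation/MAF/GMT formats, a synthetic-data
    generator with known ground-truth effects for validation, candidate
    ranking with replicate aggregation, and Mann-Whitney group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
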