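Package: dbdnmf
Title: Dual-Branch Deep Neural Matrix Factorization for Drug Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Completes partially observed drug by cell-line response matrices
    (e.g. activity area or ln IC50) with a dual-branch neural matrix
    factorization: a trainable low-rank latent input is passed through one
    shared weight stack twice, once with nonlinear activations and once
    linearly, and the two reconstructions are blended. Includes global effect
    removal preprocessing (sequential subtraction of the global, per-drug and
    per-cell-line means), full-batch iRprop+ optimization with weight
    backtracking, per-drug Pearson/RMSE evaluation with sensitive/resistant
    quartile variants, k-fold and leave-one-unit-out (cold-start)
    cross-validation harnesses, a synthetic response-matrix generator with
    retained ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
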