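Package: klminimax
Title: Minimax Density Estimation over Data-Driven Model Classes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Robust universal inference under Kullback-Leibler loss. Builds
    data-driven restricted model classes (Gaussian-mean confidence ellipsoids,
    Sison-Glaz box-simplex regions for multinomial proportions, leave-one-out
    classes for large alphabets) and solves the associated minimax density
    estimation problems through the redundancy-capacity equivalence: mixture
    minimax estimators via the Blahut-Arimoto algorithm, projected-mixture
    estimators via a constrained iterative-projection algorithm, and normalized
    maximum likelihood (Shtarkov) estimators. Includes large-alphabet base
    estimators (maximum likelihood, add-constant/Krichevsky-Trofimov, Simple
    Good-Turing), the natural-oracle baseline, the James-Stein comparator, a
    seeded simulation harness reporting mean, variance and worst-case
    divergence or regret, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
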