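Package: ceftazpbpk
Title: Population PBPK Modelling of Ceftazidime Across Age and Renal Function
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Whole-body physiologically based pharmacokinetic (PBPK)
    simulation of ceftazidime, a passively renally cleared beta-lactam, in
    virtual adult populations spanning young to geriatric ages and renal
    impairment stages. Tissue:plasma partition coefficients are predicted
    mechanistically from drug physicochemistry and tissue composition
    (Rodgers-Rowland equations); renal function per subject follows the
    Cockcroft-Gault equation; elimination combines glomerular-filtration
    scaled renal clearance with a minor well-stirred biliary pathway. The
    package generates virtual individuals, solves the linear perfusion-
    limited compartment system exactly, performs non-compartmental analysis
    (AUC, terminal half-life, clearance, fraction excreted in urine),
    replicates published clinical study designs as 20x10 virtual trials, and
    computes fold changes in exposure across an age by renal-impairment grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
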