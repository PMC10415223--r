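Package: cefepbpk
Title: Whole-Body Physiologically Based Pharmacokinetic Modeling of Cefepime
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A whole-body physiologically based pharmacokinetic (PBPK) model of the
    cephalosporin antibiotic cefepime after intravenous infusion, with perfusion-limited
    organ compartments, Rodgers-Rowland tissue:plasma partition coefficients and
    renal-only elimination. Includes physiology transforms for pediatric, moderate and
    severe chronic kidney disease and obese subjects, seeded virtual-population
    simulation with percentile-band summaries, non-compartmental analysis (Cmax, AUC,
    terminal slope, clearance), synthetic observed-data generation, and
    model-qualification statistics (observed/predicted fold ratios, average fold error,
    two-fold criterion) recomputed from packaged clinical comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
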