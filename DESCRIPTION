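Package: metabomr
Title: Two-Sample Mendelian Randomization for Plasma Metabolite Exposures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization of plasma
    metabolites on disease outcomes from GWAS summary statistics:
    instrument selection (p-value filter, greedy LD clumping, F-statistic
    screen), exposure/outcome harmonization with palindromic-SNP handling,
    inverse-variance-weighted, MR-Egger, weighted-median and weighted-mode
    causal estimators with odds-ratio presentation, a full sensitivity
    suite (Cochran's Q, Egger intercept, MR-PRESSO global/outlier/
    distortion tests, leave-one-out, Steiger directionality), a
    classification workflow for calling robust associations across several
    outcomes, hypergeometric pathway over-representation analysis, and a
    synthetic summary-statistics generator with known ground truth for
    calibration and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: graphics, stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
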