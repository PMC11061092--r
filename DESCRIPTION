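Package: eidyn
Title: Excitation-Inhibition Ratio Perturbation in Whole-Brain Neural Mass
    Models with Symbolic-Dynamics Readouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a whole-brain network of coupled excitatory-inhibitory
    neural masses on a structural connectome and quantifies the consequences of
    excitation-inhibition (E-I) ratio perturbation with ordinal symbolic
    dynamics. The inhibitory firing-threshold parameter is swept to generate
    models with low, balanced and high E-I ratios; the simulated cortical
    signals are summarized by permutation entropy, weighted symbolic mutual
    information and the inverted joint permutation entropy, through to
    region-wise functional degree and the hub disruption index, with the
    accompanying whole-brain and regional statistics (t-tests with Cohen's d,
    Pearson correlations, Mann-Whitney U tests and two-stage
    Benjamini-Krieger-Yekutieli false discovery rate control).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
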