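Package: crcscreen
Title: Multistate Cohort Simulation of Colorectal Cancer Screening
    Colonoscopy Strategies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic and stochastic annual-cycle Markov cohort
    simulation of the colorectal cancer adenoma-carcinoma sequence, with
    screening-colonoscopy interventions under a two-lifetime-exam
    constraint and 3-/10-year post-polypectomy surveillance. Evaluates
    combinations of starting ages and inter-exam intervals on cohorts of
    100,000 men or women followed from age 45 to 85, reporting cumulative
    cancer cases, cancer deaths, years of potential life lost (YPLL) and
    disability-adjusted life years (DALYs), and relative changes versus a
    reference strategy. Includes a synthetic parameter generator that
    emulates registry-derived transition rates and calibrates age-45
    starting prevalences to age-55 prevalence targets by damped
    fixed-point iteration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
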