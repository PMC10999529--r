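Package: alsonset
Title: Composite Disease-Onset Scoring and Survival Analysis for
    SOD1-G93A Phenotyping Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting amyotrophic lateral sclerosis (ALS)
    onset in longitudinal preclinical phenotype data from SOD1-G93A
    mice.  Implements a weighted composite impairment score built from
    body weight, weight-normalized grip strength and two ordinal motor
    rubrics (hind-limb extension reflex and gait), per-animal onset
    detection with right censoring, and the downstream statistical
    stage (Kaplan-Meier onset curves, log-rank and log-rank trend
    tests, Mann-Whitney onset comparisons, two-way ANOVA with Tukey
    post hoc, Shapiro-Wilk normality, mean +/- SEM summaries).  A
    seeded synthetic-cohort simulator, calibrated to an eight-week
    treadmill endurance-training design in female SOD1-G93A mice,
    generates longitudinal and endpoint tables with known ground truth
    so the whole pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
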