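Package: microresilience
Title: Longitudinal Gut Microbiome Resilience After Antibiotic Perturbation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compositional analysis of longitudinal genus-level microbiome
    count data from perturbation-recovery study designs. Implements the
    centred log-ratio transform, Aitchison distances from a per-subject
    baseline, and the resilience statistic R(t) = (dmax - d(t)) /
    (dmax + d(t)), together with alpha-diversity summaries, prevalence
    filtering, PCA ordination, treatment-by-time linear mixed models with
    post-hoc contrasts, nonparametric taxon screens with
    Benjamini-Hochberg correction, an OGTT-derived panel of insulin
    sensitivity and secretion indices, Pocock-Simon minimization
    randomization, and a synthetic two-arm perturbation-recovery cohort
    generator with known ground truth for validating the full pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    lme4,
    emmeans,
    yaml
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    vegan,
    lmerTest,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
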