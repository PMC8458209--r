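Package: osteoplanr
Title: Coronal Lower-Limb Deformity Analysis and Osteotomy Simulation
Version: 0.1.0
Authors@R:
    person("Osteoplanr", "Developers", email = "osteoplanr@example.org",
           role = c("aut", "cre"))
Description: Landmark-based measurement of coronal lower-limb alignment on
    full-leg standing radiographs (mFTA, mMPTA, mLDFA, JLCA, weight-bearing
    line ratio), the Paley malalignment test with varus severity grading and
    correction-potential grouping, and deterministic rule-based simulation of
    valgizing osteotomies (isolated high tibial osteotomy, isolated distal
    femoral osteotomy, double-level osteotomy, uncorrectable) under
    configurable joint-line-obliquity limits. Includes a synthetic varus
    cohort generator, cohort-level statistics (chi-square with Bonferroni
    post hoc, Kruskal-Wallis with Dunn post hoc, intraclass correlation),
    and a command-line interface for reproducible pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
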