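# osteoplanr

Coronal lower-limb deformity analysis and rule-based osteotomy simulation
for varus knees.

## The problem

Varus malalignment has historically been treated as a tibial problem and
corrected by high tibial osteotomy (HTO). But the bony origin of a varus
deformity varies: it can sit in the proximal tibia, the distal femur, both,
or nowhere (intra-articular wear / ligament laxity). Correcting at the
wrong site produces an oblique knee joint line — in particular, valgizing a
normally-aligned tibia overcorrects the medial proximal tibial angle
(mMPTA), which is associated with worse outcomes when it exceeds ~95°.

`osteoplanr` implements, for full-leg standing radiographs:

* **Measurement** — the five standard coronal parameters from named 2D
  landmarks: mechanical femorotibial angle (mFTA, varus-positive),
  mMPTA, mechanical lateral distal femoral angle (mLDFA), joint line
  convergence angle (JLCA, lateral-opening-positive), and the
  weight-bearing line (WBL) ratio on the tibial plateau.
* **Deformity analysis** — the Paley malalignment test (normal knee-base
  angles 85–90°): tibial (mMPTA < 85°), femoral (mLDFA > 90°), combined, or
  no bony deformity; varus severity mild [3°,6°), moderate [6°,9°),
  severe (≥ 9°); correction potential at each site.
* **Osteotomy simulation** — deterministic planning to a target of 2°
  mechanical valgus under joint-line-obliquity limits
  (mLDFA ≥ 85° always; mMPTA ≤ 90° "anatomic" or ≤ 95° "overcorrection"):
  isolated medial open-wedge HTO, isolated lateral closed-wedge DFO,
  double-level osteotomy, or uncorrectable.
* **Synthetic cohorts** — truncated-normal generation of varus cohorts
  with the published marginal distributions, plus exact inverse
  construction of landmark sets from requested angles.
* **Statistics** — severity × location/category contingency tables,
  chi-square with Bonferroni post hoc, Kruskal–Wallis with Dunn post hoc,
  two-way single-measure ICC.

The core planning rule: the first osteotomy goes to the site of the
greatest deformity (or, without a true bony deformity, the greatest
correction potential). If the required correction
`Δ = mFTA − target` exceeds that site's wedge capacity under the limits,
the primary angle is driven to its limit and a second osteotomy at the
opposite site completes the correction; if even both sites at their limits
cannot reach the target, the leg is uncorrectable. One degree of wedge
changes mFTA by one degree (first-order model; JLCA is held static).

## Worked example

The 6°-varus knee with mMPTA 85.3° and mLDFA 89.3° — both knee-base angles
normal, so no bony deformity, but correction potential at both sites:

```r
library(osteoplanr)
knee <- knee_alignment(mFTA = 6, mMPTA = 85.3, mLDFA = 89.3, JLCA = 2)
classify_location(knee)
#> [1] "NO_BONY_DEFORMITY"
correction_potential(knee)
#> $tibial   : 4.7
#> $femoral  : 4.3
#> $category : "TIBIAL_AND_FEMORAL"
```

An isolated HTO capped at mMPTA ≤ 90° cannot reach 2° valgus — 1.3° of
varus remains:

```r
simulate_single_osteotomy(knee, "TIBIA", scenario_limits("anatomic"))
#> <knee_alignment> mFTA 1.3 deg varus | mMPTA 90.0 | mLDFA 89.3 | JLCA 2.0 | WBL NA
```

so the anatomic scenario needs a double-level correction, while tolerating
overcorrection to mMPTA ≤ 95° allows an isolated HTO:

```r
plan_correction(knee, scenario_limits("anatomic"))
#> <osteotomy_plan> DOUBLE_LEVEL (anatomic scenario)
#>   primary site TIBIA | HTO wedge 4.7 deg | DFO wedge 3.3 deg
#>   post: mFTA -2.0 | mMPTA 90.0 | mLDFA 86.0
plan_correction(knee, scenario_limits("overcorrection"))
#> <osteotomy_plan> TIBIAL (overcorrection scenario)
#>   primary site TIBIA | HTO wedge 8.0 deg | DFO wedge 0.0 deg
#>   post: mFTA -2.0 | mMPTA 93.3 | mLDFA 89.3
```

Cohort-scale use:

```r
co <- generate_cohort(cohort_config(n = 300, seed = 1))
ideal_level_table(co, scenario_limits("anatomic"))
#>           category
#> severity   TIBIAL FEMORAL DOUBLE_LEVEL UNCORRECTABLE
#>   MILD          5       7           89            38
#>   MODERATE      0       0           64            53
#>   SEVERE        0       0            4            40
ideal_level_table(co, scenario_limits("overcorrection"))
#>           category
#> severity   TIBIAL FEMORAL DOUBLE_LEVEL UNCORRECTABLE
#>   MILD         68       7           64             0
#>   MODERATE     44       0           73             0
#>   SEVERE        2       0           42             0
```

Raising the mMPTA limit from 90° to 95° moves knees from double-level and
uncorrectable toward isolated HTO — the qualitative behaviour real cohorts
show. The synthetic generator matches only published *marginal*
distributions (angles drawn independently, then selected on mFTA ≥ 3°), so
its cohort-level percentages are illustrative, not a replication of any
real cohort; see the vignette.

## Command line

```sh
Rscript inst/cli/osteoplanr generate --n 100 --seed 1 --out cohort.csv
Rscript inst/cli/osteoplanr classify --cohort cohort.csv --out classified.csv
Rscript inst/cli/osteoplanr plan --cohort classified.csv --scenario anatomic \
    --out plan.csv --summary summary.csv
Rscript inst/cli/osteoplanr report --cohort cohort.csv --scenario anatomic --outdir report/
```

Every output CSV starts with `#` comment lines recording the package
version, scenario and seed.

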