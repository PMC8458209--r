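---
title: "Coronal deformity analysis and osteotomy simulation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coronal deformity analysis and osteotomy simulation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoplanr)
```

This vignette documents the models behind `osteoplanr`, the parameters
that matter, the numerical conventions, and what the synthetic-data tests
do and do not establish.

## The coronal model

A standing full-leg radiograph projects the limb onto the coronal plane.
Five parameters summarise its alignment:

* **mFTA** — angle between the femoral mechanical axis (femoral head
  centre to femoral knee base) and the tibial mechanical axis (tibial
  knee base to ankle centre). We use the varus-positive convention:
  mFTA = 6 means 6° of mechanical varus, mFTA = −2 means 2° valgus.
* **mMPTA** — medial angle between the tibial mechanical axis and the
  tibial plateau line; normal 85–90°, smaller = tibial varus.
* **mLDFA** — lateral angle between the femoral mechanical axis and the
  femoral condylar line; normal 85–90°, larger = femoral varus.
* **JLCA** — angle between condylar and plateau lines, positive when they
  converge medially (joint space opens laterally), the usual situation in
  varus knees with medial wear or lateral laxity.
* **WBL ratio** — where the femoral-head-to-ankle-centre line crosses the
  tibial plateau, in percent of the medial-to-lateral plateau width.

To first order in these small angles the contributions add:

$$\mathrm{mFTA} \;=\; (90 - \mathrm{mMPTA}) \;+\; (\mathrm{mLDFA} - 90)
\;+\; \mathrm{JLCA}.$$

`coronal_mfta()` implements this decomposition; feeding it the typical
varus-cohort medians (mMPTA 86°, mLDFA 89°, JLCA 2°) returns the matching
median mFTA of 5°. The full 2D landmark geometry
(`measure_alignment()`) agrees with the additive model to well under 0.2°
across the physiologic range — the property suite checks this — so the
planner works in angle space and the geometry module serves measurement
and validation.

### Landmark geometry conventions

Coordinates follow the digital-radiograph convention (x to the patient's
left, y downward, millimetres); a `side` flag resolves which direction is
medial, making all signs side-aware (mirroring a landmark set left/right
changes no output). The ankle centre is the midpoint of the medial and
lateral talar borders. This is a recorded package choice: planning
software may instead use the ankle-mortise centre, and nothing in our
sources fixes one or the other; for the symmetric constructions used here
the two coincide. All outputs are invariant to translation, rotation and
uniform scaling of the landmarks (checked to 1e-9°). Degenerate input —
coincident axis endpoints, a weight-bearing line parallel to the plateau —
is rejected with an error naming the offending axis. Angles are carried at
full precision internally and reported to 0.1° in printed output.

`inverse_construct_landmarks()` solves the inverse problem: given target
(mFTA, mMPTA, mLDFA) it builds an idealized leg — tibial axis vertical,
plateau tilted by mMPTA − 90, femoral axis tilted by the varus angle,
condylar line tilted by mLDFA − 90 in the femur frame — whose measured
angles reproduce the request to numerical precision. JLCA is emergent and
equals the additive-model value up to second-order terms. Segment lengths
default to femur 450 mm, tibia 380 mm, plateau width 80 mm (adult
proportions); with these defaults a 6°-varus knee yields a WBL ratio of
about 23%, consistent with the ~4–5% medial shift per varus degree
reported for real limbs. Angles are scale-invariant, so the lengths only
matter for the WBL ratio.

## Deformity classification

The malalignment test takes "normal" as the closed interval [85°, 90°]
for both knee-base angles and requires the strict inequalities
mMPTA < 85° / mLDFA > 90° for deformity. Whether a measurement of exactly
85 or 90 counts as normal is not fixed by convention anywhere we know of;
closed-interval normality is the recorded choice here (boundary values are
normal). The four groups — tibial, femoral, combined, no bony deformity —
partition the plane of knee-base angles: a knee with mMPTA < 85° and a
*low* mLDFA (< 85°) is still "tibial", matching the rule's phrasing in
terms of the two pathologic directions relevant to varus.

Severity bins the continuous mFTA into half-open intervals [3, 6),
[6, 9), [9, ∞) labelled mild / moderate / severe. The printed clinical
labels ("3°–5°", "6°–8°", "≥ 9°") enumerate integers; half-open intervals
preserve those cut points for non-integer measurements without double
counting. Severity is undefined below 3° varus (the inclusion threshold)
and the function refuses such input rather than extrapolating.

Correction potential is kept real-valued — tibial potential
`limit − mMPTA`, femoral potential `mLDFA − 85`, each floored at 0 —
because the planner consumes the magnitudes; the categorical grouping
(tibial / femoral / both / none) is derived from positivity.

## The osteotomy simulation

Scenario limits bound the postoperative knee-base angles to cap joint
line obliquity: mLDFA ≥ 85° in every scenario, and mMPTA ≤ 90°
("anatomic") or ≤ 95° ("overcorrection" — the level beyond which
excessive medial shear stress and inferior outcomes are reported). The
target alignment is 2° mechanical valgus, the common valgization goal for
medial-compartment unloading. All three are plain numbers in
`scenario_limits()` and can be varied for sweeps.

The wedge model is first order and additive: a medial open-wedge HTO of
w° raises mMPTA by w and valgizes mFTA by w; a lateral closed-wedge DFO
of w° lowers mLDFA by w and valgizes mFTA by w. No translation,
limb-length or hinge-point effects are modelled, and JLCA is frozen
during simulation — the simulation considers static alignment only.
In knees with large preoperative JLCA some of the varus is
intra-articular, and a real correction may need less bony wedge than the
static model assigns; this is a known, deliberate limitation of the
method, not of the implementation.

Planning rules, in order:

1. **Primary site** = site of the greatest deformity by the malalignment
   test. For a combined deformity, the larger deviation beyond the normal
   range (85 − mMPTA vs mLDFA − 90) decides; with no bony deformity, the
   larger anatomic-bound potential (90 − mMPTA vs mLDFA − 85) decides.
   Two recorded choices live here: ties prefer the tibia (HTO being the
   historical default procedure), and site selection always uses the
   anatomic bounds even in the overcorrection scenario, so the site is
   scenario-stable and only wedge *capacity* changes with the limit —
   consistent with isolated-DFO prevalence being identical under both
   scenarios in cohort studies.
2. **Single osteotomy** if the required correction Δ = mFTA − target fits
   the primary site's capacity under the limits.
3. **Double-level** otherwise, if the two capacities together suffice:
   the primary wedge drives its knee-base angle exactly to the scenario
   limit, the opposite-site wedge finishes the correction. In the
   overcorrection scenario the first wedge may thus set mMPTA = 95°, the
   scenario's limit.
4. **Uncorrectable** if even both sites at their limits cannot reach the
   target; the plan then records the best achievable alignment (both
   angles at their limits) rather than nothing.

The limits constrain the *correction*: a knee presenting beyond a limit
(e.g. mLDFA 83°, inside the published observed range) simply has zero
capacity at that site and keeps its presenting value. A consequence of
rule 1 worth knowing: under the overcorrection limits a femoral-primary
knee can occasionally admit an isolated HTO that the rules never
consider, because simulation starts — and stays, unless capacity runs
out — at the site of the deformity. The planner is deterministic, so the
property suite can hold it to an independent grid-enumeration oracle:
category agrees with feasibility exactly on 10,000 random knees, wedges
always sum to Δ, and raising the mMPTA limit never worsens a knee's
category (isolated ≺ double-level ≺ uncorrectable).

## The synthetic cohort generator

`generate_cohort()` emulates a varus cohort whose *marginal* angle
distributions match published summaries: mMPTA ~ N(86, 2²) truncated to
[78, 93], mLDFA ~ N(89, 2²) on [83, 95], JLCA ~ N(2, 2²) on [0, 8] — the
truncation bounds are the published observed ranges, which keeps draws
physiologic — with mFTA computed from the additive model and knees
rejected until mFTA ≥ 3° (the inclusion criterion). The published mFTA
dispersion ("6° ± 11°") is internally inconsistent with its own 3°–15°
range and is almost certainly a typographic artefact; the generator never
uses it — mFTA's distribution follows from the other three marginals plus
selection. The WBL ratio is measured geometrically on a constructed
landmark set per knee rather than drawn, making it a deterministic
function of the angles.

The three angles are drawn independently *before* selection because only
marginals are published; the dependence among accepted knees is an
emergent effect of conditioning on mFTA ≥ 3°, not a calibrated joint
distribution. Real varus cohorts concentrate deformity in correlated
patterns this generator cannot know about. Consequently:

* Generator tests establish that the sampling is correct (accepted-sample
  means match quadrature over the truncated-and-selected density within
  Monte-Carlo error at n = 10,000) and that the machinery downstream
  behaves lawfully on realistic inputs.
* Cohort-level *percentages* (deformity prevalences, plan-category
  distributions) are *not* expected to reproduce any real cohort's
  numbers, and the tests only assert their qualitative directions — e.g.
  HTO count non-decreasing and uncorrectable count non-increasing from
  the 90° to the 95° limit, the direction real data shows. In this
  generator's stated world the anatomic-scenario uncorrectable fraction
  is substantially higher than in the real cohort it emulates, because
  independent draws put more varus into JLCA (not correctable by bone)
  than a correlated cohort would.

Cohorts are pure functions of their configuration (seed included):
identical configs give byte-identical CSV artifacts.

## Statistics

The cohort statistics mirror standard radiographic-study practice:
Pearson chi-square on severity × location / scenario × category tables
(no continuity correction by default, matching the omnibus framing; a
flag enables Yates for 2×2), pairwise 2×k chi-squares with Bonferroni
adjustment (p multiplied by the number of pairs, capped at 1) as the post
hoc, Kruskal–Wallis with tie correction for JLCA across severity groups
with Dunn z-tests (Bonferroni-adjusted) as the post hoc, and the
intraclass correlation for repeated measurements. The ICC form is fixed
to two-way, single-measure, absolute agreement — ICC(A,1) — as the
default, with a consistency option; reliability studies of this design
(same raters rating all subjects, absolute values of interest) call for
exactly this form, though the convention is a package decision since
"ICC" alone underdetermines it. A zero-variance ratings matrix yields an
explicit "undefined" result rather than NaN.

## Numerical choices

* Capacity comparisons in the planner use a 1e-9° slack to absorb
  floating-point noise; wedges are computed exactly otherwise.
* The severity bins are evaluated on the continuous mFTA with half-open
  intervals, so 5.999° is mild and 6.0° moderate.
* `knee_alignment()` validates hard geometric sanity (knee-base angles in
  (60°, 120°), |JLCA| < 30°) but not study-inclusion rules; functions
  with narrower preconditions (severity, planning) enforce those
  themselves.
* The feasibility oracle used in tests enumerates wedges on a 0.05° grid
  plus the two constraint-boundary candidates, making it exact for this
  linear problem; a zero wedge is "no osteotomy" and is never held to the
  post-osteotomy limit.

## Known limitations

Static JLCA (no intra-articular correction share), first-order wedge
geometry (no hinge/translation effects, no wedge-height conversion),
2D projection only, no soft-tissue modelling, and a synthetic generator
calibrated to marginals only. These bound what a green test suite
establishes: the implementation is faithful to the stated rules and
distributions, not that those rules reproduce any particular clinical
cohort's percentages.
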