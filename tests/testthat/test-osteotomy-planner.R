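test_that("wedge operators are additive identities in angle space", {
  a <- knee_alignment(6, 85.3, 89.3, 2)
  expect_angles_within(apply_tibial_osteotomy(a, 0), a, 1e-12)
  expect_angles_within(apply_femoral_osteotomy(a, 0), a, 1e-12)

  # HTO: mMPTA up, varus down; published worked case
  h <- apply_tibial_osteotomy(knee_alignment(6, 85.3, 89.3), 4.7)
  expect_equal(h$mMPTA, 90)
  expect_equal(h$mFTA, 1.3)
  expect_equal(h$mLDFA, 89.3)

  # DFO: mLDFA down, varus down; the raw operator is unconstrained
  d <- apply_femoral_osteotomy(knee_alignment(5.5, 88, 91.5), 7.5)
  expect_equal(d$mLDFA, 84)
  expect_equal(d$mFTA, -2)
  d2 <- apply_femoral_osteotomy(knee_alignment(5, 88, 90), 5)
  expect_equal(d2$mLDFA, 85)

  # two wedges a then b == one wedge a+b
  set.seed(8)
  for (i in 1:20) {
    w <- runif(2, 0, 4)
    a0 <- knee_alignment(10, 84, 92, 2)
    expect_angles_within(
      apply_tibial_osteotomy(apply_tibial_osteotomy(a0, w[1]), w[2]),
      apply_tibial_osteotomy(a0, sum(w)), 1e-12)
    expect_angles_within(
      apply_femoral_osteotomy(apply_femoral_osteotomy(a0, w[1]), w[2]),
      apply_femoral_osteotomy(a0, sum(w)), 1e-12)
  }
  expect_error(apply_tibial_osteotomy(a, -1), "non-negative")
  expect_error(apply_femoral_osteotomy(a, -0.5), "non-negative")
})

test_that("primary site follows the greatest-deformity rule", {
  # tibial deformity -> tibia (severe worked case)
  expect_identical(choose_primary_site(knee_alignment(10, 84.4, 90)),
                   "TIBIA")
  # femoral deformity -> femur
  expect_identical(choose_primary_site(knee_alignment(6, 87, 92)), "FEMUR")
  # no deformity: greater anatomic potential wins (worked case: 4.7 > 4.3)
  expect_identical(choose_primary_site(knee_alignment(6, 85.3, 89.3)),
                   "TIBIA")
  expect_identical(choose_primary_site(knee_alignment(6, 89, 89.5)),
                   "FEMUR")
  # combined deformity: larger deviation beyond the normal range wins
  expect_identical(choose_primary_site(knee_alignment(8, 84, 92)), "FEMUR")
  expect_identical(choose_primary_site(knee_alignment(8, 82, 91)), "TIBIA")
  # ties prefer the tibia
  expect_identical(choose_primary_site(knee_alignment(8, 84, 91)), "TIBIA")
  expect_identical(choose_primary_site(knee_alignment(6, 86, 89)), "TIBIA")
  # site choice is scenario-stable: anatomic bounds even for overcorrection
  expect_identical(
    choose_primary_site(knee_alignment(6, 89, 89.5),
                        scenario_limits("overcorrection")),
    "FEMUR")
  expect_error(choose_primary_site(knee_alignment(2, 86, 89)), ">= 3")
})

test_that("plan_correction reproduces the published worked cases", {
  # no-bony-deformity 6 degree varus case
  case3 <- knee_alignment(6, 85.3, 89.3, 2)
  p90 <- plan_correction(case3, scenario_limits("anatomic"))
  expect_identical(p90$category, "DOUBLE_LEVEL")
  expect_identical(p90$primary_site, "TIBIA")
  expect_equal(p90$tibial_wedge, 4.7)
  expect_equal(p90$femoral_wedge, 3.3)
  expect_equal(p90$post_alignment$mMPTA, 90)
  expect_equal(p90$post_alignment$mFTA, -2)

  p95 <- plan_correction(case3, scenario_limits("overcorrection"))
  expect_identical(p95$category, "TIBIAL")
  expect_equal(p95$tibial_wedge, 8)
  expect_equal(p95$femoral_wedge, 0)
  expect_equal(p95$post_alignment$mMPTA, 93.3)
  expect_equal(p95$post_alignment$mFTA, -2)

  # severe tibial-deformity case: uncorrectable anatomically,
  # double-level with overcorrection
  case4 <- knee_alignment(10, 84.4, 90, 4.4)
  q90 <- plan_correction(case4, scenario_limits("anatomic"))
  expect_identical(q90$category, "UNCORRECTABLE")
  expect_equal(q90$tibial_wedge, 5.6)
  expect_equal(q90$femoral_wedge, 5)
  expect_equal(q90$post_alignment$mFTA, -0.6)  # best achievable
  q95 <- plan_correction(case4, scenario_limits("overcorrection"))
  expect_identical(q95$category, "DOUBLE_LEVEL")
  expect_equal(q95$post_alignment$mFTA, -2)

  # a tibial deformity does not guarantee isolated HTO
  mix <- plan_correction(knee_alignment(5, 84, 89, 0),
                         scenario_limits("anatomic"))
  expect_identical(mix$category, "DOUBLE_LEVEL")
  expect_equal(mix$tibial_wedge, 6)
  expect_equal(mix$femoral_wedge, 1)

  expect_error(plan_correction(knee_alignment(4, 86, 89),
                               scenario_limits(target_mFTA = 4)),
               "target")
})

test_that("capped single-site simulation reports the residual varus", {
  r <- simulate_single_osteotomy(knee_alignment(6, 85.3, 89.3), "TIBIA",
                                 scenario_limits("anatomic"))
  expect_equal(r$mFTA, 1.3)
  expect_equal(r$mMPTA, 90)
  r95 <- simulate_single_osteotomy(knee_alignment(6, 85.3, 89.3), "TIBIA",
                                   scenario_limits("overcorrection"))
  expect_equal(r95$mFTA, -2)
  r4 <- simulate_single_osteotomy(knee_alignment(10, 84.4, 90), "TIBIA",
                                  scenario_limits("anatomic"))
  expect_equal(r4$mFTA, 4.4)
  # severe case under overcorrection: isolated HTO to the 95-degree cap
  # leaves near-neutral alignment (10 - 10.6 = -0.6, i.e. 0.6 valgus)
  r4b <- simulate_single_osteotomy(knee_alignment(10, 84.4, 90), "TIBIA",
                                   scenario_limits("overcorrection"))
  expect_equal(r4b$mFTA, -0.6)
  expect_equal(r4b$mMPTA, 95)
})

test_that("planner agrees with the grid feasibility oracle", {
  knees <- random_knees(2000, seed = 101)
  for (limits in list(scenario_limits("anatomic"),
                      scenario_limits("overcorrection"))) {
    planned <- plan_cohort(knees, limits)
    oracle <- lapply(seq_len(nrow(knees)), function(i)
      oracle_feasibility(knees$mFTA[i], knees$mMPTA[i], knees$mLDFA[i],
                         limits))
    feas <- vapply(oracle, `[[`, TRUE, "feasible")
    st <- vapply(oracle, `[[`, TRUE, "single_tibial")
    sf <- vapply(oracle, `[[`, TRUE, "single_femoral")
    expect_identical(planned$category != "UNCORRECTABLE", feas)
    expect_true(all(st[planned$category == "TIBIAL"]))
    expect_true(all(sf[planned$category == "FEMORAL"]))
    # a double-level plan means no single osteotomy at the chosen primary
    # site reaches the target
    dbl <- planned$category == "DOUBLE_LEVEL"
    expect_false(any(st[dbl & planned$primary_site == "TIBIA"]))
    expect_false(any(sf[dbl & planned$primary_site == "FEMUR"]))
  }
})

test_that("plans conserve the correction and respect the limits", {
  knees <- random_knees(5000, seed = 202)
  for (limits in list(scenario_limits("anatomic"),
                      scenario_limits("overcorrection"))) {
    p <- plan_cohort(knees, limits)
    ok <- p$category != "UNCORRECTABLE"
    expect_true(all(abs(p$tibial_wedge[ok] + p$femoral_wedge[ok] -
                          (knees$mFTA[ok] - limits$target_mFTA)) < 1e-9))
    expect_true(all(p$post_mFTA[ok] - limits$target_mFTA < 1e-9))
    # the limits bound the correction, not the presentation: an angle the
    # wedge never moves past its limit, but a knee presenting beyond a
    # limit stays where it is (its capacity at that site is zero)
    expect_true(all(p$post_mMPTA <=
                      pmax(knees$mMPTA, limits$mMPTA_upper) + 1e-9))
    expect_true(all(p$post_mLDFA >=
                      pmin(knees$mLDFA, limits$mLDFA_lower) - 1e-9))
    expect_true(all(p$tibial_wedge[knees$mMPTA >= limits$mMPTA_upper] == 0))
    expect_true(all(p$femoral_wedge[knees$mLDFA <= limits$mLDFA_lower] == 0))
    expect_true(all(p$tibial_wedge >= 0 & p$femoral_wedge >= 0))
    # single-site plans leave the other site untouched
    expect_true(all(p$femoral_wedge[p$category == "TIBIAL"] == 0))
    expect_true(all(p$tibial_wedge[p$category == "FEMORAL"] == 0))
  }
})

test_that("raising the mMPTA limit is monotone per knee and cohort-wide", {
  knees <- random_knees(5000, seed = 303)
  p90 <- plan_cohort(knees, scenario_limits("anatomic"))
  p95 <- plan_cohort(knees, scenario_limits("overcorrection"))
  badness <- c(TIBIAL = 1, FEMORAL = 1, DOUBLE_LEVEL = 2, UNCORRECTABLE = 3)
  expect_true(all(badness[p95$category] <= badness[p90$category]))
  expect_gte(sum(p95$category == "TIBIAL"), sum(p90$category == "TIBIAL"))
  expect_lte(sum(p95$category == "UNCORRECTABLE"),
             sum(p90$category == "UNCORRECTABLE"))
  # headline direction: whenever a tibial-primary double-level knee exists
  # under the 90 limit, the 95-limit HTO fraction is strictly larger
  promoted <- p90$category == "DOUBLE_LEVEL" & p90$primary_site == "TIBIA"
  if (any(promoted))
    expect_gt(sum(p95$category == "TIBIAL"), sum(p90$category == "TIBIAL"))
})

test_that("ideal_level_table cross-tabulates severity by category", {
  one <- data.frame(id = 1, mFTA = 3, mMPTA = 84.9, mLDFA = 88, JLCA = 1.5)
  t1 <- ideal_level_table(one, scenario_limits("anatomic"))
  expect_equal(sum(t1), 1)
  expect_equal(t1["MILD", "TIBIAL"], 1, ignore_attr = TRUE)

  same <- data.frame(id = 1:7, mFTA = 10, mMPTA = 84.4, mLDFA = 90,
                     JLCA = 4.4)
  t2 <- ideal_level_table(same, scenario_limits("anatomic"))
  expect_equal(sum(t2 > 0), 1)
  expect_equal(t2["SEVERE", "UNCORRECTABLE"], 7, ignore_attr = TRUE)

  empty <- data.frame(id = integer(0), mFTA = numeric(0),
                      mMPTA = numeric(0), mLDFA = numeric(0))
  t0 <- ideal_level_table(empty)
  expect_equal(sum(t0), 0)
  expect_identical(dim(t0), c(3L, 4L))

  co <- generate_cohort(cohort_config(n = 400, seed = 17),
                        compute_wbl = FALSE)
  tt <- ideal_level_table(co, scenario_limits("anatomic"))
  expect_equal(sum(tt), 400)
  expect_identical(rownames(tt), c("MILD", "MODERATE", "SEVERE"))
  expect_identical(colnames(tt),
                   c("TIBIAL", "FEMORAL", "DOUBLE_LEVEL", "UNCORRECTABLE"))
})
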