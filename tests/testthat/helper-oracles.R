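# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: grid enumeration for plan feasibility, root
# finding for the plateau intersection, quadrature for the generator's
# truncated-selected moments, aov() for the ICC mean squares.

# Grid-enumeration feasibility oracle for the osteotomy planner.
# Enumerates tibial wedges on a `step` grid (femoral wedge is the exact
# complement reaching the target) subject to the scenario limits, and
# separately checks the two single-site solutions. Returns feasibility
# flags independent of the planner's potential arithmetic.
oracle_feasibility <- function(mFTA, mMPTA, mLDFA, limits, step = 0.05) {
  delta <- mFTA - limits$target_mFTA
  # a zero wedge is "no osteotomy at this site": the limit only binds an
  # osteotomy actually performed
  ok_t <- function(t) t <= 1e-12 | mMPTA + t <= limits$mMPTA_upper + 1e-9
  ok_f <- function(f) f <= 1e-12 | mLDFA - f >= limits$mLDFA_lower - 1e-9
  single_tibial <- ok_t(delta)
  single_femoral <- ok_f(delta)
  t_grid <- seq(0, delta, by = step)
  if (t_grid[length(t_grid)] < delta) t_grid <- c(t_grid, delta)
  # the feasible window can be narrower than the grid step; add the two
  # constraint-boundary candidates (clamped into [0, delta]) so the
  # enumeration is exact for this linear problem
  bnd <- c(limits$mMPTA_upper - mMPTA, delta - (mLDFA - limits$mLDFA_lower))
  t_grid <- c(t_grid, pmin(pmax(bnd, 0), delta))
  f_grid <- delta - t_grid
  pair_ok <- ok_t(t_grid) & ok_f(f_grid)
  list(feasible = any(pair_ok),
       single_tibial = single_tibial,
       single_femoral = single_femoral,
       double = any(pair_ok & t_grid > 1e-12 & f_grid > 1e-12))
}

# Root-finding oracle for the weight-bearing-line ratio: find the plateau
# parameter t at which the signed area spanned by the WBL direction and
# the vector from the femoral head to the plateau point vanishes.
oracle_wbl_ratio <- function(landmarks) {
  ankle <- (landmarks$talus_medial + landmarks$talus_lateral) / 2
  a <- landmarks$tibial_plateau_medial
  b <- landmarks$tibial_plateau_lateral
  p <- landmarks$femoral_head_center
  d <- ankle - p
  f <- function(t) {
    q <- a + t * (b - a) - p
    q[1] * d[2] - q[2] * d[1]
  }
  100 * stats::uniroot(f, c(-10, 10), tol = 1e-14)$root
}

# Midpoint-rule quadrature of the truncated joint density with the
# selection constraint mFTA >= min_varus; returns the conditional means.
oracle_selected_means <- function(cfg, h = 0.1) {
  mids <- function(b) seq(b[1] + h / 2, b[2] - h / 2, by = h)
  gm <- mids(cfg$mMPTA_bounds)
  gl <- mids(cfg$mLDFA_bounds)
  gj <- mids(cfg$JLCA_bounds)
  wm <- stats::dnorm(gm, cfg$mMPTA_mean, cfg$mMPTA_sd)
  wl <- stats::dnorm(gl, cfg$mLDFA_mean, cfg$mLDFA_sd)
  wj <- stats::dnorm(gj, cfg$JLCA_mean, cfg$JLCA_sd)
  w3 <- outer(outer(wm, wl), wj)                      # [m, l, j]
  mfta <- outer(outer(90 - gm, gl - 90, "+"), gj, "+")
  ws <- w3 * (mfta >= cfg$inclusion_min_varus)
  z <- sum(ws)
  sm <- rowSums(ws, dims = 1)
  slj <- colSums(ws)                                  # [l, j]
  sl <- rowSums(slj)
  sj <- colSums(slj)
  list(mMPTA = sum(gm * sm) / z,
       mLDFA = sum(gl * sl) / z,
       JLCA = sum(gj * sj) / z,
       mFTA = sum(mfta * ws) / z,
       accept_prob = z / sum(w3))
}

# Closed-form 2x2 Pearson chi-square
oracle_chisq_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# aov()-based mean squares for the two-way ICC
oracle_icc_agreement <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  df <- data.frame(y = as.vector(ratings),
                   subject = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Random physiologic knees for property tests (not via generate_cohort, so
# planner properties are exercised on a wider grid than the generator's)
random_knees <- function(n, seed) {
  set.seed(seed)
  d <- data.frame(id = seq_len(n),
                  mMPTA = runif(n, 78, 93),
                  mLDFA = runif(n, 83, 95),
                  JLCA = runif(n, 0, 8))
  d$mFTA <- 3 + runif(n, 0, 12)
  d
}

expect_angles_within <- function(a, b, tol = 1e-6) {
  expect_lt(abs(a$mFTA - b$mFTA), tol)
  expect_lt(abs(a$mMPTA - b$mMPTA), tol)
  expect_lt(abs(a$mLDFA - b$mLDFA), tol)
}
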