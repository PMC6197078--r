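test_that("oxygenation surrogate is the clamped capacity headroom", {
  expect_equal(oxygen_pressure(220, 100), 54.54545454545455)
  expect_equal(oxygen_pressure(150, 150), 0)   # tumor at capacity
  expect_equal(oxygen_pressure(100, 120), 0)   # capacity below active: clamped
  expect_equal(oxygen_pressure(100, 0), 100)
  expect_error(oxygen_pressure(0, 50), "capacity")
  expect_error(oxygen_pressure(-10, 50), "capacity")
  expect_error(oxygen_pressure(100, -1), "non-negative")
})

test_that("radiosensitivity maps oxygenation linearly between the bounds", {
  expect_equal(radiosensitivity(0), 0.001)
  expect_equal(radiosensitivity(100), 0.3)
  expect_equal(radiosensitivity(50), 0.1505)
  cst <- model_constants(alpha_min = 0.01, alpha_max = 0.1)
  expect_equal(radiosensitivity(25, cst), 0.01 + 0.25 * 0.09)
  expect_error(radiosensitivity(-1), "\\[0, 100\\]")
  expect_error(radiosensitivity(101), "\\[0, 100\\]")
})

test_that("LQ surviving fraction matches direct evaluation and is monotone", {
  expect_equal(surviving_fraction(0.3, 1, 0, 10), 1)
  expect_equal(surviving_fraction(0.3, 1, 1.8, 10), 0.5287709117472098)
  expect_equal(surviving_fraction(0.001, 1, 1.8, 10), 0.9978782540918205)
  # worst/best case at the standard fraction stay strictly inside (0.5, 1)
  expect_gt(surviving_fraction(0.3, 1, 1.8, 10), 0.5)
  expect_lt(surviving_fraction(0.001, 1, 1.8, 10), 1)
  # strictly decreasing in dose, alpha and gamma
  d <- seq(0, 4.5, by = 0.5)
  expect_true(all(diff(sapply(d, function(x)
    surviving_fraction(0.2, 1, x, 10))) < 0))
  a <- seq(0.001, 0.3, length.out = 20)
  expect_true(all(diff(sapply(a, function(x)
    surviving_fraction(x, 1, 2, 10))) < 0))
  expect_lt(surviving_fraction(0.2, 0.9, 2, 3),
            surviving_fraction(0.2, 0.6, 2, 3))
  expect_error(surviving_fraction(0.2, 1, -1, 10), "non-negative")
})

test_that("necrotic cohorts decay exponentially from their creation day", {
  # one half-life halves the cohort, exactly
  s <- make_state(t = 14, v_a = 50, k = 200, t_i = 0L, v0 = 10)
  expect_equal(necrotic_volume(s, 14), 5)
  # empty ledger
  expect_equal(necrotic_volume(make_state(3, 50, 200), 14), 0)
  # term-by-term sum: 10 * 2^-2 + 4 * 2^-1
  s2 <- make_state(t = 4, v_a = 50, k = 200, t_i = c(0L, 2L), v0 = c(10, 4))
  expect_equal(necrotic_volume(s2, 2), 4.5)
  # exact-halving property at arbitrary half-lives
  for (th in c(2, 4, 17, 30)) {
    s3 <- make_state(t = th, v_a = 50, k = 200, t_i = 0L, v0 = 8)
    expect_equal(necrotic_volume(s3, th), 4)
  }
})

test_that("a single irradiated day reproduces the hand-calculated update", {
  a <- patient_parameters("A", 0.17, 14, 220, 0.9)
  s1 <- tumor_step(initial_state(a), 1.8, a)
  expect_equal(attr(s1, "po2"), 54.54545454545455)
  expect_equal(attr(s1, "alpha"), 0.1640909090909091)
  expect_equal(attr(s1, "sf_t"), 0.7057253845322997)
  expect_equal(s1$v_a, 80.03192280834672)
  expect_equal(s1$k, 143.7828118514315)
  expect_equal(s1$cohorts$v0, 29.42746154677003)
  expect_equal(s1$t, 1L)
  # mass-conserving variant books the killed part of the grown volume
  s1m <- tumor_step(initial_state(a), 1.8, a, mass_conserving = TRUE)
  expect_equal(s1m$cohorts$v0 + s1m$v_a, 113.4037751261926)
  expect_equal(s1m$v_a, s1$v_a)  # active dynamics unchanged
})

test_that("degenerate daily updates behave as closed forms predict", {
  # no growth, no dose: state frozen, cohorts decay only
  p0 <- suppressWarnings(patient_parameters("z", 0, 10, 150, 0.5,
                                            relaxed = TRUE))
  s <- make_state(0, 80, 150, t_i = 0L, v0 = 10)
  s1 <- tumor_step(s, NULL, p0)
  expect_equal(s1$v_a, 80)
  expect_equal(s1$k, 150)
  expect_equal(necrotic_volume(s1, 10), 10 * 2^(-1 / 10))
  # Gompertz fixed point: v_a = k stays put without irradiation
  pf <- patient_parameters("f", 0.15, 10, 150, 0.5)
  sf <- tumor_step(make_state(0, 150, 150), NULL, pf)
  expect_equal(sf$v_a, 150)
})

test_that("simulate agrees with the naive oracle to machine precision", {
  cohort <- reference_cohort()
  cases <- list(
    list(p = cohort$A, s = constant_schedule(3)),
    list(p = cohort$B, s = constant_schedule(1.8)),
    list(p = cohort$D, s = constant_schedule(1)),
    list(p = cohort$F, s = ramp_schedule()),
    list(p = cohort$G, s = ramp_schedule(direction = "decreasing"))
  )
  for (cs in cases) {
    sim <- simulate_course(cs$p, cs$s)
    ora <- oracle_trajectory(cs$p, cs$s$fractions$day, cs$s$fractions$dose_Gy)
    expect_equal(sim$trajectory$V_a, ora$V_a, tolerance = 1e-12)
    expect_equal(sim$trajectory$V_n, ora$V_n, tolerance = 1e-12)
    expect_equal(sim$trajectory$k, ora$k, tolerance = 1e-12)
  }
})

test_that("state stays positive for the whole cohort across schedule types", {
  schedules <- c(lapply(c(1, 1.8, 3), constant_schedule),
                 list(ramp_schedule(), ramp_schedule(direction = "decreasing")))
  for (p in reference_cohort()) for (s in schedules) {
    traj <- simulate_course(p, s)$trajectory
    expect_true(all(traj$V_a > 0))
    expect_true(all(traj$V_n >= 0))
    expect_true(all(traj$k > 0))
    expect_true(all(traj$V_t >= traj$V_a))
    expect_equal(nrow(traj), max(s$fractions$day) + 2)
  }
})

test_that("without irradiation the tumor approaches capacity monotonically", {
  for (p in reference_cohort()[c("A", "D", "G")]) {
    state <- initial_state(p)
    gap <- abs(p$k_hat - 100)
    horizon <- ceiling(5 / p$rho)  # ~5 Gompertz time constants
    for (day in seq_len(horizon)) {
      state <- tumor_step(state, NULL, p)
      expect_lte(abs(state$v_a - p$k_hat), gap)
      gap <- abs(state$v_a - p$k_hat)
      expect_identical(state$k, p$k_hat)        # capacity untouched
      expect_identical(nrow(state$cohorts), 0L) # no necrosis ever
    }
    expect_lt(gap, 0.02 * p$k_hat)  # essentially saturated
  }
})

test_that("with fixed fraction count and no vascular damage, more dose per
           fraction lowers the active volume on every day", {
  days <- c(0:4, 7:11, 14:18)
  for (p0 in reference_cohort()[c("A", "C", "E")]) {
    p <- patient_parameters(p0$id, p0$rho, p0$t_half, p0$k_hat, 0)
    trajs <- lapply(c(1, 1.5, 2, 2.5, 3), function(d)
      simulate_course(p, schedule_from_fractions(days, rep(d, 15)))$trajectory$V_a)
    for (i in 1:4)
      expect_true(all(trajs[[i + 1]][-1] < trajs[[i]][-1]))
  }
})

test_that("horizon extends the course with rest days", {
  b <- reference_cohort()$B
  s <- constant_schedule(2)
  base <- simulate_course(b, s)
  long <- simulate_course(b, s, horizon = base$t_e + 30)
  expect_equal(long$trajectory$V_a[seq_len(base$t_e + 1)],
               base$trajectory$V_a)
  expect_equal(nrow(long$trajectory), base$t_e + 31)
  expect_error(simulate_course(b, s, horizon = 3), "horizon")
})
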