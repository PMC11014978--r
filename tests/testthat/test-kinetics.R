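test_that("parameter containers validate their invariants", {
  expect_s3_class(kinetic_params(0.02, 0.002, 0.02, 0.05), "kinetic_params")
  expect_error(kinetic_params(-1, 0.1, 0.1, 0.5), "non-negative")
  expect_error(kinetic_params(0.1, 0.1, 0.1, 1.5), "p1")
  expect_error(kinetic_params(0.1, 0.1, 0.1, 0.5, dt = 0), "dt")
  expect_error(kinetic_params(0.1, 0.1, 0.1, 0.5, dt = 1, t_max = 1.5),
               "t_max")
  expect_error(grea_model(-0.1, 1, 1), "non-negative")
})

test_that("closed-form pathway rates match their definitions", {
  p <- kinetic_params(0.02, 0.005, 0.004, 0.3)
  expect_equal(k_passive(p), 0.004)
  # k1/(1 + k1/k2) and the harmonic form agree
  expect_equal(k_active(p), 0.004)
  expect_equal(k_active(p), 1 / (1 / 0.02 + 1 / 0.005))
  expect_equal(k_active(kinetic_params(0.01, 0.01, 0, 0)), 0.005)
  # limits
  expect_equal(k_active(kinetic_params(0.01, 1e6, 0, 0)), 0.01,
               tolerance = 1e-6)
  expect_equal(k_active(kinetic_params(0, 0.01, 0.1, 0)), 0)
  blocked <- k_active(kinetic_params(0.01, 0, 0.1, 0))
  expect_equal(as.numeric(blocked), 0)
  expect_true(attr(blocked, "recovery_blocked"))
  # k_passive ignores k1, k2, P1
  expect_equal(k_passive(kinetic_params(9, 9, 0.004, 1)), 0.004)
})

test_that("k_active never exceeds min(k1, k2)", {
  set.seed(1)
  for (i in 1:50) {
    k1 <- runif(1, 1e-4, 1); k2 <- runif(1, 1e-4, 1)
    p <- kinetic_params(k1, k2, 0.01, 0.1)
    expect_lte(k_active(p), min(k1, k2))
  }
})

test_that("GreA enters recovery through Michaelis-Menten saturation", {
  g <- grea_model(k2_basal = 0.002, k2_cat = 0.1, km = 2)
  expect_equal(grea_adjusted_k2(g, 0), 0.002)
  expect_equal(grea_adjusted_k2(g, 2), 0.002 + 0.05)
  expect_equal(grea_adjusted_k2(g, 1e9), 0.102, tolerance = 1e-6)
  expect_error(grea_adjusted_k2(g, -1), "non-negative")
})

test_that("regime classification follows the rate ratio", {
  expect_equal(classify_regime(kinetic_params(0.001, 0.01, 0.05, 0))$label,
               "passive")
  # k_active == k_passive sits strictly between the thresholds
  expect_equal(classify_regime(kinetic_params(0.02, 0.02, 0.01, 0))$label,
               "hybrid")
  expect_equal(classify_regime(kinetic_params(0.05, 0.05, 5e-4, 0),
                               hi = 10)$label, "active")
  expect_equal(classify_regime(kinetic_params(0.05, 0.05, 0, 0.1))$label,
               "active")
  expect_error(classify_regime(kinetic_params(0, 1, 0, 0)), "zero")
})

test_that("passive-limit closed form matches hand arithmetic and limits", {
  # p = 1/2: 2 + (1/2)^2/(1/2) = 2.5
  expect_equal(passive_limit_mean(log(2), dt = 1), 2.5)
  expect_equal(passive_limit_mean(1e6, dt = 1), 2, tolerance = 1e-4)
  p <- 1 - exp(-0.01)
  expect_equal(passive_limit_mean(0.01), 2 + (1 - p)^2 / p)
  expect_error(passive_limit_mean(0), "positive")
})

test_that("degenerate parameter corners follow the update rules exactly", {
  # P1 = 1: two mandatory steps, always transited
  e <- simulate_ensemble(kinetic_params(0.5, 0.5, 0.01, 1), 500, 42)
  expect_true(all(e$outcomes$duration == 2))
  expect_true(all(e$outcomes$transited))
  # no backtracking, no dislodging, no dissociation: censored at t_max
  e2 <- simulate_ensemble(kinetic_params(0, 1, 0, 0), 50, 1)
  expect_true(all(e2$outcomes$duration == 5000))
  expect_true(all(!e2$outcomes$transited))
  expect_true(all(e2$outcomes$n_cycles == 0))
  # the literal reference agrees on the P1 = 1 trace
  r <- simulate_single_reference(kinetic_params(0.2, 0.2, 0.001, 1), 7)
  expect_equal(r$duration, 2)
  expect_equal(r$outcome, "transited")
})

test_that("durations are positive multiples of dt within [2 dt, t_max]", {
  p <- kinetic_params(0.05, 0.02, 0.01, 0.2, dt = 1, t_max = 500)
  d <- simulate_ensemble(p, 2000, 3)$outcomes$duration
  expect_true(all(d >= 2) && all(d <= 500))
  expect_true(all(d == round(d)))
  p2 <- kinetic_params(0.05, 0.02, 0.01, 0.2, dt = 0.5, t_max = 100)
  d2 <- simulate_ensemble(p2, 500, 3)$outcomes$duration
  expect_true(all(abs(d2 / 0.5 - round(d2 / 0.5)) < 1e-9))
  expect_true(all(d2 >= 1) && all(d2 <= 100))
})

test_that("passive-limit sample mean matches the closed form", {
  p <- kinetic_params(0, 1, 0.01, 0)
  d <- simulate_ensemble(p, 1e5, 7)$outcomes$duration
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - passive_limit_mean(0.01)), 3 * se)
})

test_that("mean pause is monotone in each rate (common random numbers)", {
  m <- function(k1, k2, k3, p1)
    simulate_ensemble(kinetic_params(k1, k2, k3, p1), 1e4,
                      77)$summary$mean_duration
  expect_true(!is.unsorted(rev(c(m(0.02, 0.005, 0.01, 0.2),
                                 m(0.02, 0.01, 0.01, 0.2),
                                 m(0.02, 0.02, 0.01, 0.2)))))
  expect_true(!is.unsorted(rev(c(m(0.02, 0.01, 0.005, 0.2),
                                 m(0.02, 0.01, 0.01, 0.2),
                                 m(0.02, 0.01, 0.02, 0.2)))))
  expect_true(!is.unsorted(rev(c(m(0.02, 0.01, 0.01, 0.1),
                                 m(0.02, 0.01, 0.01, 0.2),
                                 m(0.02, 0.01, 0.01, 0.4)))))
  # active regime: faster backtracking shortens pauses
  ma <- function(k1)
    simulate_ensemble(kinetic_params(k1, 0.02, 1e-4, 0.3), 1e4,
                      77)$summary$mean_duration
  expect_true(!is.unsorted(rev(c(ma(0.01), ma(0.02), ma(0.04)))))
})

test_that("active and passive regimes differ in how transit is achieved", {
  act <- simulate_ensemble(kinetic_params(0.02, 0.02, 1e-5, 0.3), 1e4, 5)
  pas <- simulate_ensemble(kinetic_params(1e-4, 0.01, 0.02, 0.05), 1e4, 5)
  expect_gt(act$summary$dislodged_fraction, 0.9)
  expect_lt(pas$summary$dislodged_fraction, 0.1)
})

test_that("ensembles are reproducible and order-independent", {
  p <- kinetic_params(0.05, 0.02, 0.01, 0.2)
  a <- simulate_ensemble(p, 200, 9)$outcomes
  b <- simulate_ensemble(p, 200, 9)$outcomes
  expect_identical(a, b)
  # the first 100 trajectories of a larger ensemble are the same
  big <- simulate_ensemble(p, 400, 9)$outcomes
  expect_identical(a[1:100, ], big[1:100, ])
  # stream offsets give fresh, non-overlapping trajectories
  off <- simulate_ensemble(p, 200, 9, stream_offset = 200)$outcomes
  tail_big <- big[201:400, ]
  rownames(tail_big) <- NULL
  expect_identical(off, tail_big)
})

test_that("generate_pause_sample censors at the observation window", {
  p <- kinetic_params(0.5, 0.5, 0.01, 1)
  s <- generate_pause_sample(p, 100, 3600, 1)
  expect_true(all(s$durations == 2) && !any(s$censored))
  s2 <- generate_pause_sample(kinetic_params(0, 1, 0, 0), 50, 3600, 1)
  expect_true(all(s2$censored) && all(s2$durations == 3600))
  # closed-form mean in the passive limit
  s3 <- generate_pause_sample(kinetic_params(0, 1, 0.01, 0), 1e5, 5000, 2)
  se <- sd(s3$durations) / sqrt(1e5)
  expect_lt(abs(mean(s3$durations) - passive_limit_mean(0.01)), 3 * se)
  # internal consistency: censored iff at the window
  s4 <- generate_pause_sample(kinetic_params(0, 1, 0.001, 0), 2000, 300, 3)
  expect_identical(s4$censored, s4$durations >= 300)
  expect_error(generate_pause_sample(p, 0, 100, 1), "positive")
  expect_error(generate_pause_sample(p, 10, -5, 1), "positive")
  expect_error(generate_pause_sample(p, 10, 1e5, 1), "t_max")
})
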