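# hand-built aligned position series: promoter dwell, transit to the
# operator, a pause, transit out, terminator dwell
stepped_positions <- function(pause_s, at = 709, v = 10, extra = NULL) {
  ramp1 <- seq(v, at - v, by = v)
  ramp2 <- seq(at + v, 1321 - v, by = v)
  c(rep(0, 60), ramp1, rep(at, pause_s), extra, ramp2, rep(1321, 60))
}
geom <- template_geometry(direction = "opposing")

test_that("pause extraction applies the window and duration thresholds", {
  # 30 s dwell at the operator: one record
  r <- extract_pauses(stepped_positions(30), geom)
  expect_equal(nrow(r), 1)
  expect_equal(r$duration_s, 30)
  expect_lt(abs(r$position_bp - 709), 1)
  expect_equal(r$outcome, "transited")
  # 15 s dwell: a ubiquitous pause, excluded
  expect_equal(nrow(extract_pauses(stepped_positions(15), geom)), 0)
  # 100 s dwell at operator + 80 bp: outside the 60 bp window
  r3 <- extract_pauses(stepped_positions(100, at = 709 + 80), geom)
  expect_equal(nrow(r3), 0)
  # empty result is allowed, not an error
  expect_s3_class(extract_pauses(rep(0, 100), geom), "pause_records")
})

test_that("sub-steps near the pause level merge into one pause", {
  # a backtracking excursion: 40 s at the operator, 6 s excursion 4 bp
  # upstream, 30 s back at the operator
  pos <- stepped_positions(40, extra = c(rep(705, 6), rep(709, 30)))
  r <- extract_pauses(pos, geom)
  expect_equal(nrow(r), 1)
  expect_equal(r$duration_s, 76)
  # a long dwell 40 bp away is within the window but far in level, so it
  # splits the record into three separate pauses (40 s and 30 s at the
  # operator, 25 s at the excursion level)
  pos2 <- stepped_positions(40, extra = c(rep(669, 25), rep(709, 30)))
  r2 <- extract_pauses(pos2, geom)
  expect_equal(nrow(r2), 3)
  expect_equal(sort(r2$duration_s), c(25, 30, 40))
})

test_that("a pause running to the end of the record is censored", {
  pos <- c(rep(0, 60), seq(10, 700, by = 10), rep(709, 400))
  r <- extract_pauses(pos, geom)
  expect_equal(r$outcome, "stalled_censored")
  r2 <- extract_pauses(pos, geom, end_state = "terminated_at_roadblock")
  expect_equal(r2$outcome, "terminated_at_roadblock")
})

test_that("thresholds act monotonically on the record set", {
  pos <- stepped_positions(25, extra = c(rep(680, 22), rep(709, 40)))
  base <- extract_pauses(pos, geom, min_pause_s = 20, window_bp = 60)
  lower <- extract_pauses(pos, geom, min_pause_s = 10, window_bp = 60)
  wider <- extract_pauses(pos, geom, min_pause_s = 20, window_bp = 90)
  expect_true(all(base$start_s %in% lower$start_s))
  expect_true(all(base$start_s %in% wider$start_s))
  expect_gte(nrow(lower), nrow(base))
  expect_gte(nrow(wider), nrow(base))
})

test_that("the CCDF is a proper survival curve", {
  s <- pause_sample(c(10, 20, 30))
  cc <- ccdf(s)
  expect_equal(cc$ccdf[1], 1)
  f <- approxfun(cc$t, cc$ccdf, method = "constant", rule = 2)
  expect_equal(f(25), 1 / 3)
  # all censored at T: flat at 1 on [0, T)
  s2 <- pause_sample(rep(100, 5), rep(TRUE, 5))
  cc2 <- ccdf(s2)
  expect_true(all(cc2$ccdf[cc2$t < 100] == 1))
  # random samples: non-increasing, bounded
  set.seed(3)
  s3 <- pause_sample(rexp(200, 1 / 50), runif(200) < 0.3)
  cc3 <- ccdf(s3)
  expect_true(all(diff(cc3$ccdf) <= 0))
  expect_true(all(cc3$ccdf >= 0 & cc3$ccdf <= 1))
  # Kaplan-Meier and truncation agree when nothing is censored
  s4 <- pause_sample(c(5, 8, 13))
  expect_equal(ccdf(s4)$ccdf, ccdf(s4, "truncate")$ccdf)
  expect_error(ccdf(pause_sample(numeric(0), logical(0))), "empty")
})

test_that("censored exponential MLE has its closed form and calibration", {
  # single duration: tau-hat = d
  expect_warning(f1 <- fit_exp_single(pause_sample(42), n_boot = 50),
                 "fewer than 5")
  expect_equal(f1$tau, 42)
  # n = 1000 uncensored, tau = 100: within sampling error
  set.seed(10)
  f2 <- fit_exp_single(pause_sample(rexp(1000, 1 / 100)), n_boot = 200)
  expect_gt(f2$tau, 93); expect_lt(f2$tau, 107)
  expect_true(f2$ci90[1] < f2$tau && f2$tau < f2$ci90[2])
  # censoring-consistency: censor at 70, tau stays near 100
  set.seed(11)
  d <- rexp(2000, 1 / 100); cens <- d >= 70; d[cens] <- 70
  f3 <- fit_exp_single(pause_sample(d, cens, censor_time = 70))
  se <- 100 / sqrt(sum(!cens))
  expect_lt(abs(f3$tau - 100), 3 * se)
  # no uncensored records: unidentifiable
  expect_error(fit_exp_single(pause_sample(rep(70, 10), rep(TRUE, 10))),
               "unidentifiable")
})

test_that("the MLE and CCDF least-squares backends agree within 10%", {
  set.seed(30)
  s <- pause_sample(rexp(500, 1 / 120))
  f_mle <- fit_exp_single(s, n_boot = 50)
  f_ls <- fit_exp_single(s, n_boot = 50, method = "ccdf_ls")
  expect_lt(abs(f_mle$tau - f_ls$tau) / f_mle$tau, 0.10)
})

test_that("fitted CCDF matches the empirical one in sup-norm (DKW)", {
  set.seed(14)
  n <- 400
  s <- pause_sample(rexp(n, 1 / 150))
  f <- fit_exp_single(s, n_boot = 50)
  cc <- ccdf(s)
  gap <- max(abs(cc$ccdf - exp(-cc$t / f$tau)))
  expect_lt(gap, 3 / sqrt(n))
})

test_that("the censored EM recovers a well-separated mixture", {
  set.seed(9)
  d <- c(rexp(2500, 1 / 50), rexp(2500, 1 / 1000))
  f <- fit_exp_double(pause_sample(d), seed = 3)
  expect_equal(f$model, "double")
  # components sorted ascending
  expect_lt(f$tau[1], f$tau[2])
  expect_lt(abs(f$tau[1] - 50) / 50, 0.15)
  expect_lt(abs(f$tau[2] - 1000) / 1000, 0.15)
  expect_lt(abs(f$weight - 0.5), 0.1)
})

test_that("single-exponential data degrades the mixture gracefully", {
  set.seed(15)
  smp <- pause_sample(rexp(2000, 1 / 100))
  f <- fit_exp_double(smp, seed = 3)
  if (f$model == "double") {
    # the EM may split an exponential into two nearby components, but the
    # extra parameters never pay for themselves
    sel <- select_model(fit_exp_single(smp, n_boot = 50), f)
    expect_equal(sel$choice, "single")
  } else {
    expect_true(f$fallback)
  }
})

test_that("model selection prefers parsimony at equal fit", {
  s <- list(model = "single", loglik = -100)
  d <- list(model = "double", loglik = -100)
  class(s) <- class(d) <- "exp_fit"
  sel <- select_model(s, d)
  expect_equal(sel$choice, "single")
  expect_equal(sel$delta_aic, 4)
  # delta-AIC exactly zero still goes single
  d2 <- list(model = "double", loglik = -98)
  class(d2) <- "exp_fit"
  expect_equal(select_model(s, d2)$choice, "single")
  # strongly bimodal data picks double
  set.seed(16)
  smp <- pause_sample(c(rexp(400, 1 / 30), rexp(400, 1 / 800)))
  sel2 <- select_model(fit_exp_single(smp, n_boot = 50),
                       fit_exp_double(smp, seed = 2))
  expect_equal(sel2$choice, "double")
})

test_that("passage fraction uses the Wilson interval", {
  expect_equal(passage_fraction(rep("transited", 8))$fraction, 1)
  p0 <- passage_fraction(rep("stalled_censored", 10))
  expect_equal(p0$fraction, 0)
  expect_lt(p0$ci[2], 0.5)
  # agreement with the textbook Wilson formula at k = 3, n = 10
  p <- passage_fraction(c(rep("transited", 3), rep("stalled_censored", 7)))
  z <- qnorm(0.975)
  centre <- (0.3 + z^2 / 20) / (1 + z^2 / 10)
  expect_equal((p$ci[1] + p$ci[2]) / 2, centre, tolerance = 1e-9)
  # dislodging raises passage within a finite window (common random numbers)
  s_a <- generate_pause_sample(kinetic_params(0.05, 0.05, 1e-4, 0.3),
                               2000, 1000, 5)
  s_b <- generate_pause_sample(kinetic_params(0.05, 0.05, 1e-4, 0),
                               2000, 1000, 5)
  f_a <- mean(!s_a$censored); f_b <- mean(!s_b$censored)
  expect_gt(f_a, f_b)
})

test_that("dropping censored records reproduces the 'excluding stalls' mode", {
  s <- pause_sample(c(30, 50, 200, 3600, 3600),
                    c(FALSE, FALSE, FALSE, TRUE, TRUE), censor_time = 3600)
  s2 <- drop_censored(s)
  expect_equal(length(s2), 3)
  expect_false(any(s2$censored))
  f_all <- suppressWarnings(fit_exp_single(s, n_boot = 50))
  f_drop <- suppressWarnings(fit_exp_single(s, n_boot = 50,
                                            drop_cens = TRUE))
  expect_gt(f_all$tau, f_drop$tau)
})
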