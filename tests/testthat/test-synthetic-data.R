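test_that("geometry and condition constructors enforce invariants", {
  g <- template_geometry()
  expect_equal(g$operator_pos, 709)
  expect_equal(g$terminator_pos, 1321)
  expect_equal(g$anchor_offset, 1021)
  expect_equal(template_geometry(direction = "assisting")$anchor_offset,
               2014)
  expect_error(template_geometry(operator_pos = 0), "operator_pos")
  expect_error(template_geometry(operator_pos = 2000,
                                 terminator_pos = 1321), "operator_pos")
  expect_error(condition("LacI-O1", "opposing", 1.3), "force_pN")
  expect_error(condition("LacI-O1", "opposing", 0), "zero")
  expect_error(condition("LacI-O1", "zero", 0.2), "zero")
  expect_s3_class(condition("LacI-O1", "zero", 0), "expt_condition")
  expect_error(trace_gen_config(velocity = -1), "velocity")
  expect_error(trace_gen_config(a_true = 1.5), "a_true")
})

test_that("a noiseless, pause-free trace is a clean single-plateau record", {
  geom <- template_geometry(direction = "opposing")
  cond <- condition("LacI-O1", "opposing", 0.2)
  gen <- trace_gen_config(noise_sd = 0, ubiquitous_pause_rate = 0,
                          seed = 2, promoter_dwell = 30)
  params <- kinetic_params(0.5, 0.5, 0.01, 1)  # pause is exactly 2 s
  tr <- generate_trace(geom, cond, gen, params)
  expect_equal(tr$meta$truth$roadblock_pause$duration_s, 2)
  op_level <- -1 * gen$nm_per_bp * geom$operator_pos
  expect_equal(sum(abs(tr$extension_nm - op_level) < 1e-9), 2)
  # uniform 1 s time base
  expect_equal(unique(diff(tr$time_s)), 1)
})

test_that("a_true rescales plateau levels linearly at fixed seed", {
  geom <- template_geometry(direction = "opposing")
  cond <- condition("LacI-O1", "opposing", 0.2)
  params <- kinetic_params(0, 0.01, 0.01, 0)
  g1 <- trace_gen_config(noise_sd = 0, a_true = 1, seed = 4)
  g8 <- trace_gen_config(noise_sd = 0, a_true = 0.8, seed = 4)
  t1 <- generate_trace(geom, cond, g1, params)
  t8 <- generate_trace(geom, cond, g8, params)
  expect_equal(t8$extension_nm, 0.8 * t1$extension_nm)
  # the latent trajectory itself is independent of a_true
  expect_identical(t8$meta$truth$position_bp, t1$meta$truth$position_bp)
})

test_that("gap insertion produces a NaN run at NTP addition", {
  geom <- template_geometry(direction = "opposing")
  cond <- condition("LacI-O1", "opposing", 0.2)
  gen <- trace_gen_config(seed = 6, gap_len = 15, promoter_dwell = 100)
  tr <- generate_trace(geom, cond, gen, kinetic_params(0, 0.01, 0.01, 0))
  expect_equal(sum(!is.finite(tr$extension_nm)), 15)
  expect_true(all(!is.finite(tr$extension_nm[101:115])))
})

test_that("stalled traces end at the operator and match their annotation", {
  geom <- template_geometry(direction = "opposing")
  cond <- condition("LacI-Os", "opposing", 0.2)
  gen <- trace_gen_config(noise_sd = 0, ubiquitous_pause_rate = 0, seed = 3)
  params <- kinetic_params(0, 1, 0, 0)  # roadblock never leaves
  tr <- generate_trace(geom, cond, gen, params)
  tp <- tr$meta$truth$roadblock_pause
  expect_true(tp$censored)
  expect_equal(tp$outcome, "stalled_censored")
  expect_equal(length(tr$time_s), 3600)
  op_level <- -1 * gen$nm_per_bp * geom$operator_pos
  expect_equal(tr$extension_nm[length(tr$extension_nm)], op_level)
})

test_that("censoring annotation equals the underlying sample's censoring", {
  geom <- template_geometry(direction = "opposing")
  cond <- condition("LacI-Os", "opposing", 0.2)
  params <- kinetic_params(0, 1, 2e-4, 0)  # mean ~ window: mixed outcomes
  stalled <- 0; censored_draws <- 0
  for (i in 1:30) {
    gen <- trace_gen_config(seed = 800 + i, ubiquitous_pause_rate = 0)
    tr <- generate_trace(geom, cond, gen, params)
    tp <- tr$meta$truth$roadblock_pause
    stalled <- stalled + (tp$outcome == "stalled_censored")
    censored_draws <- censored_draws + tp$censored
  }
  expect_equal(stalled, censored_draws)
  expect_gt(stalled, 0)
  expect_lt(stalled, 30)
})

test_that("cohorts are deterministic, labelled and seed-distinct", {
  rows <- list(
    list(label = "omin", n_traces = 3,
         condition = condition("LacI-O1", "opposing", 0.2),
         params = kinetic_params(0, 0.01, 0.01, 0),
         gen = trace_gen_config(obs_window = 600)),
    list(label = "amin", n_traces = 2,
         condition = condition("LacI-O1", "assisting", 0.2),
         params = kinetic_params(0, 0.01, 0.01, 0),
         gen = trace_gen_config(obs_window = 600)))
  co <- generate_cohort(rows, master_seed = 42)
  expect_length(co, 5)
  expect_equal(vapply(co, function(t) t$meta$label, ""),
               c("omin", "omin", "omin", "amin", "amin"))
  seeds <- vapply(co, function(t) t$meta$gen$seed, numeric(1))
  expect_equal(anyDuplicated(seeds), 0)
  # bit-identical rerun
  co2 <- generate_cohort(rows, master_seed = 42)
  expect_identical(lapply(co, `[[`, "extension_nm"),
                   lapply(co2, `[[`, "extension_nm"))
  # different master seed changes the data
  co3 <- generate_cohort(rows, master_seed = 43)
  expect_false(identical(co[[1]]$extension_nm, co3[[1]]$extension_nm))
  rows_dup <- rows; rows_dup[[2]]$label <- "omin"
  expect_error(generate_cohort(rows_dup), "duplicate")
})

test_that("the full pipeline round-trips a known pause", {
  rt <- run_trace_pipeline(seed = 64, noise_sd = 2)
  recs <- extract_pauses(rt$positions, rt$geometry)
  expect_gte(nrow(recs), 1)
  j <- which.min(abs(recs$position_bp - rt$geometry$operator_pos))
  expect_lte(abs(recs$duration_s[j] - rt$truth$duration_s), 2)
})
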