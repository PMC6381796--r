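test_that("constructors validate their inputs", {
  expect_error(barrier_spec(800, "lagging", "arrest"), "leading")
  expect_error(barrier_spec(800, "leading", "pause"), "lagging")
  expect_error(barrier_spec(800, "lagging", "pause", occupancy = 1.2))
  expect_error(helicase_params(rate_mean = -1))
  expect_error(helicase_params(pause_probability = 2))
  expect_error(sim_config(drop_factor = 1))
  expect_error(sim_config(duration_s = 1, frame_interval_s = 10))
  expect_error(
    simulate_trace(helicase_params(),
                   barrier_spec(5000, "lagging", "pause"),
                   sim_config()),
    "inside the substrate")
})

test_that("a fixed-rate, noise-free molecule completes at L / v", {
  p <- helicase_params(rate_sd = 0)
  tr <- simulate_trace(p, NULL, noiseless_config(seed = 1))
  expect_equal(tr$truth$completion_time_s, L_SUB / 8.2, tolerance = 1e-10)
  # intensity tracks unwound bp exactly, then halves
  pre <- tr$times < tr$truth$completion_time_s
  expect_equal(tr$intensity[pre], tr$truth$unwound_bp[pre])
  expect_equal(unique(tr$intensity[tr$times > tr$truth$completion_time_s]),
               0.5 * L_SUB)
})

test_that("seed determinism gives bit-identical traces and curves", {
  p <- helicase_params()
  a <- simulate_trace(p, barrier_mh_lag(), sim_config(seed = 33))
  b <- simulate_trace(p, barrier_mh_lag(), sim_config(seed = 33))
  expect_identical(a, b)
  ca <- simulate_ensemble(p, NULL, 200, sim_config(), seed = 9)
  cb <- simulate_ensemble(p, NULL, 200, sim_config(), seed = 9)
  expect_identical(ca, cb)
})

test_that("a transparent lagging-strand barrier leaves traces unchanged", {
  p <- helicase_params()
  for (seed in c(2, 17, 1234)) {
    a <- simulate_trace(p, NULL, sim_config(seed = seed))
    b <- simulate_trace(p, barrier_clk_sa_lag(), sim_config(seed = seed))
    expect_identical(a$intensity, b$intensity)
    expect_identical(a$truth$unwound_bp, b$truth$unwound_bp)
  }
})

test_that("a leading-strand arrest block halts unwinding at its position", {
  tr <- simulate_trace(helicase_params(), barrier_mh_lead(occupancy = 1),
                       sim_config(seed = 4))
  expect_equal(max(tr$truth$unwound_bp), BARRIER_BP)
  expect_true(is.na(tr$truth$completion_time_s))
  expect_true(tr$truth$arrested)
})

test_that("unwound bp is non-decreasing and bounded in every trace", {
  p <- helicase_params()
  trs <- simulate_traces(p, barrier_mh_lag(), 50, sim_config(), seed = 12)
  for (tr in trs) {
    expect_true(all(diff(tr$truth$unwound_bp) >= 0))
    expect_true(all(tr$truth$unwound_bp <= L_SUB))
    expect_true(all(diff(tr$times) == 10))
  }
})

test_that("truth pause durations are exponential with the configured mean", {
  p <- helicase_params(pause_probability = 1, pause_mean_s = 4.63 * 60)
  trs <- simulate_traces(p, barrier_mh_lag(), 1000,
                         sim_config(duration_s = 100), seed = 77)
  d <- unlist(lapply(trs, function(tr) tr$truth$pauses$duration_s))
  expect_gte(length(d), 900)
  ks <- suppressWarnings(stats::ks.test(d, "pexp", 1 / (4.63 * 60)))
  expect_gt(ks$p.value, 0.01)
})

test_that("ensemble completion times follow the m-step (Erlang) model", {
  p <- helicase_params(m_steps = 2, k_obs = 1)
  cv <- simulate_ensemble(p, NULL, 50000,
                          sim_config(duration_s = 600, frame_interval_s = 5),
                          seed = 2)
  # closed form at t = 1 min: 1 - 2/e, Monte-Carlo within 3 SE
  target <- 1 - 2 * exp(-1)
  se <- sqrt(target * (1 - target) / 50000)
  expect_lt(abs(cv$signal[cv$time_s == 60] - target), 3 * se)
  expect_equal(cv$signal[1], 0)
})

test_that("a fully occupied arrest barrier flattens the ensemble curve", {
  cv <- simulate_ensemble(helicase_params(), barrier_mh_lead(occupancy = 1),
                          500, sim_config(), seed = 5)
  expect_equal(max(cv$signal), 0)
})

test_that("trace batches round-trip through long-format CSV", {
  trs <- simulate_traces(helicase_params(), NULL, 3,
                         sim_config(duration_s = 200), seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_traces(trs, path, seed = 6)
  back <- read_traces(path)
  expect_length(back, 3)
  expect_equal(back[["mol_2"]]$intensity, trs[[2]]$intensity)
  expect_equal(back[["mol_2"]]$times, trs[[2]]$times)
})
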